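#' Read a trajectory from standard molecular file formats
#'
#' Supported combinations: a multi-model PDB (topology and coordinates
#' in one file), or a single-frame PDB topology plus a DCD coordinate
#' file.  Coordinates are returned in Angstrom, frames in file order.
#' XTC input is not supported; convert to DCD or multi-model PDB
#' first.
#'
#' @param topology path to a PDB file.
#' @param coordinates optional path to a DCD (or multi-model PDB) file;
#'   if `NULL`, frames are taken from `topology` itself.
#' @param dt frame spacing in ps (file metadata for these formats is
#'   unreliable, so it is supplied explicitly).
#' @return A [trajectory()] whose particle ids are `elety:resno` from
#'   the topology.
#' @export
read_trajectory <- function(topology, coordinates = NULL, dt = 1) {
  if (!file.exists(topology))
    stop("topology file not found: ", topology, call. = FALSE)
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  at <- pdb$atom
  ids <- paste0(trimws(at$elety), ":", at$resno)
  n_at <- nrow(at)
  xyz <- pdb$xyz
  if (!is.null(coordinates)) {
    if (!file.exists(coordinates))
      stop("coordinate file not found: ", coordinates, call. = FALSE)
    ext <- tolower(tools::file_ext(coordinates))
    if (ext == "dcd") {
      xyz <- bio3d::read.dcd(coordinates, verbose = FALSE)
    } else if (ext == "pdb") {
      xyz <- bio3d::read.pdb(coordinates, multi = TRUE)$xyz
    } else if (ext == "xtc") {
      stop("XTC reading is not supported; supply DCD or multi-model PDB",
           call. = FALSE)
    } else stop("unrecognized coordinate format: .", ext, call. = FALSE)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_at)
    stop("format error: topology has ", n_at, " atoms but coordinates ",
         "have ", ncol(xyz) / 3, call. = FALSE)
  Tn <- nrow(xyz)
  coords <- array(0, dim = c(Tn, n_at, 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3L * n_at, by = 3L),
                                      drop = FALSE]
  if (!all(is.finite(coords)))
    stop("format error: non-finite coordinates in trajectory",
         call. = FALSE)
  trajectory(coords, particle_ids = ids, dt = dt)
}

#' Write a trajectory as a multi-model PDB
#'
#' A plain-text interchange format readable by [read_trajectory()] and
#' standard visualization tools.  Particle ids of the form
#' `"name:resno"` are split back into atom names and residue numbers.
#'
#' @param traj a [trajectory()].
#' @param path output path (`.pdb`).
#' @return `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  M <- n_particles(traj)
  ids <- strsplit(traj$particle_ids, ":", fixed = TRUE)
  elety <- vapply(ids, `[`, "", 1L)
  resno <- suppressWarnings(as.integer(vapply(ids, function(x)
    if (length(x) > 1L) x[2L] else NA_character_, "")))
  resno[is.na(resno)] <- seq_len(M)[is.na(resno)]
  elety[elety == "" | grepl("^p[0-9]+$", elety)] <- "C"
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    X <- traj$coords[t, , , drop = TRUE]
    if (M == 1L) X <- matrix(X, 1L, 3L)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(M), substr(elety, 1L, 4L), "MOL", resno,
      X[, 1L], X[, 2L], X[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Run configuration documents
#'
#' A run configuration gathers grid, model, schedule, optimizer and
#' evaluation settings in one YAML document that round-trips
#' losslessly.  Defaults mirror the package function defaults; unknown
#' keys are rejected so typos fail loudly before any stage runs.
#'
#' @param grid list of [grid_spec()] arguments.
#' @param model list of [model_config()] arguments (atom/bead counts
#'   may be omitted and filled from data).
#' @param training list of [train_control()] arguments.
#' @param evaluation list: `msm_lag`, `tica_lag`, `k` (centroids),
#'   `bins`.
#' @param simulation list: `preset`, `steps`, `test_steps`.
#' @param seed integer seed for the run.
#' @return Object of class `run_config` (a validated nested list).
#' @export
run_config <- function(grid = list(), model = list(), training = list(),
                       evaluation = list(), simulation = list(),
                       seed = 1L) {
  chk <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra))
      stop("invalid config field(s) in `", where, "`: ",
           paste(extra, collapse = ", "), call. = FALSE)
    given
  }
  cfg <- list(
    grid = chk(grid, c("d", "r_grid", "sigma", "sigma_units"), "grid"),
    model = chk(model, c("n_atoms", "n_beads", "d_latent", "hidden",
                         "n_blocks"), "model"),
    training = chk(training, names(formals(train_control)), "training"),
    evaluation = chk(evaluation, c("msm_lag", "tica_lag", "k", "bins"),
                     "evaluation"),
    simulation = chk(simulation, c("preset", "steps", "test_steps",
                                   "barrier"), "simulation"),
    seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_run_config()` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(run_config, doc)
}

#' Write a run manifest
#'
#' Each pipeline stage records its configuration, seeds and input file
#' hashes in a JSON manifest next to its outputs, so identical
#' config + seeds reproduce identical artifacts.
#'
#' @param path output JSON path.
#' @param config a `run_config` (or any list).
#' @param inputs character vector of input file paths to hash.
#' @param extra additional fields to record.
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(),
                           extra = list()) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, "")
  man <- c(list(config = unclass(config),
                inputs = as.list(hashes),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
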