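#' Particle configuration frames and trajectories
#'
#' A `frame` holds the Cartesian coordinates (in Angstrom) of an ordered
#' set of particles at one time point; a `trajectory` is a stack of
#' frames with a fixed particle order and a uniform frame spacing `dt`
#' (picoseconds).  Particle order is part of the data contract: it is
#' identical across all frames of a trajectory, and coarse-grained (CG)
#' bead order is defined by the mapping that produced the beads.
#'
#' @param coords numeric M x 3 matrix of coordinates (A).
#' @param particle_ids character vector of particle labels, length M.
#'   Defaults to `"p1" ... "pM"`.
#' @return An object of class `frame`: a list with elements `coords`
#'   and `particle_ids`.
#' @examples
#' f <- frame(matrix(rnorm(9), 3, 3))
#' n_particles(f)
#' @export
frame <- function(coords, particle_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("`coords` must be an M x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in frame", call. = FALSE)
  storage.mode(coords) <- "double"
  if (is.null(particle_ids))
    particle_ids <- paste0("p", seq_len(nrow(coords)))
  if (length(particle_ids) != nrow(coords))
    stop("`particle_ids` must have one entry per particle", call. = FALSE)
  structure(list(coords = coords, particle_ids = as.character(particle_ids)),
            class = "frame")
}

#' @rdname frame
#' @param x object to inspect or convert.
#' @export
n_particles <- function(x) {
  if (inherits(x, "frame")) return(nrow(x$coords))
  if (inherits(x, "trajectory")) return(dim(x$coords)[2L])
  stop("not a frame or trajectory", call. = FALSE)
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame> ", nrow(x$coords), " particles\n", sep = "")
  invisible(x)
}

#' Build a trajectory from a coordinate array
#'
#' @param coords a T x M x 3 numeric array, or a list of M x 3 matrices.
#' @param particle_ids particle labels (length M).
#' @param dt frame spacing in ps.
#' @return An object of class `trajectory` with elements `coords`
#'   (T x M x 3 array), `particle_ids` and `dt`.
#' @export
trajectory <- function(coords, particle_ids = NULL, dt = 1) {
  if (is.list(coords)) {
    M <- nrow(coords[[1L]])
    arr <- array(0, dim = c(length(coords), M, 3L))
    for (t in seq_along(coords)) arr[t, , ] <- as.matrix(coords[[t]])
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("`coords` must be a T x M x 3 array", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in trajectory", call. = FALSE)
  if (is.null(particle_ids))
    particle_ids <- paste0("p", seq_len(dim(coords)[2L]))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(coords = coords, particle_ids = as.character(particle_ids),
                 dt = dt),
            class = "trajectory")
}

#' @rdname trajectory
#' @param x a trajectory.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  dim(x$coords)[1L]
}

#' @rdname trajectory
#' @param t frame index (1-based).
#' @export
get_frame <- function(x, t) {
  stopifnot(inherits(x, "trajectory"))
  if (t < 1L || t > n_frames(x))
    stop("frame index out of range", call. = FALSE)
  frame(x$coords[t, , , drop = TRUE], x$particle_ids)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", n_particles(x),
      " particles, dt = ", x$dt, " ps\n", sep = "")
  invisible(x)
}

#' Root-mean-square deviation between two frames
#'
#' Computed on raw coordinates without superposition; see
#' [kabsch_align()] for optimal rigid-body alignment.
#'
#' @param a,b frames (or M x 3 matrices) with matching particle counts.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  ca <- if (inherits(a, "frame")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "frame")) b$coords else as.matrix(b)
  if (!all(dim(ca) == dim(cb)))
    stop("frames have different particle counts", call. = FALSE)
  sqrt(mean(rowSums((ca - cb)^2)))
}

.coords <- function(x) {
  if (inherits(x, "frame")) x$coords else as.matrix(x)
}
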