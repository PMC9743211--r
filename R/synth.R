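#' Toy molecular systems for synthetic trajectory generation
#'
#' Bundles everything needed to generate sequentially correlated
#' Langevin trajectories of a bead-spring molecule: atom count,
#' bonded topology (through the [toy_forcefield()]), CG mapping,
#' thermodynamic state and integration settings.  Temperature is given
#' directly as `kT` in kJ/mol (2.479 kJ/mol corresponds to 300 K).
#'
#' @param n_atoms number of atoms.
#' @param forcefield a [toy_forcefield()] covering those atoms.
#' @param mapping a [cg_mapping()] into the atomistic frame.
#' @param x0 initial coordinates (n_atoms x 3, A).
#' @param kT thermal energy in kJ/mol.
#' @param friction Langevin friction in 1/ps.
#' @param mass per-atom mass in amu (recycled).
#' @param dt integration time step in ps.
#' @param stride record one frame every `stride` steps (>= 1).
#' @param grid suggested [grid_spec()] for voxelizing this system.
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(n_atoms, forcefield, mapping, x0,
                       kT = 2.479, friction = 2, mass = 12,
                       dt = 0.002, stride = 10L, grid = NULL) {
  stopifnot(inherits(forcefield, "toy_forcefield"),
            inherits(mapping, "cg_mapping"))
  x0 <- as.matrix(x0)
  if (nrow(x0) != n_atoms || ncol(x0) != 3L)
    stop("`x0` must be n_atoms x 3", call. = FALSE)
  if (max(mapping$atom_indices) > n_atoms)
    stop("mapping indexes beyond the system's atoms", call. = FALSE)
  stride <- as.integer(stride)
  if (stride < 1L) stop("`stride` must be >= 1", call. = FALSE)
  structure(list(n_atoms = as.integer(n_atoms), forcefield = forcefield,
                 mapping = mapping, x0 = x0, kT = kT, friction = friction,
                 mass = rep_len(mass, n_atoms), dt = dt, stride = stride,
                 grid = grid),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system> ", x$n_atoms, " atoms -> ", n_beads(x$mapping),
      " beads, kT = ", x$kT, " kJ/mol, dt = ", x$dt, " ps, stride = ",
      x$stride, "\n", sep = "")
  invisible(x)
}

#' Benchmark toy-molecule presets
#'
#' Two fixed systems exercise every pipeline stage at desk scale:
#' \describe{
#'   \item{`"dimer"`}{two atoms joined by one harmonic bond
#'     (k_b = 100 kJ/mol/A^2, r0 = 1.5 A), coarse-grained to the first
#'     atom.  The simplest non-trivial system; its bond-length variance
#'     has the closed form kT / k_b.}
#'   \item{`"tetramer-2state"`}{a four-atom chain (three bonds, two
#'     angles) with one torsional double well of 6 kJ/mol barrier
#'     (about 2.4 kT at 300 K), giving two metastable torsional states
#'     with dwell times long compared to the frame spacing yet short
#'     enough to sample many transitions in a desk-scale run.
#'     Coarse-grained to the two end atoms.  This is the minimal
#'     analogue of a dipeptide's metastable backbone-dihedral
#'     structure.}
#' }
#' The suggested voxel grid for the tetramer is `d = 17`,
#' `r_grid = 8 A`, `sigma` = one lattice spacing (1 A): after centering
#' on the CG centroid all atoms stay more than `3 sigma` inside the
#' boundary.
#'
#' @param preset `"dimer"` or `"tetramer-2state"`.
#' @param barrier torsional barrier height (kJ/mol), tetramer only.
#' @return A [toy_system()].
#' @export
make_benchmark_system <- function(preset = c("dimer", "tetramer-2state"),
                                  barrier = 6) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e)
                       stop("unknown preset: ", preset[1L], call. = FALSE))
  if (preset == "dimer") {
    ff <- toy_forcefield(bonds = cbind(1, 2, 100, 1.5))
    map <- cg_mapping(1L, "b1")
    x0 <- rbind(c(-0.75, 0, 0), c(0.75, 0, 0))
    return(toy_system(2L, ff, map, x0,
                      grid = grid_spec(d = 17L, r_grid = 6, sigma = 1,
                                       sigma_units = "angstrom")))
  }
  ff <- toy_forcefield(
    bonds = rbind(c(1, 2, 100, 1.5),
                  c(2, 3, 100, 1.5),
                  c(3, 4, 100, 1.5)),
    angles = rbind(c(1, 2, 3, 40, 1.911),
                   c(2, 3, 4, 40, 1.911)),
    dihedrals = cbind(1, 2, 3, 4, barrier))
  map <- cg_mapping(c(1L, 4L), c("end1", "end2"))
  # trans-planar chain with tetrahedral-ish angles
  x0 <- rbind(c(-1.95, 0.70, 0),
              c(-0.75, -0.20, 0),
              c(0.75, 0.20, 0),
              c(1.95, -0.70, 0))
  toy_system(4L, ff, map, x0,
             grid = grid_spec(d = 17L, r_grid = 8, sigma = 1,
                              sigma_units = "angstrom"))
}

#' Simulate a Langevin trajectory of a toy system
#'
#' Underdamped Langevin dynamics integrated with the BAOAB splitting
#' scheme; frames are recorded every `system$stride` steps so that
#' consecutive recorded frames are correlated but not duplicated.  All
#' randomness flows through R's RNG: `set.seed()` (or the `seed`
#' argument) makes runs bit-reproducible.
#'
#' @param system a [toy_system()].
#' @param steps number of integration steps (recorded frames =
#'   `steps %/% stride`).
#' @param seed optional integer seed applied before integration.
#' @param x0,v0 optional starting coordinates/velocities (defaults:
#'   `system$x0` and Maxwell-Boltzmann velocities).
#' @param guard abort if any coordinate magnitude exceeds this bound
#'   (instability detection).
#' @return A [trajectory()] with `dt = system$dt * system$stride`;
#'   attributes `x_final` and `v_final` support chained runs.
#' @export
simulate_langevin <- function(system, steps, seed = NULL, x0 = NULL,
                              v0 = NULL, guard = 1e4) {
  stopifnot(inherits(system, "toy_system"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- system$x0
  x0 <- as.matrix(x0)
  if (is.null(v0)) {
    sdv <- sqrt(.KJU * system$kT / system$mass)
    v0 <- matrix(rnorm(3L * system$n_atoms), system$n_atoms, 3L) * sdv
  }
  steps <- as.integer(steps)
  if (steps < system$stride)
    stop("`steps` must be at least one stride", call. = FALSE)
  res <- .langevin_cpp(x0, as.matrix(v0), unclass(system$forcefield),
                       system$mass, system$kT, system$friction,
                       system$dt, steps, system$stride, guard)
  traj <- trajectory(res$coords, dt = system$dt * system$stride)
  attr(traj, "x_final") <- res$x_final
  attr(traj, "v_final") <- res$v_final
  traj
}

#' Emit a toy system preset as standard files
#'
#' Writes a single-frame PDB topology, a multi-model PDB trajectory and
#' the force-field/mapping YAML documents so that the preset is
#' consumable through the standard-format readers.
#'
#' @param system a [toy_system()].
#' @param traj a [trajectory()] from [simulate_langevin()].
#' @param dir output directory (created if needed).
#' @param name base name for the emitted files.
#' @return Named list of file paths.
#' @export
write_system <- function(system, traj, dir, name = "toy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    topology = file.path(dir, paste0(name, "_top.pdb")),
    trajectory = file.path(dir, paste0(name, "_traj.pdb")),
    forcefield = file.path(dir, paste0(name, "_ff.yaml")),
    mapping = file.path(dir, paste0(name, "_mapping.yaml")))
  write_trajectory(trajectory(array(system$x0,
                                    dim = c(1L, system$n_atoms, 3L)),
                              dt = traj$dt),
                   paths$topology)
  write_trajectory(traj, paths$trajectory)
  write_forcefield(system$forcefield, paths$forcefield)
  write_mapping(system$mapping, paths$mapping)
  paths
}
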