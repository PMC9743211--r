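#' Fit a generative backmapping model to atomistic trajectories
#'
#' The top-level modelling interface: given one or more reference
#' atomistic trajectories and a CG mapping, assembles the
#' (current frame, CG frame, previous frame) training triplets, trains
#' the conditional VAE, encodes the training set and fits the ex-post
#' Gaussian-mixture latent prior.  The returned object backmaps CG
#' trajectories through [predict.backmapper()] and generates
#' alternative reconstructions of a single condition through
#' [simulate.backmapper()].
#'
#' @param trajectories a [trajectory()] or list of trajectories.
#' @param mapping a [cg_mapping()].
#' @param grid a [grid_spec()]; defaults to a cube that encloses the
#'   training data with a 3-sigma margin after CG-centroid centering.
#' @param forcefield optional [toy_forcefield()] for the energy
#'   regularizer.
#' @param config optional [model_config()] (built automatically
#'   otherwise).
#' @param control a [train_control()].
#' @param prior_components mixture components for the latent prior.
#' @param prior_subsample cap on the number of training codes used for
#'   the mixture fit.
#' @param seed integer seed for the whole fit.
#' @return Object of class `backmapper` with elements `checkpoint`,
#'   `prior`, `mapping`, `grid`, `dataset_size`, `reference` (the
#'   first training trajectory, kept for seed-frame selection) and
#'   `call`.
#' @seealso [backmap_trajectory()], [select_seed_frame()]
#' @export
backmapper <- function(trajectories, mapping, grid = NULL,
                       forcefield = NULL, config = NULL,
                       control = train_control(), prior_components = 10L,
                       prior_subsample = 2000L, seed = 1L) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  dataset <- build_dataset(trajectories, mapping)
  N <- n_particles(trajectories[[1L]])
  n <- n_beads(mapping)
  if (is.null(grid)) grid <- .auto_grid(trajectories, mapping)
  if (is.null(config))
    config <- model_config(N, n, grid)
  ck <- train_model(dataset, config, forcefield = forcefield,
                    control = control, seed = seed)
  idx <- seq_len(nrow(dataset$index))
  if (length(idx) > prior_subsample) {
    set.seed(seed)
    idx <- sort(sample(idx, prior_subsample))
  }
  codes <- posterior_codes(ck, dataset, idx)
  prior <- fit_latent_prior(codes, K = min(prior_components, nrow(codes)))
  structure(list(checkpoint = ck, prior = prior, mapping = mapping,
                 grid = grid, dataset_size = nrow(dataset$index),
                 reference = trajectories[[1L]], seed = seed,
                 call = match.call()),
            class = "backmapper")
}

.auto_grid <- function(trajectories, mapping, d = 17L) {
  ext <- 0
  for (tr in trajectories) {
    for (t in seq_len(n_frames(tr))) {
      X <- tr$coords[t, , , drop = TRUE]
      cen <- colMeans(X[mapping$atom_indices, , drop = FALSE])
      ext <- max(ext, abs(sweep(X, 2L, cen)))
    }
  }
  spacing_guess <- 2 * ext / (d - 7)  # leave a 3-spacing sigma margin
  r <- ext + 3.5 * spacing_guess
  grid_spec(d = d, r_grid = r, sigma = 1, sigma_units = "lattice")
}

#' @export
print.backmapper <- function(x, ...) {
  cfg <- x$checkpoint$model$config
  cat("Generative CG backmapping model\n")
  cat("  atoms: ", cfg$n_atoms, "  beads: ", cfg$n_beads,
      "  reduction: ", signif(reduction_factor(cfg$n_atoms, cfg$n_beads), 4),
      "x\n", sep = "")
  cat("  latent dim: ", cfg$d_latent, "  grid: d = ", cfg$grid$d,
      ", r_grid = ", signif(cfg$grid$r_grid, 4), " A\n", sep = "")
  cat("  training samples: ", x$dataset_size, "; final loss: ",
      signif(tail(x$checkpoint$log$total, 1L), 5), "\n", sep = "")
  invisible(x)
}

#' @export
summary.backmapper <- function(object, ...) {
  log <- object$checkpoint$log
  structure(list(log = log, prior = object$prior,
                 config = object$checkpoint$model$config,
                 final = log[nrow(log), ],
                 dataset_size = object$dataset_size),
            class = "summary.backmapper")
}

#' @export
print.summary.backmapper <- function(x, ...) {
  cat("Backmapping cVAE fit\n")
  print(x$config)
  cat("Training samples:", x$dataset_size, "\n")
  cat("Final losses (step ", x$final$step, "):\n", sep = "")
  print(round(unlist(x$final[-1L]), 6))
  cat("Latent prior: "); print(x$prior)
  invisible(x)
}

#' Backmap a CG trajectory with a fitted model
#'
#' @param object a [backmapper()] fit.
#' @param newdata the CG [trajectory()] to backmap.
#' @param seed_frame optional seed [frame()]; selected automatically
#'   from the stored reference trajectory when omitted.
#' @param seed integer seed for the latent draws.
#' @param ... unused.
#' @return An atomistic [trajectory()].
#' @export
predict.backmapper <- function(object, newdata, seed_frame = NULL,
                               seed = 1L, ...) {
  stopifnot(inherits(newdata, "trajectory"))
  if (is.null(seed_frame))
    seed_frame <- select_seed_frame(object$reference,
                                    get_frame(newdata, 1L),
                                    object$mapping)
  backmap_trajectory(newdata, object$checkpoint, prior = object$prior,
                     seed_frame = seed_frame, seed = seed)
}

#' Generate alternative reconstructions of one CG condition
#'
#' Draws `nsim` latent codes from the ex-post prior and decodes each
#' under the same fixed condition, exposing the conformational
#' diversity of the learned conditional distribution.
#'
#' @param object a [backmapper()] fit.
#' @param nsim number of reconstructions.
#' @param seed integer seed.
#' @param cg_frame the conditioning CG [frame()].
#' @param prev_frame the conditioning previous atomistic [frame()].
#' @param ... unused.
#' @return List of `nsim` atomistic [frame()]s.
#' @export
simulate.backmapper <- function(object, nsim = 1L, seed = 1L,
                                cg_frame, prev_frame, ...) {
  model <- object$checkpoint$model
  config <- model$config
  set.seed(seed)
  Z <- sample_latent_prior(object$prior, nsim)
  G <- .coords(cg_frame); P <- .coords(prev_frame)
  cen <- colMeans(G)
  Gc <- sweep(G, 2L, cen); Pc <- sweep(P, 2L, cen)
  spec <- config$grid
  Gr <- .readout_coords(Gc, spec); Pr <- .readout_coords(Pc, spec)
  lapply(seq_len(nsim), function(i) {
    Xp <- .decode_coords(model$params, config, Z[i, ], Gr, Pr)
    frame(sweep(.readout_coords(Xp, spec), 2L, cen, "+"))
  })
}

#' @export
plot.backmapper <- function(x, ...) {
  log <- x$checkpoint$log
  graphics::matplot(log$step,
                    log[, c("total", "coord_mse", "cg_mse", "kl")],
                    type = "l", lty = 1, lwd = 2, log = "y",
                    xlab = "training step", ylab = "loss (log scale)",
                    col = c("black", "firebrick", "steelblue",
                            "darkorange"), ...)
  graphics::legend("topright", legend = c("total", "coord", "CG", "KL"),
                   col = c("black", "firebrick", "steelblue",
                           "darkorange"), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Residual CG-consistency errors of a backmapped trajectory
#'
#' Per-frame RMSD between the CG projection of each reconstructed
#' frame and the CG frame it was conditioned on — the primary internal
#' quality control of a backmapping.
#'
#' @param object a [backmapper()] fit.
#' @param backmapped the reconstructed atomistic [trajectory()].
#' @param cg_traj the CG [trajectory()] it was generated from.
#' @param ... unused.
#' @return Numeric vector of per-frame RMSDs (A).
#' @export
residuals.backmapper <- function(object, backmapped, cg_traj, ...) {
  proj <- apply_mapping(object$mapping, backmapped)
  vapply(seq_len(n_frames(proj)), function(t)
    rmsd(proj$coords[t, , , drop = TRUE],
         cg_traj$coords[t, , , drop = TRUE]),
    0)
}

#' Structural / thermodynamic / kinetic evaluation battery
#'
#' Compares a backmapped trajectory against a reference atomistic
#' trajectory with the package's full evaluation toolkit: potential
#' energy distributions, a free-energy surface over a collective
#' variable (torsion angle by default), Markov-model implied
#' timescales with eigenvector similarities on a shared k-means
#' discretization fitted to the reference, and finite-difference
#' velocity distributions with mean-matching rescaling.
#'
#' @param reference,backmapped atomistic [trajectory()]s with a common
#'   particle order and frame spacing.
#' @param forcefield a [toy_forcefield()] for the energy comparison
#'   (optional).
#' @param cv_indices 4-vector of atom indices defining the torsion
#'   collective variable (default `1:4`).
#' @param k k-means centroids for the Markov models.
#' @param msm_lag Markov-model lag in frames.
#' @param bins histogram bins.
#' @return A list report (JSON-serializable) with components
#'   `energy`, `fes`, `msm`, `velocity`.
#' @export
evaluate_backmapping <- function(reference, backmapped,
                                 forcefield = NULL, cv_indices = 1:4,
                                 k = 20L, msm_lag = 5L, bins = 36L) {
  stopifnot(inherits(reference, "trajectory"),
            inherits(backmapped, "trajectory"))
  report <- list()
  if (!is.null(forcefield)) {
    e_ref <- vapply(seq_len(n_frames(reference)), function(t)
      potential_energy(forcefield, reference$coords[t, , , drop = TRUE]), 0)
    e_bm <- vapply(seq_len(n_frames(backmapped)), function(t)
      potential_energy(forcefield, backmapped$coords[t, , , drop = TRUE]), 0)
    report$energy <- compare_energy_distributions(e_ref, e_bm, bins)
  }
  phi_ref <- dihedral_series(reference, cv_indices)
  phi_bm <- dihedral_series(backmapped, cv_indices)
  lim <- list(c(-180, 180))
  report$fes <- list(
    reference = fes_histogram(matrix(phi_ref), bins, limits = lim)$F,
    backmapped = fes_histogram(matrix(phi_bm), bins, limits = lim)$F)
  km <- kmeans_discretize(matrix(phi_ref), k)
  d_ref <- km$states
  d_bm <- assign_states(km$centroids, matrix(phi_bm))
  m_ref <- msm_estimate(d_ref, lag = msm_lag)
  m_bm <- msm_estimate(d_bm, lag = msm_lag)
  ts_ref <- implied_timescales(m_ref, tau = msm_lag * reference$dt)
  ts_bm <- implied_timescales(m_bm, tau = msm_lag * backmapped$dt)
  report$msm <- list(
    timescales_reference = ts_ref,
    timescales_backmapped = ts_bm,
    eigenvector_similarity =
      tryCatch(eigenvector_similarity(m_ref, m_bm, 3L),
               error = function(e) NA_real_))
  v_ref <- velocity_distribution(reference)
  v_bm <- velocity_distribution(backmapped)
  report$velocity <- list(
    mean_reference = v_ref$mean, mean_backmapped = v_bm$mean,
    ratio = v_bm$mean / v_ref$mean,
    rescale_factor = rescale_velocities(v_bm$pooled, v_ref$pooled)$factor,
    wasserstein_after_rescale = wasserstein1(
      as.vector(v_ref$pooled),
      as.vector(v_bm$pooled) * v_ref$mean / v_bm$mean))
  report
}
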