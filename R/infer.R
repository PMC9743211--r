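#' Fit an ex-post Gaussian-mixture prior over latent codes
#'
#' After training, the decoder has only ever seen latent codes from the
#' aggregated training posterior, so sampling from the assumed standard
#' normal prior can land in unvisited latent regions.  Fitting a
#' K-component Gaussian mixture to the encoder's posterior means over
#' the training set (ex-post density estimation) and sampling from that
#' mixture at inference keeps the decoder on-distribution.  The default
#' of 10 components follows common practice for this estimator.
#'
#' @param codes numeric matrix (samples x d_latent) of posterior means.
#' @param K number of mixture components.
#' @param model_names covariance structures to try, passed to
#'   [mclust::Mclust()]; the best by BIC is kept.
#' @return Object of class `latent_prior`: `weights` (K), `means`
#'   (K x d), `covariances` (d x d x K).
#' @export
fit_latent_prior <- function(codes, K = 10L,
                             model_names = c("VVV", "VVI", "VII", "EII")) {
  codes <- as.matrix(codes)
  if (nrow(codes) < K)
    stop("need at least K = ", K, " codes to fit the mixture", call. = FALSE)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- mclust::Mclust(codes, G = K, modelNames = model_names,
                        verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed for every covariance structure", call. = FALSE)
  p <- fit$parameters
  d <- ncol(codes)
  covs <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    S <- if (length(dim(p$variance$sigma)) == 3L) p$variance$sigma[, , k]
         else p$variance$sigma
    covs[, , k] <- as.matrix(S)
  }
  structure(list(weights = p$pro, means = t(p$mean), covariances = covs,
                 K = K, model_name = fit$modelName),
            class = "latent_prior")
}

#' @export
print.latent_prior <- function(x, ...) {
  cat("<latent_prior> ", x$K, "-component Gaussian mixture (",
      x$model_name, ") over R^", ncol(x$means), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_latent_prior
#' @param prior a `latent_prior`.
#' @param n number of samples.
#' @param seed optional integer seed (sampling is seed-reproducible).
#' @return `sample_latent_prior()` returns an n x d matrix.
#' @export
sample_latent_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "latent_prior"))
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(prior$means)
  comp <- sample.int(prior$K, n, replace = TRUE, prob = prior$weights)
  out <- matrix(0, n, d)
  chols <- lapply(seq_len(prior$K), function(k)
    chol(prior$covariances[, , k] + diag(1e-12, d)))
  for (i in seq_len(n))
    out[i, ] <- prior$means[comp[i], ] +
      drop(rnorm(d) %*% chols[[comp[i]]])
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation minimizing the RMSD between the mobile and
#' reference point sets after centering both on their centroids, via
#' SVD of the 3 x 3 covariance with a determinant correction that
#' excludes reflections.
#'
#' @param mobile,reference [frame()]s (or M x 3 matrices) with equal
#'   particle counts.
#' @return List with `rotation` (3 x 3, applied as `X %*% rotation`),
#'   `aligned` (the mobile frame rotated and translated onto the
#'   reference centroid), `rmsd` (after alignment) and `rmsd_before`.
#' @export
kabsch_align <- function(mobile, reference) {
  X <- .coords(mobile); Y <- .coords(reference)
  if (!all(dim(X) == dim(Y)))
    stop("particle counts differ", call. = FALSE)
  if (nrow(X) < 3L)
    warning("fewer than 3 particles: rotation is underdetermined; ",
            "returning best-effort alignment", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (nrow(X) >= 3L && abs(sv$d[2L]) < 1e-10 * max(sv$d[1L], 1e-300))
    warning("degenerate (collinear) geometry: rotation about the axis ",
            "is arbitrary", call. = FALSE)
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  aligned <- sweep(Xc %*% R, 2L, cy, "+")
  ids <- if (inherits(mobile, "frame")) mobile$particle_ids else NULL
  list(rotation = R,
       aligned = frame(aligned, ids),
       rmsd = sqrt(mean(rowSums((Xc %*% R - Yc)^2))),
       rmsd_before = sqrt(mean(rowSums((Xc - Yc)^2))))
}

#' Select the seed frame for autoregressive backmapping
#'
#' The first backmapped frame has no preceding atomistic frame, so one
#' is borrowed from the training data: find the training frame `t*`
#' whose CG projection minimizes the aligned RMSD to the first CG frame
#' to be backmapped, take the immediately preceding frame `t* - 1` (or
#' `t*` itself when `t* = 1`), and rigidly align it to the CG target
#' (rotation computed on the CG beads, applied to all atoms).
#'
#' @param train_traj atomistic [trajectory()] from the training data.
#' @param cg0 the first CG [frame()] of the trajectory to backmap.
#' @param mapping the [cg_mapping()].
#' @return The aligned seed [frame()]; attributes `t_star` and `rmsd`
#'   record the matched frame and its CG RMSD.
#' @export
select_seed_frame <- function(train_traj, cg0, mapping) {
  stopifnot(inherits(train_traj, "trajectory"))
  G0 <- .coords(cg0)
  Tn <- n_frames(train_traj)
  best <- Inf; t_star <- 1L
  cg_all <- train_traj$coords[, mapping$atom_indices, , drop = FALSE]
  for (t in seq_len(Tn)) {
    r <- suppressWarnings(
      kabsch_align(cg_all[t, , , drop = TRUE], G0)$rmsd)
    if (r < best) { best <- r; t_star <- t }
  }
  t_seed <- max(t_star - 1L, 1L)
  seed_f <- get_frame(train_traj, t_seed)
  cg_seed <- seed_f$coords[mapping$atom_indices, , drop = FALSE]
  al <- suppressWarnings(kabsch_align(cg_seed, G0))
  cen <- colMeans(cg_seed)
  aligned <- sweep(sweep(seed_f$coords, 2L, cen) %*% al$rotation,
                   2L, colMeans(G0), "+")
  out <- frame(aligned, seed_f$particle_ids)
  attr(out, "t_star") <- t_star
  attr(out, "rmsd") <- best
  out
}

#' Generatively backmap a CG trajectory
#'
#' Autoregressive rollout of the trained decoder: frame 0 is decoded
#' from a latent sample, the CG frame and the seed frame; every later
#' frame is decoded from a fresh latent sample, its CG frame and the
#' previous reconstruction.  Each step centers the condition on the
#' current CG centroid, exactly as during training, and shifts the
#' decoded atoms back.  Different seeds give distinct but individually
#' valid trajectories (nondeterministic backmapping); a fixed seed is
#' bit-reproducible.
#'
#' @param cg_traj CG [trajectory()] to backmap.
#' @param checkpoint a `cvae_checkpoint` (or `cvae_model`).
#' @param prior a [fit_latent_prior()] result; `NULL` falls back to
#'   the standard-normal prior.
#' @param seed_frame atomistic [frame()] standing in for the frame
#'   before the first CG frame (see [select_seed_frame()]).
#' @param seed integer seed for the latent draws.
#' @param decoder optional override of the decoder core, a
#'   `function(z, cg_coords, prev_coords)` returning N x 3 coordinates
#'   in the centered condition frame; used for diagnostics (e.g. an
#'   echo decoder proving the autoregressive wiring).
#' @return Atomistic [trajectory()] of the same length as `cg_traj`.
#' @export
backmap_trajectory <- function(cg_traj, checkpoint, prior = NULL,
                               seed_frame, seed = 1L, decoder = NULL) {
  model <- .as_cvae_model(checkpoint)
  config <- model$config
  stopifnot(inherits(cg_traj, "trajectory"))
  if (n_particles(cg_traj) != config$n_beads)
    stop("CG trajectory bead count does not match the model", call. = FALSE)
  P <- .coords(seed_frame)
  if (nrow(P) != config$n_atoms)
    stop("seed frame must have N = ", config$n_atoms, " atoms",
         call. = FALSE)
  set.seed(seed)
  Tn <- n_frames(cg_traj)
  Z <- if (is.null(prior)) matrix(rnorm(Tn * config$d_latent), Tn)
       else sample_latent_prior(prior, Tn)
  out <- array(0, dim = c(Tn, config$n_atoms, 3L))
  spec <- config$grid
  for (t in seq_len(Tn)) {
    G <- cg_traj$coords[t, , , drop = TRUE]
    if (config$n_beads == 1L) G <- matrix(G, 1L, 3L)
    cen <- colMeans(G)
    Gc <- sweep(G, 2L, cen); Pc <- sweep(P, 2L, cen)
    margin <- spec$r_grid - 3 * spec$sigma
    if (max(abs(c(Gc, Pc))) > margin)
      stop("enclosure violation at frame ", t,
           ": condition extends beyond the voxel grid", call. = FALSE)
    Xc <- if (is.null(decoder)) {
      Gr <- .readout_coords(Gc, spec)
      Pr <- .readout_coords(Pc, spec)
      Xp <- .decode_coords(model$params, config, Z[t, ], Gr, Pr)
      .readout_coords(Xp, spec)   # devoxelize(voxelize(Xp)), separable
    } else decoder(Z[t, ], Gc, Pc)
    X <- sweep(Xc, 2L, cen, "+")
    out[t, , ] <- X
    P <- X
  }
  trajectory(out, particle_ids = seed_frame$particle_ids %||%
               paste0("p", seq_len(config$n_atoms)),
             dt = cg_traj$dt)
}

#' Posterior latent codes of a dataset
#'
#' Runs the encoder over (a subset of) the dataset and returns the
#' posterior means, the summary statistics the ex-post prior is fitted
#' on.
#'
#' @param model a `cvae_model` or checkpoint.
#' @param dataset a [build_dataset()] result.
#' @param indices optional subset of sample indices.
#' @return Matrix (samples x d_latent) of posterior means.
#' @export
posterior_codes <- function(model, dataset, indices = NULL) {
  model <- .as_cvae_model(model)
  config <- model$config
  if (is.null(indices)) indices <- seq_len(nrow(dataset$index))
  out <- matrix(0, length(indices), config$d_latent)
  spec <- config$grid
  map_idx <- attr(config, "map_idx") %||% dataset$mapping$atom_indices
  Wb <- .interp_weights(map_idx, config$n_atoms)
  for (j in seq_along(indices)) {
    s <- get_sample(dataset, indices[j])
    cen <- colMeans(s$cg_t$coords)
    Yr <- .readout_coords(sweep(s$aa_t$coords, 2L, cen), spec)
    Gr <- .readout_coords(sweep(s$cg_t$coords, 2L, cen), spec)
    Pr <- .readout_coords(sweep(s$aa_prev$coords, 2L, cen), spec)
    base <- .decoder_base(Pr, Gr, map_idx, Wb)
    fe <- .mlp_forward(model$params$enc,
                       .enc_features(Yr, Gr, Pr, spec, base))
    out[j, ] <- drop(model$params$enc$W_mu %*% fe$h) + model$params$enc$b_mu
  }
  out
}
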