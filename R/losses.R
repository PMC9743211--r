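#' Composite reconstruction losses
#'
#' The training objective for one sample is the sum of five
#' reconstruction terms and a KL regularizer:
#' `voxel + coord + cg + edm + lambda * energy + beta * kl`.
#' Every mean-squared-error term averages over all of its entries
#' (voxels: all `N d^3` values; coordinates: all `3N` entries; CG
#' consistency: all `3n` entries; EDM: all `N^2` pairwise-distance
#' entries including the zero diagonal and both orderings of each
#' pair); the energy term is the squared difference of the two scalar
#' potential energies.
#'
#' @param target_frame,recon_frame atomistic [frame()]s (target and
#'   reconstruction), matching particle order.
#' @param target_grid,recon_grid matching `density_grid`s (may be
#'   `NULL` to skip the voxel term, e.g. for quick diagnostics).
#' @param cg_frame the conditioning CG frame.
#' @param mapping the [cg_mapping()] tying atoms to beads.
#' @param target_energy,recon_energy scalar potential energies of the
#'   two frames, from the same energy model.
#' @return Named list with `voxel_mse`, `coord_mse`, `cg_mse`,
#'   `edm_mse`, `energy_mse`.
#' @export
reconstruction_losses <- function(target_frame, recon_frame, cg_frame,
                                  mapping, target_grid = NULL,
                                  recon_grid = NULL,
                                  target_energy = 0, recon_energy = 0) {
  Y <- .coords(target_frame); X <- .coords(recon_frame)
  if (!all(dim(Y) == dim(X)))
    stop("target and reconstruction particle counts differ", call. = FALSE)
  G <- .coords(cg_frame)
  if (nrow(G) != n_beads(mapping))
    stop("CG frame does not match the mapping's bead count", call. = FALSE)
  voxel_mse <- if (is.null(target_grid) || is.null(recon_grid)) 0 else {
    if (!all(dim(target_grid$values) == dim(recon_grid$values)))
      stop("grid dimensions differ", call. = FALSE)
    mean((recon_grid$values - target_grid$values)^2)
  }
  coord_mse <- mean((X - Y)^2)
  cg_mse <- mean((X[mapping$atom_indices, , drop = FALSE] - G)^2)
  DY <- as.matrix(dist(Y)); DX <- as.matrix(dist(X))
  edm_mse <- mean((DX - DY)^2)
  energy_mse <- (recon_energy - target_energy)^2
  list(voxel_mse = voxel_mse, coord_mse = coord_mse, cg_mse = cg_mse,
       edm_mse = edm_mse, energy_mse = energy_mse)
}

#' Kullback-Leibler divergence of a diagonal Gaussian from N(0, I)
#'
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`; zero iff the
#' posterior equals the standard normal.
#'
#' @param mean,log_variance numeric vectors of equal length (the
#'   posterior parameters), or a `latent_distribution` as `mean`.
#' @return Nonnegative scalar.
#' @examples
#' kl_loss(1, 0)        # 0.5
#' kl_loss(0, log(4))   # 0.5 * (4 - 1 - log 4)
#' @export
kl_loss <- function(mean, log_variance = NULL) {
  if (inherits(mean, "latent_distribution")) {
    log_variance <- mean$log_variance
    mean <- mean$mean
  }
  if (length(mean) != length(log_variance))
    stop("`mean` and `log_variance` lengths differ", call. = FALSE)
  0.5 * sum(mean^2 + exp(log_variance) - 1 - log_variance)
}

#' Assemble the total training loss
#'
#' @param losses list of reconstruction terms as returned by
#'   [reconstruction_losses()].
#' @param kl KL divergence of the sample's posterior.
#' @param step training step (0-based) used to evaluate the schedules;
#'   ignored when `lambda`/`beta` are supplied directly.
#' @param lambda,beta explicit prefactors; by default taken from
#'   [lambda_schedule()] and [beta_schedule()] with the supplied
#'   schedule parameter lists.
#' @param lambda_args,beta_args named argument lists for the schedules.
#' @param weights optional named per-term weights (default 1 for every
#'   reconstruction term).
#' @return Object of class `loss_breakdown`: the five terms, `kl`,
#'   `lambda_t`, `beta_t` and `total`.
#' @export
total_loss <- function(losses, kl, step = 0L, lambda = NULL, beta = NULL,
                       lambda_args = list(), beta_args = list(),
                       weights = NULL) {
  w <- list(voxel_mse = 1, coord_mse = 1, cg_mse = 1, edm_mse = 1,
            energy_mse = 1)
  if (!is.null(weights)) w[names(weights)] <- weights
  if (is.null(lambda))
    lambda <- do.call(lambda_schedule, c(list(step = step), lambda_args))
  if (is.null(beta))
    beta <- do.call(beta_schedule, c(list(step = step), beta_args))
  total <- w$voxel_mse * losses$voxel_mse + w$coord_mse * losses$coord_mse +
    w$cg_mse * losses$cg_mse + w$edm_mse * losses$edm_mse +
    lambda * w$energy_mse * losses$energy_mse + beta * kl
  structure(c(losses, list(kl = kl, lambda_t = lambda, beta_t = beta,
                           total = total)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown> total =", signif(x$total, 6), "\n")
  terms <- c("voxel_mse", "coord_mse", "cg_mse", "edm_mse", "energy_mse",
             "kl")
  for (t in terms) cat(sprintf("  %-10s %g\n", t, x[[t]]))
  cat(sprintf("  lambda = %g, beta = %g\n", x$lambda_t, x$beta_t))
  invisible(x)
}

#' Exponential warm-up schedule for the energy-loss prefactor
#'
#' `lambda = 0` for `step < warmup` (so the energy term cannot dominate
#' before the model localizes atoms stably), then
#' `1 - exp(-rate * (step - warmup))`, rising monotonically to 1.
#'
#' @param step training step (0-based, >= 0).
#' @param warmup number of initial steps with lambda = 0.
#' @param rate exponential annealing rate per step (> 0).
#' @return `lambda` in `[0, 1]`.
#' @export
lambda_schedule <- function(step, warmup = 1000L, rate = 1e-3) {
  stopifnot(step >= 0, rate > 0)
  if (step < warmup) 0 else 1 - exp(-rate * (step - warmup))
}

#' Constant or cyclic annealing schedule for the KL prefactor
#'
#' `"constant"` keeps `beta = 1` throughout training; `"cyclic"`
#' mitigates KL vanishing by ramping `beta` linearly from 0 to
#' `beta_max` over the first half of each cycle of `period` steps and
#' holding it at `beta_max` for the second half, exactly periodic in
#' `period`.
#'
#' @param step training step (0-based).
#' @param mode `"constant"` or `"cyclic"`.
#' @param period cycle length in steps (cyclic mode).
#' @param beta_max plateau value (cyclic mode).
#' @return `beta`.
#' @export
beta_schedule <- function(step, mode = c("constant", "cyclic"),
                          period = 1000L, beta_max = 1) {
  mode <- match.arg(mode)
  stopifnot(step >= 0)
  if (mode == "constant") return(1)
  phase <- (step %% period) / period
  if (phase < 0.5) beta_max * phase / 0.5 else beta_max
}

#' Draw a rotation matrix uniformly from SO(3)
#'
#' Uniformity on the rotation group is obtained from a random unit
#' quaternion (four iid standard normals, normalized); naive uniform
#' Euler angles would oversample the poles and are deliberately not
#' used.  The same matrix is applied jointly to all three frames of a
#' training triplet so their relative geometry is preserved.
#'
#' @param seed optional integer seed.
#' @return 3 x 3 rotation matrix with `R'R = I`, `det R = 1`.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}
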