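#' Assemble training triplets from atomistic trajectories
#'
#' One training sample per frame `t >= 2` of each trajectory: the
#' current atomistic frame `AA^t`, its CG projection
#' `CG^t = apply_mapping(mapping, AA^t)`, and the previous atomistic
#' frame `AA^{t-1}`.  Samples never span a trajectory boundary;
#' single-frame trajectories are skipped with a warning.
#'
#' @param trajectories a [trajectory()] or list of trajectories with a
#'   common particle order.
#' @param mapping a [cg_mapping()].
#' @return Object of class `backmap_dataset`: the trajectories, the
#'   mapping and an index of (trajectory, frame) pairs.
#' @export
build_dataset <- function(trajectories, mapping) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L, inherits(mapping, "cg_mapping"))
  idx_tr <- integer(); idx_t <- integer()
  for (k in seq_along(trajectories)) {
    Tk <- n_frames(trajectories[[k]])
    if (Tk < 2L) {
      warning("trajectory ", k, " has fewer than 2 frames; skipped",
              call. = FALSE)
      next
    }
    idx_tr <- c(idx_tr, rep.int(k, Tk - 1L))
    idx_t <- c(idx_t, seq.int(2L, Tk))
  }
  if (!length(idx_tr))
    stop("no usable trajectories (all have < 2 frames)", call. = FALSE)
  structure(list(trajectories = trajectories, mapping = mapping,
                 index = data.frame(traj = idx_tr, t = idx_t)),
            class = "backmap_dataset")
}

#' @export
print.backmap_dataset <- function(x, ...) {
  cat("<backmap_dataset> ", nrow(x$index), " samples from ",
      length(x$trajectories), " trajectories\n", sep = "")
  invisible(x)
}

#' @rdname build_dataset
#' @param dataset a `backmap_dataset`.
#' @param i sample number.
#' @return `get_sample()` returns a list with frames `aa_t`, `cg_t`,
#'   `aa_prev` plus the source trajectory id and frame index.
#' @export
get_sample <- function(dataset, i) {
  row <- dataset$index[i, ]
  tr <- dataset$trajectories[[row$traj]]
  aa_t <- get_frame(tr, row$t)
  list(aa_t = aa_t,
       cg_t = apply_mapping(dataset$mapping, aa_t),
       aa_prev = get_frame(tr, row$t - 1L),
       traj = row$traj, t = row$t)
}

#' @rdname build_dataset
#' @param ids vector of trajectory identifiers.
#' @param n_train number assigned to training; the rest are the test
#'   split (e.g. 3744 identifiers with 3650 for training leave 94 for
#'   testing).
#' @param seed optional seed for the random assignment.
#' @return `split_trajectories()` returns `list(train =, test =)`.
#' @export
split_trajectories <- function(ids, n_train, seed = NULL) {
  if (n_train > length(ids))
    stop("`n_train` exceeds the number of identifiers", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- sort(sample(seq_along(ids), n_train))
  list(train = ids[tr], test = ids[setdiff(seq_along(ids), tr)])
}

#' Training-loop settings
#'
#' @param steps optimizer steps.
#' @param batch_size samples per step.
#' @param lr ADAM learning rate.
#' @param lambda_warmup,lambda_rate energy-term schedule, see
#'   [lambda_schedule()].
#' @param beta_mode,beta_period,beta_max KL schedule, see
#'   [beta_schedule()].
#' @param rotate apply a shared random rotation to each sample triplet.
#' @param condition_noise sd (A) of isotropic Gaussian noise added to
#'   the previous-frame condition during training.  At inference the
#'   previous frame is the model's own imperfect reconstruction, so
#'   training against noised conditions teaches the decoder to
#'   contract condition errors instead of propagating them through the
#'   autoregressive rollout; choose it comparable to the per-frame
#'   innovation displacement.  0 disables the augmentation.
#' @param condition_shuffle probability of replacing a sample's
#'   previous-frame condition with a random other frame of the same
#'   trajectory (re-centered on its own CG centroid).  This condition
#'   dropout teaches the decoder to rebuild the atomistic geometry from
#'   the CG frame alone when the temporal condition is unreliable — the
#'   situation at rollout seeding and after rare state transitions —
#'   which bounds error propagation in autoregressive inference.
#' @param rollout_fraction scheduled-sampling rate: maximum probability
#'   of building a sample's previous-frame condition by rolling the
#'   current model itself autoregressively for a random number of
#'   steps (up to `rollout_depth`) from an earlier true frame, using
#'   the true CG frames along the way (no gradient through those
#'   steps).  The probability ramps linearly from 0 to this value over
#'   the first half of training.  This exposes the decoder to its own
#'   compounded error distribution — the conditions it actually faces
#'   during autoregressive rollout — and trains it to contract those
#'   errors back onto the data manifold.
#' @param rollout_depth maximum depth of the scheduled-sampling
#'   self-rollout.
#' @param weights optional per-term loss weights.
#' @param log_every record a loss row every this many steps.
#' @param checkpoint_every,checkpoint_dir optional periodic checkpoint
#'   writing.
#' @return List of class `train_control`.
#' @export
train_control <- function(steps = 2000L, batch_size = 16L, lr = 1e-3,
                          lambda_warmup = 500L, lambda_rate = 2e-3,
                          beta_mode = "cyclic", beta_period = 500L,
                          beta_max = 1, rotate = TRUE,
                          condition_noise = 0.1, condition_shuffle = 0.1,
                          rollout_fraction = 0, rollout_depth = 8L,
                          weights = NULL,
                          log_every = 25L, checkpoint_every = NULL,
                          checkpoint_dir = NULL) {
  structure(list(steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 lambda_warmup = as.integer(lambda_warmup),
                 lambda_rate = lambda_rate, beta_mode = beta_mode,
                 beta_period = as.integer(beta_period),
                 beta_max = beta_max, rotate = isTRUE(rotate),
                 condition_noise = condition_noise,
                 condition_shuffle = condition_shuffle,
                 rollout_fraction = rollout_fraction,
                 rollout_depth = as.integer(rollout_depth),
                 weights = weights, log_every = as.integer(log_every),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "train_control")
}

#' Train the conditional VAE end-to-end
#'
#' Per step: sample a batch; center each triplet by the centroid of its
#' CG frame (applied identically to all three frames); optionally apply
#' one shared random rotation per sample; run the encoder,
#' reparameterize, decode, and accumulate analytic gradients of the
#' composite loss; update parameters with ADAM.  Per-term losses are
#' logged; a non-finite loss aborts with the offending term and step.
#'
#' @param dataset a [build_dataset()] result.
#' @param config a [model_config()] (atom/bead counts must match the
#'   dataset).
#' @param forcefield [toy_forcefield()] used for the energy term (or
#'   `NULL` to drop it); any scalar energy model exposed through
#'   `energy_fn(coords) -> kJ/mol` may be substituted via `energy_fn`.
#' @param control a [train_control()].
#' @param seed integer seed governing initialization, batch order,
#'   rotations and latent noise.
#' @param energy_fn optional function overriding `forcefield` for
#'   target energies (reconstruction energies still need `forcefield`
#'   gradients, so supplying only `energy_fn` disables the term's
#'   gradient).
#' @param init optional `cvae_model` to continue training from.
#' @return Object of class `cvae_checkpoint`: the trained `model`, the
#'   training `log` (data.frame), the control settings and the seed.
#' @export
train_model <- function(dataset, config, forcefield = NULL,
                        control = train_control(), seed = 1L,
                        energy_fn = NULL, init = NULL) {
  stopifnot(inherits(dataset, "backmap_dataset"),
            inherits(config, "model_config"))
  n_at <- n_particles(dataset$trajectories[[1L]])
  if (config$n_atoms != n_at)
    stop("config has N = ", config$n_atoms, " but trajectories have ",
         n_at, " atoms", call. = FALSE)
  if (config$n_beads != n_beads(dataset$mapping))
    stop("config bead count does not match the mapping", call. = FALSE)
  attr(config, "map_idx") <- dataset$mapping$atom_indices
  set.seed(seed)
  model <- if (is.null(init)) cvae_init(config) else init
  params <- model$params
  skeleton <- params
  theta <- .flatten_params(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  nS <- nrow(dataset$index)
  log_rows <- list()
  use_ff <- if (is.null(forcefield)) NULL else forcefield
  efn <- if (!is.null(energy_fn)) energy_fn
         else if (!is.null(use_ff))
           function(X) .ff_energy_cpp(X, unclass(use_ff))
         else NULL

  for (step in seq_len(control$steps) - 1L) {
    lam <- lambda_schedule(step, control$lambda_warmup, control$lambda_rate)
    if (is.null(efn)) lam <- 0
    bet <- beta_schedule(step, control$beta_mode, control$beta_period,
                         control$beta_max)
    batch <- sample.int(nS, min(control$batch_size, nS))
    grad <- NULL
    terms <- c(voxel_mse = 0, coord_mse = 0, cg_mse = 0, edm_mse = 0,
               energy_mse = 0, kl = 0, total = 0)
    for (b in batch) {
      s <- get_sample(dataset, b)
      cen <- colMeans(s$cg_t$coords)
      Y <- sweep(s$aa_t$coords, 2L, cen)
      G <- sweep(s$cg_t$coords, 2L, cen)
      u_aug <- runif(1L)
      p_roll <- if (control$rollout_fraction > 0 && s$t >= 3L)
        control$rollout_fraction *
          min(1, step / max(1L, control$steps %/% 2L)) else 0
      P <- if (u_aug < control$condition_shuffle) {
        tr_b <- dataset$trajectories[[s$traj]]
        alt <- tr_b$coords[sample.int(n_frames(tr_b), 1L), , ,
                           drop = TRUE]
        sweep(alt, 2L,
              colMeans(alt[dataset$mapping$atom_indices, , drop = FALSE]))
      } else if (u_aug < control$condition_shuffle + p_roll) {
        # scheduled sampling: roll the current model j steps from an
        # earlier true frame, driven by the true CG frames, and use
        # the final self-generated frame as the condition
        tr_b <- dataset$trajectories[[s$traj]]
        j <- sample.int(min(control$rollout_depth, s$t - 2L), 1L)
        P_abs <- tr_b$coords[s$t - j - 1L, , , drop = TRUE]
        midx <- dataset$mapping$atom_indices
        for (tt in (s$t - j):(s$t - 1L)) {
          Gt <- tr_b$coords[tt, midx, , drop = TRUE]
          if (is.null(dim(Gt))) Gt <- matrix(Gt, 1L, 3L)
          cent <- colMeans(Gt)
          Phat <- .decode_coords(params, config, rnorm(config$d_latent),
                                 .readout_coords(sweep(Gt, 2L, cent),
                                                 config$grid),
                                 .readout_coords(sweep(P_abs, 2L, cent),
                                                 config$grid))
          P_abs <- sweep(Phat, 2L, cent, "+")
        }
        sweep(P_abs, 2L, cen)
      } else sweep(s$aa_prev$coords, 2L, cen)
      if (control$rotate) {
        R <- random_rotation()
        Y <- Y %*% R; G <- G %*% R; P <- P %*% R
      }
      if (control$condition_noise > 0)
        P <- P + matrix(rnorm(length(P), 0, control$condition_noise),
                        nrow(P), 3L)
      epsv <- rnorm(config$d_latent)
      U_t <- if (!is.null(efn)) efn(Y) else NULL
      fw <- .cvae_forward(params, config, Y, G, P, epsv, lam, bet,
                          ff = if (lam > 0) use_ff else NULL,
                          target_energy = U_t,
                          weights = control$weights)
      for (nm in names(terms)) terms[nm] <- terms[nm] + fw$losses[[nm]]
      g <- .cvae_backward(params, config, fw)
      gf <- .flatten_params(g)
      grad <- if (is.null(grad)) gf else grad + gf
    }
    nb <- length(batch)
    grad <- grad / nb
    terms <- terms / nb
    bad <- names(terms)[!is.finite(terms)]
    if (length(bad))
      stop("non-finite loss term '", bad[1L], "' at step ", step,
           call. = FALSE)
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mhat <- m / (1 - b1^(step + 1)); vhat <- v / (1 - b2^(step + 1))
    theta <- theta - control$lr * mhat / (sqrt(vhat) + eps_adam)
    params <- .relist_params(theta, skeleton)
    if (step %% control$log_every == 0L || step == control$steps - 1L)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, lambda = lam, beta = bet, t(terms))
    if (!is.null(control$checkpoint_every) &&
        (step + 1L) %% control$checkpoint_every == 0L &&
        !is.null(control$checkpoint_dir)) {
      dir.create(control$checkpoint_dir, showWarnings = FALSE,
                 recursive = TRUE)
      save_checkpoint(
        .make_checkpoint(params, config, do.call(rbind, log_rows),
                         control, seed, dataset$mapping),
        file.path(control$checkpoint_dir,
                  sprintf("checkpoint_%06d.rds", step + 1L)))
    }
  }
  .make_checkpoint(params, config, do.call(rbind, log_rows), control,
                   seed, dataset$mapping)
}

.make_checkpoint <- function(params, config, log, control, seed,
                             mapping) {
  structure(list(model = structure(list(params = params, config = config),
                                   class = "cvae_model"),
                 log = log, control = control, seed = seed,
                 mapping = mapping, grid = config$grid),
            class = "cvae_checkpoint")
}

#' @export
print.cvae_checkpoint <- function(x, ...) {
  cat("<cvae_checkpoint> trained ", max(x$log$step) + 1L, " steps; ",
      "final total loss = ", signif(tail(x$log$total, 1L), 5), "\n",
      sep = "")
  invisible(x)
}

#' Save or load a self-describing model checkpoint
#'
#' The checkpoint bundles parameters, model configuration, grid
#' specification, CG mapping and the training log, so inference needs
#' no external context.
#'
#' @param checkpoint a `cvae_checkpoint`.
#' @param path file path.
#' @return `path` invisibly; `load_checkpoint()` returns the
#'   checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "cvae_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "cvae_checkpoint"))
  ck
}

#' Mean total loss of a model over a dataset (no gradient updates)
#'
#' Deterministic given `seed`; used for held-out monitoring and
#' checkpoint round-trip checks.
#'
#' @inheritParams train_model
#' @param model a `cvae_model` or checkpoint.
#' @param lambda,beta loss prefactors.
#' @param indices optional subset of sample indices.
#' @param seed seed for the latent noise.
#' @return Mean total loss.
#' @export
evaluate_loss <- function(model, dataset, forcefield = NULL, lambda = 0,
                          beta = 1, indices = NULL, seed = 1L) {
  model <- .as_cvae_model(model)
  config <- model$config
  attr(config, "map_idx") <- dataset$mapping$atom_indices
  if (is.null(indices)) indices <- seq_len(nrow(dataset$index))
  set.seed(seed)
  tot <- 0
  for (i in indices) {
    s <- get_sample(dataset, i)
    cen <- colMeans(s$cg_t$coords)
    fw <- .cvae_forward(model$params, config,
                        sweep(s$aa_t$coords, 2L, cen),
                        sweep(s$cg_t$coords, 2L, cen),
                        sweep(s$aa_prev$coords, 2L, cen),
                        rnorm(config$d_latent), lambda, beta,
                        ff = if (lambda > 0) forcefield else NULL,
                        target_energy = if (!is.null(forcefield))
                          potential_energy(forcefield, s$aa_t) else NULL)
    tot <- tot + fw$losses$total
  }
  tot / length(indices)
}

#' Reference training settings for the benchmark toy systems
#'
#' The settings used by the package's own end-to-end checks on the
#' [make_benchmark_system()] presets: cyclic KL annealing with
#' `beta_max = 0.03` (keeps the latent code at a few nats — active
#' enough to supply per-step conformational sampling, constrained
#' enough not to duplicate what the condition determines), the energy
#' term rescaled to be commensurate with the other reconstruction
#' terms, and all three exposure-bias augmentations enabled.  The
#' energy warm-up ends at 40% of the step budget.
#'
#' @param steps optimizer steps.
#' @param ... overrides forwarded to [train_control()].
#' @return A [train_control()] object.
#' @export
toy_train_control <- function(steps = 12000L, ...) {
  args <- modifyList(
    list(steps = as.integer(steps), batch_size = 16L, lr = 1e-3,
         beta_mode = "cyclic", beta_period = 500L, beta_max = 0.03,
         condition_noise = 0.1, condition_shuffle = 0.1,
         rollout_fraction = 0.3, rollout_depth = 12L,
         lambda_warmup = as.integer(steps * 0.4), lambda_rate = 1e-3,
         weights = list(energy_mse = 1e-3), log_every = 200L),
    list(...))
  do.call(train_control, args)
}
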