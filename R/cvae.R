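#' Conditional VAE model configuration
#'
#' The encoder maps the voxelized triplet (current atomistic frame,
#' current CG frame, previous atomistic frame) to a diagonal-Gaussian
#' latent posterior; the decoder maps a latent code plus the voxelized
#' condition (CG frame and previous atomistic frame) back to an
#' atomistic density grid and its devoxelized coordinates.
#'
#' Both networks first collapse each density channel to its
#' density-weighted centroid (the same weighted average that
#' [devoxelize()] performs) and then run a stack of fully connected
#' residual blocks on the flattened centroid coordinates.  The decoder
#' predicts per-atom displacements relative to the previous-frame
#' channel centroids and re-renders the displaced atoms as peak-1
#' Gaussians on the lattice, which keeps every operation smooth and
#' makes the whole pipeline differentiable end-to-end.  All widths are
#' configurable.
#'
#' @param n_atoms atomistic particle count N.
#' @param n_beads CG bead count n.
#' @param grid a [grid_spec()] shared by every channel.
#' @param d_latent latent dimensionality.
#' @param hidden width of the dense residual blocks.
#' @param n_blocks residual blocks per network.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_atoms, n_beads, grid, d_latent = 16L,
                         hidden = 64L, n_blocks = 2L) {
  stopifnot(inherits(grid, "grid_spec"))
  cfg <- list(n_atoms = as.integer(n_atoms), n_beads = as.integer(n_beads),
              grid = grid, d_latent = as.integer(d_latent),
              hidden = as.integer(hidden), n_blocks = as.integer(n_blocks))
  with(cfg, stopifnot(n_atoms >= 1L, n_beads >= 1L, d_latent >= 1L,
                      hidden >= 1L, n_blocks >= 0L))
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> N = ", x$n_atoms, ", n = ", x$n_beads,
      ", d_latent = ", x$d_latent, ", hidden = ", x$hidden, " x ",
      x$n_blocks, " blocks, grid d = ", x$grid$d, "\n", sep = "")
  invisible(x)
}

#' Initialize a conditional VAE model
#'
#' Weights use scaled-Gaussian (Xavier-style) initialization; the
#' decoder output layer starts near zero so the initial model
#' reproduces the previous-frame condition, a stable starting point for
#' the autoregressive task.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed.
#' @return Object of class `cvae_model` holding `params` and `config`.
#' @export
cvae_init <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_atoms; n <- config$n_beads
  H <- config$hidden; L <- config$d_latent
  # inputs: centroid coordinates plus per-frame pairwise distances
  E <- 3L * (2L * N + n) + 2L * .n_pairs(N) + .n_pairs(n)
  Dm <- L + 3L * (N + n) + .n_pairs(N) + .n_pairs(n)
  mk <- function(nr, nc, scale = sqrt(1 / nc))
    matrix(rnorm(nr * nc, sd = scale), nr, nc)
  mlp <- function(nin) {
    list(W_in = mk(H, nin), b_in = numeric(H),
         blocks = lapply(seq_len(config$n_blocks), function(k)
           list(W = mk(H, H, sqrt(1 / H) / config$n_blocks), b = numeric(H))))
  }
  params <- list(
    enc = c(mlp(E), list(W_mu = mk(L, H), b_mu = numeric(L),
                         W_lv = mk(L, H, 0.01), b_lv = numeric(L))),
    dec = c(mlp(Dm), list(W_out = mk(3L * N, H, 1e-3),
                          b_out = numeric(3L * N))))
  structure(list(params = params, config = config), class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  np <- length(unlist(x$params))
  cat("<cvae_model> ", np, " parameters\n", sep = "")
  print(x$config)
  invisible(x)
}

## ---- dense residual MLP ----------------------------------------------

.mlp_forward <- function(p, x) {
  a0 <- drop(p$W_in %*% x) + p$b_in
  h <- tanh(a0)
  hs <- list(h); as <- list()
  for (blk in p$blocks) {
    a <- drop(blk$W %*% h) + blk$b
    h <- h + tanh(a)
    as[[length(as) + 1L]] <- a
    hs[[length(hs) + 1L]] <- h
  }
  list(h = h, cache = list(x = x, a0 = a0, hs = hs, as = as))
}

.mlp_backward <- function(p, cache, g_h) {
  K <- length(p$blocks)
  gblocks <- vector("list", K)
  for (k in rev(seq_len(K))) {
    tk <- tanh(cache$as[[k]])
    g_a <- g_h * (1 - tk^2)
    gblocks[[k]] <- list(W = outer(g_a, cache$hs[[k]]), b = g_a)
    g_h <- g_h + drop(crossprod(p$blocks[[k]]$W, g_a))
  }
  h0 <- tanh(cache$a0)
  g_a0 <- g_h * (1 - h0^2)
  list(W_in = outer(g_a0, cache$x), b_in = g_a0, blocks = gblocks,
       g_x = drop(crossprod(p$W_in, g_a0)))
}

## ---- feature construction --------------------------------------------

# MLP inputs are centroid coordinates divided by r_grid so they land in
# roughly [-1, 1] (keeping the tanh units out of saturation), augmented
# with the rigid-motion-invariant pairwise distances of each frame:
# bond-scale geometry and the bead separations that signal torsional
# state are then directly visible to the network instead of having to
# be synthesized from raw coordinates.
#
# The encoder sees the *residual* of the target relative to the
# bead-anchored base configuration (and residual pairwise distances),
# not the raw target: everything the condition already determines is
# subtracted out, so the latent code is structurally limited to
# innovation-scale information and cannot smuggle the slow
# conformational state past the condition.  Residuals are Angstrom
# scale, hence their own feature scaling.
.RES_SCALE <- 2  # 1 / (0.5 A): typical innovation residual to ~[-1, 1]
.pdist <- function(X) if (nrow(X) > 1L) as.vector(dist(X)) else numeric()
.enc_features <- function(Yr, Gr, Pr, spec, base) {
  c(as.vector(t(Yr - base)) * .RES_SCALE,
    c(as.vector(t(Gr)), as.vector(t(Pr))) / spec$r_grid,
    (.pdist(Yr) - .pdist(Pr)) * .RES_SCALE,
    c(.pdist(Gr), .pdist(Pr)) / spec$r_grid)
}
.dec_input <- function(z, Gr, Pr, spec) {
  c(z, c(as.vector(t(Gr)), as.vector(t(Pr)), .pdist(Gr), .pdist(Pr)) /
      spec$r_grid)
}
.n_pairs <- function(m) (m * (m - 1L)) %/% 2L

# Interpolation weights distributing CG bead displacements over atoms
# by index position along the chain: mapped atoms follow their bead
# exactly; atoms between two mapped atoms blend the two displacements
# linearly; atoms outside the mapped range follow the nearest bead.
.interp_weights <- function(map_idx, N) {
  n <- length(map_idx)
  W <- matrix(0, N, n)
  ord <- order(map_idx)
  ms <- map_idx[ord]
  for (i in seq_len(N)) {
    if (i <= ms[1L]) {
      W[i, ord[1L]] <- 1
    } else if (i >= ms[n]) {
      W[i, ord[n]] <- 1
    } else {
      j <- max(which(ms <= i))
      t_ <- (i - ms[j]) / (ms[j + 1L] - ms[j])
      W[i, ord[j]] <- 1 - t_
      W[i, ord[j + 1L]] <- t_
    }
  }
  W
}

# Decoder base configuration: the previous frame shifted so that every
# mapped atom lands exactly on its current bead and intermediate atoms
# follow the interpolated bead displacement.  The network then only
# has to learn the residual inner-atom geometry, which keeps rollouts
# anchored to the CG trajectory by construction.
.decoder_base <- function(Pr, Gr, map_idx, W) {
  Pr + W %*% (Gr - Pr[map_idx, , drop = FALSE])
}

## ---- core forward / backward -----------------------------------------

# Forward pass on centered coordinates.  Y (N x 3) target, G (n x 3)
# CG condition, P (N x 3) previous frame; eps: latent noise (length L).
# Returns every intermediate needed for the analytic backward pass.
.cvae_forward <- function(params, config, Y, G, P, eps, lambda, beta,
                          ff = NULL, target_energy = NULL,
                          weights = NULL) {
  spec <- config$grid
  N <- config$n_atoms; n <- config$n_beads; L <- config$d_latent
  Yr <- .readout_coords(Y, spec)
  Gr <- .readout_coords(G, spec)
  Pr <- .readout_coords(P, spec)
  map_idx0 <- attr(config, "map_idx") %||% seq_len(n)
  Wb <- .interp_weights(map_idx0, N)
  base <- .decoder_base(Pr, Gr, map_idx0, Wb)
  e <- .enc_features(Yr, Gr, Pr, spec, base)
  fe <- .mlp_forward(params$enc, e)
  mu <- drop(params$enc$W_mu %*% fe$h) + params$enc$b_mu
  lv <- drop(params$enc$W_lv %*% fe$h) + params$enc$b_lv
  z <- mu + exp(lv / 2) * eps
  u <- .dec_input(z, Gr, Pr, spec)
  fd <- .mlp_forward(params$dec, u)
  delta <- drop(params$dec$W_out %*% fd$h) + params$dec$b_out
  Xp <- base + matrix(delta, N, 3L, byrow = TRUE)

  d3 <- spec$d^3
  rho <- vector("list", N); Zs <- numeric(N)
  ctx <- .grid_ctx(spec)
  X_out <- matrix(0, N, 3L)
  for (i in seq_len(N)) {
    rho[[i]] <- .channel_density(Xp[i, ], spec)
    Zs[i] <- sum(rho[[i]])
    if (!is.finite(Zs[i]) || Zs[i] <= 1e-300)
      stop("degenerate density: decoded atom ", i,
           " fell outside the grid", call. = FALSE)
    X_out[i, ] <- c(sum(rho[[i]] * ctx$AX), sum(rho[[i]] * ctx$AY),
                    sum(rho[[i]] * ctx$AZ)) / Zs[i]
  }
  rho_t <- lapply(seq_len(N), function(i) .channel_density(Y[i, ], spec))

  w <- list(voxel_mse = 1, coord_mse = 1, cg_mse = 1, edm_mse = 1,
            energy_mse = 1)
  if (!is.null(weights)) w[names(weights)] <- weights
  voxel_mse <- sum(vapply(seq_len(N),
                          function(i) sum((rho[[i]] - rho_t[[i]])^2),
                          0)) / (N * d3)
  coord_mse <- mean((X_out - Y)^2)
  map_idx <- map_idx0
  cg_mse <- mean((X_out[map_idx, , drop = FALSE] - G)^2)
  DY <- as.matrix(dist(Y)); DX <- as.matrix(dist(X_out))
  edm_mse <- mean((DX - DY)^2)
  U_rec <- if (!is.null(ff)) .ff_energy_cpp(X_out, unclass(ff)) else 0
  U_tgt <- if (!is.null(target_energy)) target_energy else 0
  energy_mse <- (U_rec - U_tgt)^2
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  total <- w$voxel_mse * voxel_mse + w$coord_mse * coord_mse +
    w$cg_mse * cg_mse + w$edm_mse * edm_mse +
    lambda * w$energy_mse * energy_mse + beta * kl
  list(e = e, fe = fe, mu = mu, lv = lv, eps = eps, z = z, u = u,
       fd = fd, Xp = Xp, Pr = Pr, Gr = Gr, rho = rho, rho_t = rho_t,
       Zs = Zs, X_out = X_out, DX = DX, DY = DY, Y = Y, G = G,
       U_rec = U_rec, U_tgt = U_tgt, lambda = lambda, beta = beta,
       w = w, ctx = ctx, map_idx = map_idx, ff = ff,
       losses = list(voxel_mse = voxel_mse, coord_mse = coord_mse,
                     cg_mse = cg_mse, edm_mse = edm_mse,
                     energy_mse = energy_mse, kl = kl, total = total))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic gradient of the total loss w.r.t. every parameter.
.cvae_backward <- function(params, config, fw) {
  N <- config$n_atoms; n <- config$n_beads; L <- config$d_latent
  spec <- config$grid; d3 <- spec$d^3
  w <- fw$w
  X <- fw$X_out; Y <- fw$Y

  # d total / d X_out
  G_X <- 2 * w$coord_mse * (X - Y) / (3 * N)
  G_X[fw$map_idx, ] <- G_X[fw$map_idx, , drop = FALSE] +
    2 * w$cg_mse * (X[fw$map_idx, , drop = FALSE] - fw$G) / (3 * n)
  if (w$edm_mse != 0 && N > 1L) {
    Ddiff <- fw$DX - fw$DY
    for (a in seq_len(N)) {
      idx <- setdiff(seq_len(N), a)
      dv <- X[rep(a, length(idx)), , drop = FALSE] - X[idx, , drop = FALSE]
      dn <- fw$DX[a, idx]
      ok <- dn > 1e-12
      if (any(ok))
        G_X[a, ] <- G_X[a, ] + (4 * w$edm_mse / N^2) *
          colSums(Ddiff[a, idx][ok] * dv[ok, , drop = FALSE] / dn[ok])
    }
  }
  if (fw$lambda != 0 && !is.null(fw$ff)) {
    Frc <- .ff_forces_cpp(X, unclass(fw$ff))
    G_X <- G_X + 2 * fw$lambda * fw$w$energy_mse *
      (fw$U_rec - fw$U_tgt) * (-Frc)
  }

  # through devoxelize and the Gaussian rendering to predicted coords
  G_Xp <- matrix(0, N, 3L)
  ctx <- fw$ctx
  for (i in seq_len(N)) {
    g_rho <- 2 * w$voxel_mse * (fw$rho[[i]] - fw$rho_t[[i]]) / (N * d3)
    g_rho <- g_rho +
      (G_X[i, 1L] * (ctx$AX - X[i, 1L]) +
       G_X[i, 2L] * (ctx$AY - X[i, 2L]) +
       G_X[i, 3L] * (ctx$AZ - X[i, 3L])) / fw$Zs[i]
    rr <- fw$rho[[i]] * g_rho
    G_Xp[i, ] <- c(sum(rr * (ctx$AX - fw$Xp[i, 1L])),
                   sum(rr * (ctx$AY - fw$Xp[i, 2L])),
                   sum(rr * (ctx$AZ - fw$Xp[i, 3L]))) / spec$sigma^2
  }

  g_delta <- as.vector(t(G_Xp))
  g_dec_out_W <- outer(g_delta, fw$fd$h)
  g_dec_h <- drop(crossprod(params$dec$W_out, g_delta))
  bd <- .mlp_backward(params$dec, fw$fd$cache, g_dec_h)
  g_z <- bd$g_x[seq_len(L)]

  g_mu <- g_z + fw$beta * fw$mu
  g_lv <- g_z * fw$eps * exp(fw$lv / 2) / 2 +
    fw$beta * 0.5 * (exp(fw$lv) - 1)
  g_enc_h <- drop(crossprod(params$enc$W_mu, g_mu)) +
    drop(crossprod(params$enc$W_lv, g_lv))
  be <- .mlp_backward(params$enc, fw$fe$cache, g_enc_h)

  list(enc = list(W_in = be$W_in, b_in = be$b_in, blocks = be$blocks,
                  W_mu = outer(g_mu, fw$fe$h), b_mu = g_mu,
                  W_lv = outer(g_lv, fw$fe$h), b_lv = g_lv),
       dec = list(W_in = bd$W_in, b_in = bd$b_in, blocks = bd$blocks,
                  W_out = g_dec_out_W, b_out = g_delta))
}

## ---- public operations -----------------------------------------------

#' Encode a voxelized training triplet
#'
#' The input stack concatenates, along the channel dimension, the
#' voxelized current atomistic frame (N channels), current CG frame
#' (n channels) and previous atomistic frame (N channels), all sharing
#' one [grid_spec()].  Deterministic for fixed parameters.
#'
#' @param model a `cvae_model` (or a checkpoint containing one).
#' @param stack a `density_grid` with `2N + n` channels.
#' @return Object of class `latent_distribution` with `mean` and
#'   `log_variance` of length `d_latent`.
#' @export
encode <- function(model, stack) {
  model <- .as_cvae_model(model)
  config <- model$config
  N <- config$n_atoms; n <- config$n_beads
  nc <- dim(stack$values)[4L]
  if (nc != 2L * N + n)
    stop("encoder stack must have 2N + n = ", 2L * N + n,
         " channels, got ", nc, call. = FALSE)
  E <- devoxelize(stack)$coords
  Yr <- E[seq_len(N), , drop = FALSE]
  Gr <- E[N + seq_len(n), , drop = FALSE]
  Pr <- E[N + n + seq_len(N), , drop = FALSE]
  map_idx <- attr(config, "map_idx") %||% seq_len(n)
  base <- .decoder_base(Pr, Gr, map_idx, .interp_weights(map_idx, N))
  e <- .enc_features(Yr, Gr, Pr, config$grid, base)
  fe <- .mlp_forward(model$params$enc, e)
  structure(list(mean = drop(model$params$enc$W_mu %*% fe$h) +
                   model$params$enc$b_mu,
                 log_variance = drop(model$params$enc$W_lv %*% fe$h) +
                   model$params$enc$b_lv),
            class = "latent_distribution")
}

#' @export
print.latent_distribution <- function(x, ...) {
  cat("<latent_distribution> d_latent =", length(x$mean), "\n")
  invisible(x)
}

#' Sample a latent code by reparameterization
#'
#' `z = mean + exp(log_variance / 2) * eps` with `eps ~ N(0, I)` drawn
#' from R's RNG (seed-reproducible).
#'
#' @param dist a `latent_distribution`.
#' @param seed optional integer seed.
#' @param eps optional explicit noise vector (overrides sampling).
#' @return Numeric latent vector.
#' @export
reparameterize <- function(dist, seed = NULL, eps = NULL) {
  stopifnot(inherits(dist, "latent_distribution"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eps)) eps <- rnorm(length(dist$mean))
  dist$mean + exp(dist$log_variance / 2) * eps
}

#' Decode a latent code under a voxelized condition
#'
#' The condition stacks the voxelized CG frame (n channels) followed by
#' the voxelized previous atomistic frame (N channels).  The decoder
#' returns both the reconstructed atomistic density grid (N channels)
#' and its coordinates; the coordinate output is exactly
#' `devoxelize(grid)`.
#'
#' @param model a `cvae_model`.
#' @param z latent vector of length `d_latent`.
#' @param condition a `density_grid` with `N + n` channels (CG first).
#' @return List with `grid` (a `density_grid`) and `frame` (a
#'   [frame()] of N atoms).
#' @export
decode <- function(model, z, condition) {
  model <- .as_cvae_model(model)
  config <- model$config
  N <- config$n_atoms; n <- config$n_beads
  if (length(z) != config$d_latent)
    stop("`z` must have length d_latent = ", config$d_latent, call. = FALSE)
  nc <- dim(condition$values)[4L]
  if (nc != N + n)
    stop("condition must have N + n = ", N + n, " channels, got ", nc,
         call. = FALSE)
  C <- devoxelize(condition)$coords
  Gr <- C[seq_len(n), , drop = FALSE]
  Pr <- C[n + seq_len(N), , drop = FALSE]
  Xp <- .decode_coords(model$params, config, z, Gr, Pr)
  grid <- voxelize(frame(Xp), config$grid, strict = FALSE)
  frm <- devoxelize(grid)
  list(grid = grid, frame = frm)
}

# Decoder core on centroid coordinates (no grids).
.decode_coords <- function(params, config, z, Gr, Pr) {
  u <- .dec_input(z, Gr, Pr, config$grid)
  fd <- .mlp_forward(params$dec, u)
  delta <- drop(params$dec$W_out %*% fd$h) + params$dec$b_out
  map_idx <- attr(config, "map_idx") %||% seq_len(config$n_beads)
  Wb <- .interp_weights(map_idx, config$n_atoms)
  .decoder_base(Pr, Gr, map_idx, Wb) +
    matrix(delta, config$n_atoms, 3L, byrow = TRUE)
}

.as_cvae_model <- function(x) {
  if (inherits(x, "cvae_model")) return(x)
  if (!is.null(x$model) && inherits(x$model, "cvae_model")) return(x$model)
  stop("not a cvae_model (or checkpoint holding one)", call. = FALSE)
}

## ---- parameter flattening (optimizer + serialization) ----------------

.flatten_params <- function(params) unlist(params, use.names = FALSE)

.relist_params <- function(flat, skeleton) {
  rel <- utils::relist(flat, skeleton)
  # relist drops matrix dims; restore them from the skeleton
  restore <- function(r, s) {
    if (is.list(s)) return(mapply(restore, r, s, SIMPLIFY = FALSE))
    if (is.matrix(s)) r <- matrix(r, nrow(s), ncol(s))
    r
  }
  restore(rel, skeleton)
}
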