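test_that("encoder produces finite latent parameters deterministically", {
  cfg <- tiny_config()
  model <- cvae_init(cfg, seed = 11)
  gs <- cfg$grid
  set.seed(1)
  aa <- random_inbounds_frame(4, gs)
  cg <- frame(aa$coords[c(1, 4), ])
  prev <- random_inbounds_frame(4, gs)
  stack_arr <- array(0, dim = c(gs$d, gs$d, gs$d, 10))
  stack_arr[, , , 1:4] <- voxelize(aa, gs)$values
  stack_arr[, , , 5:6] <- voxelize(cg, gs)$values
  stack_arr[, , , 7:10] <- voxelize(prev, gs)$values
  stack <- structure(list(values = stack_arr, spec = gs,
                          particle_ids = paste0("c", 1:10)),
                     class = "density_grid")
  d1 <- encode(model, stack)
  expect_s3_class(d1, "latent_distribution")
  expect_length(d1$mean, cfg$d_latent)
  expect_length(d1$log_variance, cfg$d_latent)
  expect_true(all(is.finite(c(d1$mean, d1$log_variance))))
  # identical input twice -> identical output
  d2 <- encode(model, stack)
  expect_identical(d1, d2)
  # channel-count mismatch is a shape error
  bad <- structure(list(values = stack_arr[, , , 1:9], spec = gs,
                        particle_ids = paste0("c", 1:9)),
                   class = "density_grid")
  expect_error(encode(model, bad), "2N \\+ n")
})

test_that("reparameterization is exact in mean, variance and seed", {
  d <- structure(list(mean = c(1, -2), log_variance = c(0, log(4))),
                 class = "latent_distribution")
  # zero-variance limit returns the mean exactly
  d0 <- structure(list(mean = c(3, 4), log_variance = c(-1e8, -1e8)),
                  class = "latent_distribution")
  expect_equal(reparameterize(d0, seed = 1), c(3, 4))
  # fixed seed -> bit-reproducible
  expect_identical(reparameterize(d, seed = 5), reparameterize(d, seed = 5))
  # Monte-Carlo mean within 3 standard errors
  set.seed(2)
  Z <- t(vapply(seq_len(1e4), function(i) reparameterize(d), numeric(2)))
  se <- sqrt(c(1, 4) / 1e4)
  expect_true(all(abs(colMeans(Z) - d$mean) < 3 * se))
  expect_equal(apply(Z, 2, sd), c(1, 2), tolerance = 0.05)
})

test_that("decode returns an N-channel grid whose frame is its devoxelization", {
  cfg <- tiny_config()
  model <- cvae_init(cfg, seed = 3)
  gs <- cfg$grid
  set.seed(4)
  cg <- random_inbounds_frame(2, gs, frac = 0.5)
  prev <- random_inbounds_frame(4, gs, frac = 0.5)
  cond_arr <- array(0, dim = c(gs$d, gs$d, gs$d, 6))
  cond_arr[, , , 1:2] <- voxelize(cg, gs)$values
  cond_arr[, , , 3:6] <- voxelize(prev, gs)$values
  cond <- structure(list(values = cond_arr, spec = gs,
                         particle_ids = paste0("c", 1:6)),
                    class = "density_grid")
  # an untrained decoder may place an atom near the boundary, which
  # non-strict voxelization reports with a warning by design
  out <- suppressWarnings(decode(model, rnorm(cfg$d_latent), cond))
  expect_equal(dim(out$grid$values), c(gs$d, gs$d, gs$d, 4L))
  expect_identical(out$frame, devoxelize(out$grid))  # exact pipeline identity
  expect_true(all(out$grid$values >= 0))
  expect_error(decode(model, rnorm(2), cond), "d_latent")
  expect_error(decode(model, rnorm(cfg$d_latent),
                      structure(list(values = cond_arr[, , , 1:5],
                                     spec = gs,
                                     particle_ids = paste0("c", 1:5)),
                                class = "density_grid")),
               "N \\+ n")
})

test_that("analytic loss gradients match finite differences", {
  cfg <- tiny_config()
  attr(cfg, "map_idx") <- c(1L, 4L)
  model <- cvae_init(cfg, seed = 5)
  sys <- make_benchmark_system("tetramer-2state")
  set.seed(3)
  Y <- sys$x0 + matrix(rnorm(12, 0, 0.2), 4, 3)
  G <- Y[c(1, 4), ]
  cen <- colMeans(G)
  Y <- sweep(Y, 2, cen); G <- sweep(G, 2, cen)
  P <- Y + matrix(rnorm(12, 0, 0.1), 4, 3)
  eps <- rnorm(cfg$d_latent)
  Ut <- potential_energy(sys$forcefield, Y)
  fw <- backmapr:::.cvae_forward(model$params, cfg, Y, G, P, eps,
                                 lambda = 0.5, beta = 0.7,
                                 ff = sys$forcefield, target_energy = Ut)
  g <- backmapr:::.flatten_params(
    backmapr:::.cvae_backward(model$params, cfg, fw))
  theta <- backmapr:::.flatten_params(model$params)
  set.seed(11)
  idx <- sample(length(theta), 40)
  h <- 1e-5
  floor_ <- 1e-3 * max(abs(g))  # guards against FD round-off on ~0 entries
  relerr <- vapply(idx, function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    lp <- backmapr:::.cvae_forward(
      backmapr:::.relist_params(tp, model$params), cfg, Y, G, P, eps,
      0.5, 0.7, sys$forcefield, Ut)$losses$total
    lm <- backmapr:::.cvae_forward(
      backmapr:::.relist_params(tm, model$params), cfg, Y, G, P, eps,
      0.5, 0.7, sys$forcefield, Ut)$losses$total
    fd <- (lp - lm) / (2 * h)
    abs(g[j] - fd) / max(abs(fd), floor_)
  }, 0)
  expect_lt(max(relerr), 1e-4)
})

test_that("distinct latent codes decode to distinct valid frames", {
  cfg <- tiny_config()
  model <- cvae_init(cfg, seed = 13)
  gs <- cfg$grid
  set.seed(6)
  cg <- random_inbounds_frame(2, gs)
  prev <- random_inbounds_frame(4, gs)
  Gr <- backmapr:::.readout_coords(cg$coords, gs)
  Pr <- backmapr:::.readout_coords(prev$coords, gs)
  X1 <- backmapr:::.decode_coords(model$params, cfg, rep(2, 3), Gr, Pr)
  X2 <- backmapr:::.decode_coords(model$params, cfg, rep(-2, 3), Gr, Pr)
  expect_gt(rmsd(X1, X2), 0)
  expect_true(all(is.finite(c(X1, X2))))
})
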