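test_that("kabsch alignment recovers planted rotations", {
  set.seed(30)
  X <- matrix(rnorm(30), 10, 3)
  same <- kabsch_align(X, X)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  for (i in 1:5) {
    R0 <- random_rotation()
    shift <- rnorm(3, 0, 4)
    al <- kabsch_align(X, sweep(X %*% R0, 2, shift, "+"))
    expect_equal(al$rotation, R0, tolerance = 1e-8)
    expect_lt(al$rmsd, 1e-10)
  }
  # alignment never increases RMSD
  for (i in 1:10) {
    A <- matrix(rnorm(18), 6, 3); B <- matrix(rnorm(18), 6, 3)
    al <- kabsch_align(A, B)
    expect_lte(al$rmsd, al$rmsd_before + 1e-12)
    expect_equal(det(al$rotation), 1, tolerance = 1e-10)
  }
  expect_warning(kabsch_align(matrix(rnorm(6), 2, 3),
                              matrix(rnorm(6), 2, 3)),
                 "fewer than 3")
  # independent cross-check against bio3d's least-squares fit
  A <- matrix(rnorm(15), 5, 3); B <- sweep(A %*% random_rotation(seed = 2),
                                           2, c(1, 2, 3), "+")
  al <- kabsch_align(A, B)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(B)), as.vector(t(A))))
  expect_equal(matrix(fitted, 5, 3, byrow = TRUE), al$aligned$coords,
               tolerance = 1e-6)
})

test_that("seed-frame selection returns the aligned preceding frame", {
  sys <- make_benchmark_system("tetramer-2state")
  tr <- simulate_langevin(sys, 2000, seed = 55)
  map <- sys$mapping
  # cg0 equal to the CG projection of frame 120 -> match is exact and
  # the seed is frame 119, rigidly moved (alignment on the beads; with
  # two beads the rotation about their axis is a gauge freedom, so the
  # invariants are the frame identity, the bead alignment and the
  # preserved internal geometry)
  cg0 <- frame(tr$coords[120, map$atom_indices, ])
  seedf <- select_seed_frame(tr, cg0, map)
  expect_equal(attr(seedf, "t_star"), 120L)
  expect_lt(attr(seedf, "rmsd"), 1e-10)
  edm119 <- as.vector(dist(tr$coords[119, , ]))
  expect_equal(as.vector(dist(seedf$coords)), edm119,
               tolerance = 1e-8)
  expect_lt(rmsd(seedf$coords[map$atom_indices, ], cg0),
            rmsd(tr$coords[119, map$atom_indices, ],
                 tr$coords[120, map$atom_indices, ]) + 1e-8)
  # rotated copy of a training frame's CG projection: the planted
  # rotation is recovered (zero residual bead RMSD at the matched frame)
  R0 <- random_rotation(seed = 77)
  cg_rot <- frame(tr$coords[120, map$atom_indices, ] %*% R0)
  seed_r <- select_seed_frame(tr, cg_rot, map)
  expect_equal(attr(seed_r, "t_star"), 120L)
  expect_lt(attr(seed_r, "rmsd"), 1e-8)
  expect_equal(as.vector(dist(seed_r$coords)), edm119,
               tolerance = 1e-8)
  # t* = 1 falls back to frame 1 itself (same geometry, beads aligned)
  cg_first <- frame(tr$coords[1, map$atom_indices, ])
  seed_1 <- select_seed_frame(tr, cg_first, map)
  expect_equal(attr(seed_1, "t_star"), 1L)
  expect_equal(as.vector(dist(seed_1$coords)),
               as.vector(dist(tr$coords[1, , ])), tolerance = 1e-8)
  expect_lt(rmsd(seed_1$coords[map$atom_indices, ], cg_first), 1e-8)
})

test_that("latent prior defaults to 10 components and samples reproducibly", {
  expect_equal(formals(fit_latent_prior)$K, 10L)
  set.seed(40)
  codes <- matrix(rnorm(600, 2, 0.5), ncol = 3)
  prior <- fit_latent_prior(codes, K = 4L)
  expect_s3_class(prior, "latent_prior")
  expect_equal(sum(prior$weights), 1, tolerance = 1e-8)
  expect_equal(dim(prior$means), c(4L, 3L))
  for (k in 1:4) {
    S <- prior$covariances[, , k]
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }
  # single-Gaussian codes: sampled mean within 3 standard errors
  Zs <- sample_latent_prior(prior, 5000, seed = 3)
  se <- apply(codes, 2, sd) / sqrt(5000)
  expect_true(all(abs(colMeans(Zs) - colMeans(codes)) < 3 * se + 0.05))
  expect_identical(sample_latent_prior(prior, 10, seed = 5),
                   sample_latent_prior(prior, 10, seed = 5))
  expect_error(fit_latent_prior(codes[1:3, ], K = 10L), "at least K")
})

test_that("autoregressive wiring feeds each reconstruction forward", {
  sys <- make_benchmark_system("tetramer-2state")
  tr <- simulate_langevin(sys, 1000, seed = 66)
  cg <- apply_mapping(sys$mapping, tr)
  cfg <- tiny_config(grid = sys$grid)
  model <- cvae_init(cfg, seed = 1)
  ck <- backmapr:::.make_checkpoint(model$params, cfg,
                                    data.frame(step = 0, total = 1),
                                    train_control(steps = 1L), 1L,
                                    sys$mapping)
  seedf <- get_frame(tr, 1)
  # a stub decoder that echoes its atomistic condition: every output
  # frame must equal the seed frame, proving the recursion
  echo <- function(z, g, p) p
  bm <- backmap_trajectory(cg, ck, prior = NULL, seed_frame = seedf,
                           seed = 2, decoder = echo)
  expect_equal(n_frames(bm), n_frames(cg))
  expect_equal(n_particles(bm), 4L)
  for (t in c(1, 5, n_frames(bm)))
    expect_equal(bm$coords[t, , ], seedf$coords, tolerance = 1e-12)
  # real decoder: fixed seeds are bit-reproducible, different seeds differ
  b1 <- backmap_trajectory(cg, ck, NULL, seedf, seed = 7)
  b2 <- backmap_trajectory(cg, ck, NULL, seedf, seed = 7)
  b3 <- backmap_trajectory(cg, ck, NULL, seedf, seed = 8)
  expect_identical(b1$coords, b2$coords)
  expect_false(identical(b1$coords, b3$coords))
  # bead-count mismatch is rejected
  expect_error(backmap_trajectory(tr, ck, NULL, seedf), "bead count")
  expect_error(backmap_trajectory(cg, ck, NULL,
                                  frame(matrix(0, 3, 3))),
               "N = 4")
})
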