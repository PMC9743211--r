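test_that("dihedral angles follow the atan2 sign convention", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, -1, 0)), 180)
  # the worked right-handed quarter turn
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, 1)), 90)
  # rigid-motion invariance
  set.seed(31)
  P <- matrix(rnorm(12), 4, 3)
  a0 <- dihedral_angle(P[1, ], P[2, ], P[3, ], P[4, ])
  R <- random_rotation(seed = 6)
  Q <- sweep(P %*% R, 2, c(2, -1, 5), "+")
  expect_equal(dihedral_angle(Q[1, ], Q[2, ], Q[3, ], Q[4, ]), a0,
               tolerance = 1e-10)
  # collinear points are rejected
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("pairwise distance features are complete, ordered and invariant", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  f <- pairwise_distance_features(frame(X))
  expect_length(f, 45L)
  expect_equal(f[1], sqrt(sum((X[1, ] - X[2, ])^2)))
  expect_equal(f[45], sqrt(sum((X[9, ] - X[10, ])^2)))
  expect_equal(pairwise_distance_features(frame(rbind(c(0, 0, 0),
                                                      c(0, 3, 4)))), 5)
  R <- random_rotation(seed = 1)
  expect_equal(pairwise_distance_features(frame(sweep(X %*% R, 2, 1:3, "+"))),
               f, tolerance = 1e-10)
  expect_error(pairwise_distance_features(frame(matrix(0, 1, 3))),
               "at least 2")
})

test_that("tica recovers the slow direction of a 2-D linear process", {
  # OU-like AR(1) with distinct relaxation times along known axes
  set.seed(10)
  Tn <- 60000
  a_slow <- 0.99; a_fast <- 0.5
  x <- numeric(Tn); y <- numeric(Tn)
  for (t in 2:Tn) {
    x[t] <- a_slow * x[t - 1] + rnorm(1)
    y[t] <- a_fast * y[t - 1] + rnorm(1)
  }
  # mix the axes: slow direction (1, 1)/sqrt(2), fast (1, -1)/sqrt(2)
  Xmix <- cbind(x + y, x - y)
  tm <- tica_fit(Xmix, lag = 5L)
  expect_true(all(tm$eigenvalues <= 1 + 1e-10 & tm$eigenvalues >= -1 - 1e-10))
  # analytic eigenvalue of the slow process at lag 5
  expect_equal(tm$eigenvalues[1], a_slow^5, tolerance = 0.05)
  # leading IC within 5 degrees of the analytic slow direction
  v <- tm$projection[, 1]
  ang <- acos(abs(sum(v * c(1, 1)) / sqrt(2 * sum(v^2)))) * 180 / pi
  expect_lt(ang, 5)
  # projection is centered and ordered
  proj <- tica_transform(tm, Xmix)
  expect_equal(mean(proj[, 1]), 0, tolerance = 1e-8)
})

test_that("white-noise features have near-zero tica eigenvalues", {
  set.seed(3)
  tm <- tica_fit(matrix(rnorm(3e4), ncol = 3), lag = 2L)
  expect_lt(max(abs(tm$eigenvalues)), 0.05)
  expect_error(tica_fit(cbind(rnorm(100), rep(1, 100)), lag = 1L),
               "degenerate feature.*2")
})

test_that("kmeans discretization freezes centroids for reassignment", {
  set.seed(5)
  # two planted, well-separated clusters
  X <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
             matrix(rnorm(200, 5, 0.3), ncol = 2))
  km <- kmeans_discretize(X, k = 2L, seed = 9)
  truth <- rep(1:2, each = 100)
  agree <- mean(km$states == truth)
  expect_true(agree > 0.99 || agree < 0.01)  # labels may swap
  # k = 1: centroid is the mean, single state
  km1 <- kmeans_discretize(X, k = 1L, seed = 9)
  expect_equal(as.vector(km1$centroids), colMeans(X), tolerance = 1e-10)
  expect_true(all(km1$states == 1L))
  # frozen-centroid assignment of new data
  Xnew <- rbind(c(0.1, -0.1), c(5.2, 4.9))
  st <- assign_states(km$centroids, Xnew)
  expect_equal(st[1], km$states[1])
  expect_equal(st[2], km$states[150])
  # determinism under seed
  expect_equal(kmeans_discretize(X, 2L, seed = 9)$centroids, km$centroids)
  expect_error(kmeans_discretize(X[0, , drop = FALSE], 2L), "empty")
})

test_that("msm estimation is stochastic, reversible and accurate", {
  P <- rbind(c(0.95, 0.05), c(0.10, 0.90))
  # direct eigen-decomposition oracle
  m0 <- msm_estimate(c(1, 1, 2, 1, 2, 2, 1, 1, 2, 1), lag = 1L)
  expect_equal(rowSums(m0$transition_matrix), c(1, 1), tolerance = 1e-10)
  expect_true(all(m0$transition_matrix >= 0))
  expect_equal(m0$eigenvalues[1], 1, tolerance = 1e-10)

  # long sampled chain recovers the generator within tight tolerance
  set.seed(20)
  Tn <- 1e6
  u <- runif(Tn)
  s <- integer(Tn)
  s[1] <- 1L
  for (t in 2:Tn) {
    p_stay <- P[s[t - 1], s[t - 1]]
    s[t] <- if (u[t] < p_stay) s[t - 1] else 3L - s[t - 1]
  }
  m <- msm_estimate(s, lag = 1L)
  expect_equal(m$transition_matrix, P, tolerance = 0.01)
  # detailed balance of the estimate
  flux <- m$stationary * m$transition_matrix
  expect_equal(flux, t(flux), tolerance = 1e-8)

  # a sequence that never leaves state 1 yields a 1x1 model
  m1 <- msm_estimate(rep(1L, 50), lag = 1L, n_states = 3L)
  expect_equal(m1$active, 1L)
  expect_equal(dim(m1$transition_matrix), c(1L, 1L))
  expect_error(msm_estimate(integer(0), lag = 1L), "no transition")
})

test_that("implied timescales follow -tau / log(lambda)", {
  m <- msm_estimate(c(1, 2, 1, 2, 1, 1, 2, 2, 1, 2), lag = 1L)
  m$eigenvalues <- c(1, 0.7)
  expect_equal(implied_timescales(m, tau = 1), -1 / log(0.7))
  expect_equal(implied_timescales(m, tau = 1), 2.804, tolerance = 1e-3)
  # stationary eigenvalue excluded; tau scales linearly
  expect_length(implied_timescales(m), 1L)
  expect_equal(implied_timescales(m, tau = 5), 5 * implied_timescales(m, 1))
  m$eigenvalues <- c(1, 0.5, -0.2)
  expect_warning(ts2 <- implied_timescales(m, tau = 1), "non-positive")
  expect_length(ts2, 1L)
})

test_that("timescale normalization matches slowest processes exactly", {
  out <- normalize_timescales(c(20, 5, 1), c(100, 40))
  expect_equal(out$factor, 5)
  expect_equal(out$rescaled[1], 100)
  expect_equal(out$rescaled, c(100, 25, 5))
  # ratios preserved
  expect_equal(out$rescaled / out$rescaled[1], c(20, 5, 1) / 20)
  # self-normalization is the identity
  self <- normalize_timescales(c(7, 3), c(7, 3))
  expect_equal(self$factor, 1)
  expect_equal(self$rescaled, c(7, 3))
  expect_error(normalize_timescales(c(0, 0), c(1)), "positive")
})

test_that("eigenvector similarity restricts to mutual states", {
  mk_model <- function(active, vecs) {
    structure(list(active = active, right_eigenvectors = vecs),
              class = "transition_model")
  }
  # identical eigenvectors -> 1; orthogonal -> 0
  va <- cbind(1, c(2, 2, 1) / 3)
  ma <- mk_model(1:3, va)
  expect_equal(eigenvector_similarity(ma, ma), 1)
  mb <- mk_model(1:3, cbind(1, c(1, -1, 0)))
  expect_equal(eigenvector_similarity(
    mk_model(1:3, cbind(1, c(1, 1, 0))), mb), 0)
  # worked mutual-support case: (2,2) vs (1,0) -> 2/sqrt(8)
  m1 <- mk_model(c(1L, 2L, 3L), cbind(1, c(2, 2, 9)))
  m2 <- mk_model(c(1L, 2L, 4L), cbind(1, c(1, 0, 7)))
  expect_equal(eigenvector_similarity(m1, m2), 2 / sqrt(8))
  # sign-invariance
  expect_equal(eigenvector_similarity(m1, mk_model(c(1L, 2L, 4L),
                                                   cbind(1, c(-1, 0, 7)))),
               2 / sqrt(8))
  expect_error(eigenvector_similarity(m1, mk_model(c(9L), cbind(1, 1))),
               "mutually occupied")
})

test_that("fes histograms are min-shifted, masked and weight-invariant", {
  set.seed(6)
  u <- matrix(runif(20000, -1, 1))
  f1 <- fes_histogram(u, bins = 10, limits = list(c(-1, 1)))
  expect_equal(min(f1$F), 0)
  expect_lt(max(f1$F), 0.25)  # flat within sampling noise
  # known 1-D double-well density as oracle
  x <- c(rnorm(40000, -1, 0.25), rnorm(20000, 1, 0.25))
  fes <- fes_histogram(matrix(x), bins = 60, limits = list(c(-2, 2)))
  mid <- fes$midpoints[[1]]
  p <- 2 / 3 * dnorm(mid, -1, 0.25) + 1 / 3 * dnorm(mid, 1, 0.25)
  Fa <- -log(p) - min(-log(p))
  ok <- fes$F < 4  # compare where sampling is adequate
  expect_lt(max(abs(fes$F[ok] - Fa[ok])), 0.35)
  # scaling weights by a constant changes nothing
  w <- runif(length(x))
  fa <- fes_histogram(matrix(x), bins = 20, weights = w)
  fb <- fes_histogram(matrix(x), bins = 20, weights = 7 * w)
  expect_equal(fa$F, fb$F)
  # empty bins are NA, not zero
  gap <- matrix(c(rnorm(100, -3, 0.1), rnorm(100, 3, 0.1)))
  fg <- fes_histogram(gap, bins = 30)
  expect_true(anyNA(fg$F))
  # uniform stationary distribution makes reweighting a no-op
  dtraj <- rep(1:2, 500)
  m <- msm_estimate(dtraj, lag = 1L)
  w_msm <- msm_frame_weights(m, dtraj)
  feat <- matrix(rnorm(1000))
  expect_equal(fes_histogram(feat, 10, weights = w_msm)$F,
               fes_histogram(feat, 10)$F, tolerance = 1e-10)
})

test_that("velocity distributions implement forward differences and rescaling", {
  # static trajectory -> all zero
  still <- trajectory(array(1, dim = c(5, 3, 3)), dt = 1)
  v0 <- velocity_distribution(still)
  expect_true(all(v0$pooled == 0))
  # uniform translation of (1,0,0) A per frame at dt = 1 ps
  Tn <- 6
  arr <- array(0, dim = c(Tn, 2, 3))
  for (t in seq_len(Tn)) arr[t, , 1] <- t
  v1 <- velocity_distribution(trajectory(arr, dt = 1))
  expect_equal(v1$per_frame_rms, rep(1, Tn - 1))
  expect_equal(v1$mean, 1)
  # dt rescales inversely
  v2 <- velocity_distribution(trajectory(arr, dt = 1), dt = 0.5)
  expect_equal(v2$mean, 2)
  # mean-matching rescaling is exact
  set.seed(4)
  ref <- abs(rnorm(500, 3)); tst <- abs(rnorm(500, 7))
  rs <- rescale_velocities(tst, ref)
  expect_equal(mean(rs$rescaled), mean(ref))
  expect_equal(rs$factor, mean(ref) / mean(tst))
  expect_error(velocity_distribution(trajectory(arr[1, , , drop = FALSE])),
               "2 frames")
})

test_that("distribution comparison reports overlap and KS agreement", {
  set.seed(13)
  a <- rnorm(4000); b <- rnorm(4000)
  same <- compare_energy_distributions(a, b)
  expect_gt(same$overlap, 0.9)
  expect_lt(same$ks_statistic, 0.05)
  diff <- compare_energy_distributions(a, rnorm(4000, 5))
  expect_lt(diff$overlap, 0.1)
  expect_gt(diff$ks_statistic, 0.9)
})

test_that("wasserstein distance matches closed-form shift cases", {
  set.seed(14)
  x <- rnorm(5000)
  expect_equal(wasserstein1(x, x + 2), 2, tolerance = 1e-10)
  expect_lt(wasserstein1(x, rnorm(5000)), 0.06)
})

test_that("the two-well pipeline recovers the slowest timescale", {
  sys <- make_benchmark_system("tetramer-2state")
  tr <- simulate_langevin(sys, 6e5, seed = 23)
  phi <- dihedral_series(tr, 1:4)
  # dihedral -> k-means -> MSM -> implied timescale
  km <- kmeans_discretize(matrix(cos(phi * pi / 180)), k = 2L, seed = 2)
  lag <- 25L
  m <- msm_estimate(km$states, lag = lag)
  t_msm <- implied_timescales(m, tau = lag * tr$dt)[1]
  # model-free mean-first-passage oracle from the same data, with
  # hysteresis cores (cis |phi| < 60, trans |phi| > 120) so brief
  # barrier recrossings do not count as transitions
  st <- integer(length(phi))
  cur <- if (abs(phi[1]) > 90) 2L else 1L
  for (t in seq_along(phi)) {
    if (abs(phi[t]) < 60) cur <- 1L
    else if (abs(phi[t]) > 120) cur <- 2L
    st[t] <- cur
  }
  t_mfpt <- two_state_relaxation_time(st, dt = tr$dt)
  expect_equal(t_msm, t_mfpt, tolerance = 0.2)
})
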