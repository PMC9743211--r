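#' Torsion (dihedral) angle of four points
#'
#' Standard two-plane-normal construction with the atan2 sign
#' convention: with bond vectors `b1 = p2 - p1`, `b2 = p3 - p2`,
#' `b3 = p4 - p3` and normals `n1 = b1 x b2`, `n2 = b2 x b3`, the
#' angle is `atan2((n1 x n2) . b2 / |b2|, n1 . n2)`.  Planar cis is 0
#' degrees, planar trans 180; the value is rigid-motion invariant and
#' lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 points, or `p1` may be an M x 3
#'   matrix/frame with `indices` selecting four atoms.
#' @param indices optional 4-vector of row indices into `p1`.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL,
                           indices = NULL) {
  if (!is.null(indices)) {
    X <- .coords(p1)
    p1 <- X[indices[1L], ]; p2 <- X[indices[2L], ]
    p3 <- X[indices[3L], ]; p4 <- X[indices[4L], ]
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                            a[3L] * b[1L] - a[1L] * b[3L],
                            a[1L] * b[2L] - a[2L] * b[1L])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear points: dihedral undefined", call. = FALSE)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @rdname dihedral_angle
#' @param traj a [trajectory()].
#' @return `dihedral_series()` returns the per-frame angle (degrees).
#' @export
dihedral_series <- function(traj, indices) {
  vapply(seq_len(n_frames(traj)), function(t)
    dihedral_angle(traj$coords[t, , , drop = TRUE], indices = indices),
    0)
}

#' All pairwise interparticle distances of a frame
#'
#' Features in fixed lexicographic pair order (1,2), (1,3), ...,
#' (1,M), (2,3), ...: `M (M - 1) / 2` values (45 for a 10-bead
#' chain), rigid-motion invariant.
#'
#' @param frm a [frame()] or M x 3 matrix (M >= 2); or a
#'   [trajectory()], in which case a T x M(M-1)/2 matrix is returned.
#' @return Numeric vector (or matrix) of distances in A.
#' @export
pairwise_distance_features <- function(frm) {
  if (inherits(frm, "trajectory")) {
    return(t(vapply(seq_len(n_frames(frm)), function(t)
      as.vector(dist(frm$coords[t, , , drop = TRUE])),
      numeric(n_particles(frm) * (n_particles(frm) - 1L) / 2L))))
  }
  X <- .coords(frm)
  if (nrow(X) < 2L) stop("need at least 2 particles", call. = FALSE)
  as.vector(dist(X))
}

#' Time-lagged independent component analysis
#'
#' Solves the symmetrized generalized eigenproblem
#' `C_tau v = lambda C_0 v`, where `C_0` and `C_tau` are the
#' instantaneous and time-lagged covariances estimated symmetrically in
#' time (guaranteeing eigenvalues in `[-1, 1]`).  Features are mean
#' centered, so the trivial constant component is excluded by
#' construction; components are ordered by decreasing eigenvalue
#' (slowest first).
#'
#' @param features T x F matrix of time-series features.
#' @param lag lag time in frames (>= 1, < T).
#' @param dim number of components to keep (default all).
#' @param epsilon relative variance cutoff below which a feature
#'   direction is treated as degenerate during whitening.
#' @return Object of class `tica_model`: `mean`, `projection`
#'   (F x dim), `eigenvalues`, `lag`.
#' @export
tica_fit <- function(features, lag, dim = NULL, epsilon = 1e-10) {
  X <- as.matrix(features)
  Tn <- nrow(X)
  if (Tn <= lag) stop("series length must exceed the lag", call. = FALSE)
  cvar <- apply(X, 2L, var)
  if (any(cvar < 1e-14))
    stop("degenerate feature: column(s) ",
         paste(which(cvar < 1e-14), collapse = ", "),
         " have (near-)zero variance", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  A <- Xc[seq_len(Tn - lag), , drop = FALSE]
  B <- Xc[(lag + 1L):Tn, , drop = FALSE]
  C0 <- (crossprod(A) + crossprod(B)) / (2 * (Tn - lag))
  Ct <- (crossprod(A, B) + crossprod(B, A)) / (2 * (Tn - lag))
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > epsilon * max(e0$values)
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- crossprod(W, Ct %*% W)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  proj <- W %*% em$vectors
  k <- if (is.null(dim)) ncol(proj) else min(dim, ncol(proj))
  structure(list(mean = mu, projection = proj[, seq_len(k), drop = FALSE],
                 eigenvalues = em$values[seq_len(k)], lag = lag),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("<tica_model> lag =", x$lag, "frames;",
      length(x$eigenvalues), "components; leading eigenvalues:",
      paste(signif(head(x$eigenvalues, 3L), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tica_fit
#' @param model a `tica_model`.
#' @return `tica_transform()` returns the projected T x dim series.
#' @export
tica_transform <- function(model, features) {
  sweep(as.matrix(features), 2L, model$mean) %*% model$projection
}

#' Discretize a feature space with frozen k-means centroids
#'
#' Centroids are fitted once on a designated reference series; state
#' assignments for any other series reuse those same frozen centroids
#' (via [assign_states()]), which is what makes Markov models built on
#' different trajectories directly comparable.
#'
#' @param features T x F reference series (fitting set).
#' @param k number of centroids.
#' @param seed integer seed for the k-means initialization.
#' @param nstart random restarts.
#' @param iter_max k-means iteration cap.
#' @return List with `centroids` (k x F) and `states` (assignment of
#'   the fitting series, integers in 1..k).
#' @export
kmeans_discretize <- function(features, k, seed = 1L, nstart = 5L,
                              iter_max = 100L) {
  X <- as.matrix(features)
  if (!nrow(X)) stop("empty feature series", call. = FALSE)
  if (nrow(X) <= k)
    stop("need more samples than centroids", call. = FALSE)
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = nstart, iter.max = iter_max)
  list(centroids = km$centers, states = km$cluster)
}

#' @rdname kmeans_discretize
#' @param centroids frozen centroid matrix (k x F).
#' @return `assign_states()` returns nearest-centroid indices.
#' @export
assign_states <- function(centroids, features) {
  X <- as.matrix(features)
  cn2 <- rowSums(centroids^2)
  # squared distances via ||x||^2 - 2 x.c + ||c||^2; argmin over c
  D <- sweep(-2 * X %*% t(centroids), 2L, cn2, "+")
  max.col(-D, ties.method = "first")
}

#' Estimate a reversible Markov state model
#'
#' Counts transitions at lag `tau` (sliding window) within each state
#' sequence, restricts to the largest connected set of visited states,
#' and runs the standard fixed-point iteration for the reversible
#' maximum-likelihood transition matrix.  The eigen-decomposition
#' (computed through the symmetrized similarity transform, so it is
#' real) is attached.
#'
#' @param dtrajs integer state sequence, or list of sequences (states
#'   in 1..k over a common centroid set).
#' @param lag lag time in frames (>= 1).
#' @param n_states total number of states in the discretization
#'   (default: largest observed index).
#' @param maxiter,tol fixed-point iteration controls.
#' @return Object of class `transition_model`: `transition_matrix`
#'   (row-stochastic over the active set), `active` (state ids),
#'   `stationary`, `eigenvalues`, `right_eigenvectors`,
#'   `left_eigenvectors`, `lag`.
#' @export
msm_estimate <- function(dtrajs, lag = 1L, n_states = NULL,
                         maxiter = 1000L, tol = 1e-12) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (!sum(lengths(dtrajs)))
    stop("no transition pairs at lag ", lag, call. = FALSE)
  k <- as.integer(n_states %||%
                    max(vapply(dtrajs, function(s) max(as.numeric(s)), 0)))
  C <- matrix(0, k, k)
  for (s in dtrajs) {
    s <- as.integer(s)
    if (length(s) > lag) {
      from <- s[seq_len(length(s) - lag)]
      to <- s[(lag + 1L):length(s)]
      C <- C + matrix(tabulate(from + k * (to - 1L), k * k), k, k)
    }
  }
  if (sum(C) == 0)
    stop("no transition pairs at lag ", lag, call. = FALSE)
  active <- .largest_connected_set(C)
  C <- C[active, active, drop = FALSE]
  ka <- length(active)
  # reversible MLE fixed point (symmetric X parameterization)
  Csym <- C + t(C)
  X <- Csym / sum(C)
  ci <- rowSums(C)
  for (it in seq_len(maxiter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xn <- Csym / denom
    Xn <- Xn / sum(Xn)
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  pi_ <- rowSums(X)
  P <- X / pi_
  P <- P / rowSums(P)   # clean residual rounding
  # symmetrized eigenproblem: D^1/2 P D^-1/2 is symmetric
  sq <- sqrt(pi_)
  S <- diag(sq, ka) %*% P %*% diag(1 / sq, ka)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  vals <- es$values[ord]
  right <- diag(1 / sq, ka) %*% es$vectors[, ord, drop = FALSE]
  left <- diag(sq, ka) %*% es$vectors[, ord, drop = FALSE]
  structure(list(transition_matrix = P, active = active,
                 stationary = pi_, eigenvalues = vals,
                 right_eigenvectors = right, left_eigenvectors = left,
                 lag = lag, counts = C),
            class = "transition_model")
}

.largest_connected_set <- function(C) {
  k <- nrow(C)
  adj <- (C + t(C)) > 0
  visited <- rep(FALSE, k)
  present <- which(rowSums(C) + colSums(C) > 0)
  best <- integer()
  for (s in present) {
    if (visited[s]) next
    comp <- s; queue <- s; visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
      comp <- c(comp, nb)
    }
    if (length(comp) > length(best)) best <- comp
  }
  sort(best)
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$active), " states, lag = ",
      x$lag, "; eigenvalues: ",
      paste(signif(head(x$eigenvalues, 4L), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Implied relaxation timescales of a Markov state model
#'
#' `t_i = -tau / log(lambda_i)` for every nontrivial eigenvalue
#' `0 < lambda_i < 1`, sorted descending; the stationary eigenvalue 1
#' is excluded and non-positive eigenvalues are skipped with a warning.
#'
#' @param model a `transition_model`.
#' @param tau lag time in physical units (defaults to `model$lag`,
#'   i.e. timescales in frames).
#' @return Numeric vector of timescales (same units as `tau`).
#' @export
implied_timescales <- function(model, tau = NULL) {
  tau <- tau %||% model$lag
  lam <- model$eigenvalues
  nontriv <- lam[lam < 1 - 1e-12]
  bad <- nontriv[nontriv <= 0]
  if (length(bad))
    warning(length(bad), " non-positive eigenvalue(s) skipped",
            call. = FALSE)
  lam_ok <- nontriv[nontriv > 0]
  sort(-tau / log(lam_ok), decreasing = TRUE)
}

#' Rescale timescales so the slowest processes match
#'
#' Multiplies every target timescale by
#' `slowest(reference) / slowest(target)`, the standard correction for
#' the uniform acceleration of coarse-grained dynamics; ratios within
#' the target list are preserved exactly.
#'
#' @param target,reference descending timescale vectors.
#' @return List with `rescaled` and `factor`.
#' @export
normalize_timescales <- function(target, reference) {
  if (!length(target) || !length(reference))
    stop("empty timescale list", call. = FALSE)
  if (max(target) <= 0)
    stop("slowest target timescale must be positive", call. = FALSE)
  factor <- max(reference) / max(target)
  list(rescaled = target * factor, factor = factor)
}

#' Cosine similarity of MSM eigenvectors on mutually occupied states
#'
#' For models built on one shared centroid set, restricts each paired
#' nontrivial right eigenvector to the states occupied in both models,
#' renormalizes, and reports the absolute cosine (eigenvector signs
#' are arbitrary).
#'
#' @param model_a,model_b `transition_model`s over the same centroid
#'   set.
#' @param n_processes number of nontrivial process pairs to compare
#'   (default: all shared).
#' @return Numeric vector of |cosine| similarities, one per process.
#' @export
eigenvector_similarity <- function(model_a, model_b, n_processes = NULL) {
  mutual <- intersect(model_a$active, model_b$active)
  if (!length(mutual))
    stop("no mutually occupied states", call. = FALSE)
  ia <- match(mutual, model_a$active)
  ib <- match(mutual, model_b$active)
  npa <- ncol(model_a$right_eigenvectors) - 1L
  npb <- ncol(model_b$right_eigenvectors) - 1L
  np <- min(npa, npb, n_processes %||% Inf)
  out <- numeric(np)
  for (p in seq_len(np)) {
    va <- model_a$right_eigenvectors[ia, p + 1L]
    vb <- model_b$right_eigenvectors[ib, p + 1L]
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    if (na < 1e-300 || nb < 1e-300) { out[p] <- NA_real_; next }
    out[p] <- abs(sum(va * vb)) / (na * nb)
  }
  out
}

#' Free-energy surface from a (weighted) histogram
#'
#' `F = -ln(weighted density)` in units of kT, shifted so the minimum
#' is zero; empty bins are reported as `NA` (undefined), never zero.
#' Per-frame weights default to uniform; Markov-model reweighting
#' weights from [msm_frame_weights()] turn the histogram of a biased
#' or short trajectory into an estimate under the model's stationary
#' distribution.
#'
#' @param features T x 1 or T x 2 matrix of collective variables.
#' @param bins number of bins per dimension (or length-2 vector).
#' @param weights optional nonnegative per-frame weights.
#' @param limits optional list of per-dimension c(min, max).
#' @return List with `F` (vector or matrix, kT), `midpoints` (list),
#'   `breaks` (list).
#' @export
fes_histogram <- function(features, bins = 32L, weights = NULL,
                          limits = NULL) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite features", call. = FALSE)
  nd <- ncol(X)
  if (!nd %in% 1:2) stop("features must have 1 or 2 columns", call. = FALSE)
  Tn <- nrow(X)
  if (is.null(weights)) weights <- rep(1, Tn)
  if (length(weights) != Tn || any(weights < 0))
    stop("weights must be nonnegative, one per frame", call. = FALSE)
  bins <- rep_len(as.integer(bins), nd)
  brk <- mid <- vector("list", nd)
  ix <- matrix(0L, Tn, nd)
  for (d in seq_len(nd)) {
    lim <- if (is.null(limits)) range(X[, d]) else limits[[d]]
    brk[[d]] <- seq(lim[1L], lim[2L], length.out = bins[d] + 1L)
    mid[[d]] <- (head(brk[[d]], -1L) + tail(brk[[d]], -1L)) / 2
    ix[, d] <- pmin(pmax(findInterval(X[, d], brk[[d]],
                                      rightmost.closed = TRUE), 1L),
                    bins[d])
  }
  if (nd == 1L) {
    h <- vapply(seq_len(bins[1L]),
                function(b) sum(weights[ix[, 1L] == b]), 0)
  } else {
    h <- matrix(0, bins[1L], bins[2L])
    for (t in seq_len(Tn))
      h[ix[t, 1L], ix[t, 2L]] <- h[ix[t, 1L], ix[t, 2L]] + weights[t]
  }
  h <- h / sum(h)
  F_ <- -log(h)
  F_[!is.finite(F_)] <- NA_real_
  F_ <- F_ - min(F_, na.rm = TRUE)
  list(F = F_, midpoints = mid, breaks = brk)
}

#' Stationary-reweighting frame weights from a Markov model
#'
#' Frame `t` in state `i` receives weight `pi_i / N_i` (stationary
#' probability over the number of frames observed in that state), so
#' the weighted histogram estimates observables under the model's
#' stationary distribution.  Frames in states outside the model's
#' active set get weight 0.
#'
#' @param model a `transition_model`.
#' @param dtraj integer state sequence (same centroid set).
#' @return Nonnegative per-frame weights summing to ~1.
#' @export
msm_frame_weights <- function(model, dtraj) {
  w <- numeric(length(dtraj))
  counts <- table(factor(dtraj, levels = model$active))
  for (j in seq_along(model$active)) {
    s <- model$active[j]
    if (counts[j] > 0)
      w[dtraj == s] <- model$stationary[j] / as.numeric(counts[j])
  }
  w / sum(w)
}

#' Finite-difference velocity distributions of a trajectory
#'
#' Forward differences between sequential frames: per-atom velocity
#' magnitudes `|x(t+1) - x(t)| / dt`, the per-frame RMS over atoms, and
#' the pooled distribution over all atomic velocities.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param dt frame spacing in ps (defaults to `traj$dt`).
#' @return List with `per_frame_rms` (length T-1), `pooled`
#'   ((T-1) x M matrix of atomic speeds), `mean` of the pooled
#'   distribution. Units A/ps.
#' @export
velocity_distribution <- function(traj, dt = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- dt %||% traj$dt
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  Tn <- n_frames(traj)
  if (Tn < 2L) stop("need at least 2 frames", call. = FALSE)
  d <- traj$coords[2:Tn, , , drop = FALSE] -
    traj$coords[seq_len(Tn - 1L), , , drop = FALSE]
  speed <- sqrt(d[, , 1L]^2 + d[, , 2L]^2 + d[, , 3L]^2) / dt
  if (is.null(dim(speed))) speed <- matrix(speed, ncol = 1L)
  list(per_frame_rms = sqrt(rowMeans(speed^2)), pooled = speed,
       mean = mean(speed))
}

#' @rdname velocity_distribution
#' @param test,reference velocity samples (vectors/matrices).
#' @return `rescale_velocities()` returns the rescaled test sample and
#'   the constant factor `mean(reference) / mean(test)` that equalizes
#'   the two means.
#' @export
rescale_velocities <- function(test, reference) {
  factor <- mean(reference) / mean(test)
  list(rescaled = test * factor, factor = factor)
}

#' Compare two scalar distributions (e.g. potential energies)
#'
#' Histogram overlap coefficient on a shared binning plus the
#' two-sample Kolmogorov-Smirnov statistic, a quantitative stand-in
#' for the visual distribution comparisons used when judging
#' structural similarity of backmapped ensembles.
#'
#' @param reference,test numeric samples.
#' @param bins shared bin count.
#' @return List with `overlap` (in [0, 1]), `ks_statistic`,
#'   `ks_p_value`, and the two sample means.
#' @export
compare_energy_distributions <- function(reference, test, bins = 50L) {
  rng <- range(c(reference, test))
  brk <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h1 <- hist_w(reference, brk); h2 <- hist_w(test, brk)
  ks <- suppressWarnings(ks.test(reference, test))
  list(overlap = sum(pmin(h1, h2)),
       ks_statistic = unname(ks$statistic),
       ks_p_value = ks$p.value,
       mean_reference = mean(reference), mean_test = mean(test))
}

hist_w <- function(x, brk) {
  ix <- pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE), 1L),
             length(brk) - 1L)
  tabulate(ix, length(brk) - 1L) / length(x)
}

#' First Wasserstein distance between two empirical distributions
#'
#' Computed from the quantile representation:
#' `W1 = integral |Q1(u) - Q2(u)| du`, approximated on a fine uniform
#' grid of probabilities.
#'
#' @param a,b numeric samples.
#' @param n_quantiles grid resolution.
#' @return Nonnegative scalar in the units of the samples.
#' @export
wasserstein1 <- function(a, b, n_quantiles = 2000L) {
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  mean(abs(quantile(a, p, names = FALSE, type = 4) -
             quantile(b, p, names = FALSE, type = 4)))
}

#' Mean first-passage estimate of the slowest two-state timescale
#'
#' Model-free check used against Markov-model implied timescales on
#' double-well systems: measures mean dwell times in each of two
#' states from a binary occupancy series and returns the implied
#' relaxation time `1 / (k12 + k21)` of the equivalent two-state
#' kinetic model.
#'
#' @param binary_states vector of 1/2 state labels over time.
#' @param dt frame spacing (units of the returned timescale).
#' @return Relaxation timescale.
#' @export
two_state_relaxation_time <- function(binary_states, dt = 1) {
  s <- as.integer(binary_states)
  runs <- rle(s)
  if (length(unique(s)) < 2L || length(runs$lengths) < 3L)
    stop("need multiple visits to both states", call. = FALSE)
  # drop the censored first and last dwells
  keep <- seq(2L, length(runs$lengths) - 1L)
  d1 <- runs$lengths[keep][runs$values[keep] == 1L]
  d2 <- runs$lengths[keep][runs$values[keep] == 2L]
  if (!length(d1) || !length(d2))
    stop("need completed dwells in both states", call. = FALSE)
  k12 <- 1 / (mean(d1) * dt)
  k21 <- 1 / (mean(d2) * dt)
  1 / (k12 + k21)
}
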