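test_that("white-noise series has no slow component", {
  set.seed(61)
  X <- matrix(rnorm(20000 * 5), 20000, 5)
  m <- fit_tica(X, tau = 25)
  expect_lt(max(abs(m$eigenvalues)), 3 / sqrt(20000))
})

test_that("two-state series recovers the analytic leading eigenvalue", {
  k <- 0.005; tau <- 50
  ts <- make_two_state_series(n_frames = 100000, k12 = k, k21 = k, seed = 3)
  m <- fit_tica(ts$features, tau = tau)
  expect_equal(m$eigenvalues[1], exp(-2 * k * tau), tolerance = 0.1)
  expect_lt(max(abs(m$eigenvalues[-1])), 0.05)  # fast directions ~ 0
})

test_that("eigenvectors are C-orthonormal and eigenvalues bounded", {
  ts <- make_two_state_series(n_frames = 50000, k12 = 0.01, k21 = 0.02,
                              seed = 8)
  m <- fit_tica(ts$features, tau = 20)
  G <- t(m$eigenvectors) %*% m$C %*% m$eigenvectors
  expect_equal(G, diag(ncol(G)), tolerance = 1e-6)
  expect_true(all(abs(m$eigenvalues) <= 1 + 5 / sqrt(m$n_samples)))
})

test_that("spectrum is invariant under invertible affine feature maps", {
  ts <- make_two_state_series(n_frames = 30000, k12 = 0.01, k21 = 0.01,
                              seed = 5)
  m0 <- fit_tica(ts$features, tau = 20)
  set.seed(71)
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(25), 5, 5) + diag(5)
  Y <- ts$features %*% t(A) + matrix(rep(rnorm(5), each = 30000), 30000, 5)
  m1 <- fit_tica(Y, tau = 20)
  expect_equal(m1$eigenvalues, m0$eigenvalues, tolerance = 1e-6)
})

test_that("multiple trajectories pool pairs without crossing boundaries", {
  ts1 <- make_two_state_series(n_frames = 30000, k12 = 0.01, k21 = 0.01,
                               seed = 1)
  ts2 <- make_two_state_series(n_frames = 30000, k12 = 0.01, k21 = 0.01,
                               seed = 2)
  m <- fit_tica(list(ts1$features, ts2$features), tau = 20)
  expect_equal(m$n_samples, 60000L)
  expect_equal(m$n_pairs, 2L * (30000L - 20L))
  expect_equal(m$eigenvalues[1], exp(-0.02 * 20), tolerance = 0.15)
  expect_error(fit_tica(ts1$features[1:10, ], tau = 20), "T > tau")
})

test_that("implied timescale recovers 1/(2k) across rates and lags", {
  # Emission noise attenuates the leading eigenvalue by a = q/(1+q) with
  # q = (1/4) sum (Delta_i / sigma_i)^2 (state separation over noise), so
  # the exact finite-noise expectation is lambda1 = a exp(-2 k tau) and
  # the implied timescale tau/(-ln lambda1) has a noise floor -ln(a).
  # The median over 5 replicate series is compared to that closed form
  # everywhere; the plain 1/(2k) recovery band additionally holds
  # wherever the floor is negligible (2 k tau >> -ln a). At k = 0.001,
  # tau = 10 the floor alone biases the timescale by ~30%: that cell can
  # only meet the corrected prediction.
  delta <- c(8.0, 6.0, 4.9, 4.5, 12.5) - c(3.5, 4.0, 8.9, 12.3, 7.5)
  q <- sum((delta / 0.5)^2) / 4
  att <- q / (1 + q)
  for (k in c(0.001, 0.005, 0.02)) for (tau in c(10, 50)) {
    its <- vapply(1:5, function(s) {
      ts <- make_two_state_series(n_frames = 200000, k12 = k, k21 = k,
                                  seed = 1000 * s + round(1e4 * k))
      implied_timescale(fit_tica(ts$features, tau = tau), 1)
    }, numeric(1))
    med <- stats::median(its)
    expected <- tau / (2 * k * tau - log(att))
    expect_lt(abs(med / expected - 1), 0.15)
    if (2 * k * tau > 10 * (-log(att))) {
      expect_lt(abs(med / (1 / (2 * k)) - 1), 0.15)
    }
  }
})

test_that("projection is deterministic, centres the mean, separates states", {
  ts <- make_two_state_series(n_frames = 40000, k12 = 0.01, k21 = 0.01,
                              seed = 6)
  m <- fit_tica(ts$features, tau = 20)
  p1 <- project_tica(m, ts$features)
  p2 <- project_tica(m, ts$features)
  expect_identical(p1, p2)
  expect_equal(as.numeric(project_tica(m, rbind(m$mean))), c(0, 0),
               tolerance = 1e-12)
  # state-conditional means separate along tIC1 by construction
  mu1 <- mean(p1[ts$states == 1L, 1]); mu2 <- mean(p1[ts$states == 2L, 1])
  expect_gt(abs(mu1 - mu2), 1)
  # fresh frames from the same generator land near the mapped state centres
  ts_new <- make_two_state_series(n_frames = 5000, k12 = 0.01, k21 = 0.01,
                                  seed = 99)
  pn <- project_tica(m, ts_new$features)
  c1 <- as.numeric(project_tica(m, rbind(ts_new$features[1, ] * 0 +
                                         colMeans(ts$features[ts$states == 1L, ]))))
  grp <- mean(pn[ts_new$states == 1L, 1])
  expect_equal(grp, c1[1], tolerance = 0.2)
  expect_error(project_tica(m, matrix(0, 5, 3)), "features")
})

test_that("microstate clustering is deterministic and recovers populations", {
  set.seed(81)
  blob1 <- matrix(rnorm(2000, sd = 0.3), ncol = 2) + 3
  blob2 <- matrix(rnorm(2000, sd = 0.3), ncol = 2) - 3
  coords <- rbind(blob1, blob2)
  ms <- cluster_microstates(coords, k = 2, seed = 10)
  expect_equal(sort(ms$populations), c(0.5, 0.5), tolerance = 1e-12)
  # zero misassignments for well-separated blobs
  lab <- ms$assignments
  expect_true(all(lab[1:1000] == lab[1]) && all(lab[1001:2000] == lab[1001]))
  expect_false(lab[1] == lab[1001])
  ms2 <- cluster_microstates(coords, k = 2, seed = 10)
  expect_identical(ms$assignments, ms2$assignments)
  expect_error(cluster_microstates(coords, k = 1), "k must be")
  expect_true(all(tabulate(ms$assignments, 2) > 0))
  expect_equal(sum(ms$populations), 1)
})

test_that("k-means++ objective beats random restarts", {
  set.seed(91)
  coords <- rbind(matrix(rnorm(600, sd = 0.5), ncol = 2),
                  matrix(rnorm(600, sd = 0.5), ncol = 2) + 5,
                  matrix(rnorm(600, sd = 0.5), ncol = 2) %*%
                    diag(c(1, -1)) + c(8, -4))
  ms <- cluster_microstates(coords, k = 3, seed = 2)
  rand_obj <- vapply(1:10, function(i) {
    init <- coords[sample.int(nrow(coords), 3), ]
    sum(suppressWarnings(stats::kmeans(coords, init, iter.max = 1,
                                       algorithm = "Lloyd"))$withinss)
  }, numeric(1))
  expect_lte(ms$withinss, min(rand_obj) + 1e-9)
})

test_that("two-state populations from clustering match the generator", {
  ts <- make_two_state_series(n_frames = 100000, k12 = 0.005, k21 = 0.005,
                              seed = 13)
  m <- fit_tica(ts$features, tau = 50)
  p <- project_tica(m, ts$features)
  ms <- cluster_microstates(p, k = 2, seed = 3)
  expect_equal(unname(ms$populations), c(0.5, 0.5), tolerance = 0.06)
})

test_that("density landscape normalizes and localizes the two states", {
  ts <- make_two_state_series(n_frames = 50000, k12 = 0.01, k21 = 0.01,
                              seed = 17)
  m <- fit_tica(ts$features, tau = 20)
  p <- project_tica(m, ts$features)
  land <- density_landscape(p, bins = 40)
  expect_equal(sum(land$p), 1, tolerance = 1e-12)
  expect_true(all(is.na(land$neglogp) | is.finite(land$neglogp)))
  # two local maxima along tIC1: marginal density is bimodal at the mapped
  # state centres
  marg <- rowSums(land$p)
  c1 <- as.numeric(project_tica(m, rbind(colMeans(ts$features[ts$states == 1L, ])))[1])
  c2 <- as.numeric(project_tica(m, rbind(colMeans(ts$features[ts$states == 2L, ])))[1])
  n <- length(marg)
  is_peak <- c(FALSE, marg[2:(n - 1)] > marg[1:(n - 2)] &
                 marg[2:(n - 1)] > marg[3:n], FALSE)
  peaks <- land$x[is_peak][order(marg[is_peak], decreasing = TRUE)[1:2]]
  expect_equal(sort(peaks), sort(c(c1, c2)), tolerance = 0.25)
  # uniform coordinates: flat within multinomial error
  set.seed(23)
  u <- cbind(runif(200000), runif(200000))
  lu <- density_landscape(u, bins = 10)
  expect_lt(max(abs(lu$p - 0.01)), 5 * sqrt(0.01 * 0.99 / 200000) + 1e-4)
})
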