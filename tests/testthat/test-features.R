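test_that("spike-triggered slices are exact stimulus windows", {
  # ramp stimulus, one spike: the row is the closing slice
  stim <- tibble::tibble(time = seq(0, 199), current = seq(0, 199))
  ste <- spike_triggered_matrix(stim, spikes = 100, window = 10,
                                center = FALSE)
  expect_equal(as.numeric(ste$X), seq(91, 100))

  # duplicated spike times give identical rows
  ste2 <- spike_triggered_matrix(stim, c(100, 100), window = 10,
                                 center = FALSE)
  expect_equal(ste2$X[1, ], ste2$X[2, ])

  # early spikes are dropped and counted; none usable is an error
  ste3 <- spike_triggered_matrix(stim, c(3, 100), window = 10)
  expect_equal(ste3$n_dropped, 1L)
  expect_error(spike_triggered_matrix(stim, 3, window = 10), "spikes")
})

test_that("STA and STC match brute-force oracles", {
  ste <- planted_ste(50, mu = rep(0, 10), Lambda = diag(10), seed = 2)

  # STA: row mean
  brute_mu <- apply(ste$X, 2, mean)
  expect_equal(compute_sta(ste)$filter, brute_mu, tolerance = 1e-12)

  # STC: brute-force outer-product sum / n
  mu <- brute_mu
  brute <- matrix(0, 10, 10)
  for (i in seq_len(nrow(ste$X))) {
    d <- ste$X[i, ] - mu
    brute <- brute + outer(d, d)
  }
  brute <- brute / nrow(ste$X)
  stc <- compute_stc(ste)
  expect_equal(stc$Lambda, brute, tolerance = 1e-10)
  expect_identical(stc$Lambda, t(stc$Lambda))
  expect_true(all(diff(stc$values) <= 1e-12))

  # symmetric rows average to zero; identical rows give a zero matrix
  v <- rnorm(6)
  sym <- structure(list(X = rbind(v, -v), lags = seq(-5, 0), dt = 1,
                        spike_times = 1:2, n_dropped = 0L, stim_mean = 0,
                        centered = TRUE, tag = "toy"), class = "sdm_ste")
  expect_equal(compute_sta(sym)$filter, rep(0, 6))
  same <- structure(list(X = rbind(v, v), lags = seq(-5, 0), dt = 1,
                         spike_times = 1:2, n_dropped = 0L, stim_mean = 0,
                         centered = TRUE, tag = "toy"), class = "sdm_ste")
  expect_equal(compute_stc(same)$Lambda, matrix(0, 6, 6),
               tolerance = 1e-12)
})

test_that("subspace information matches its closed form and quadrature", {
  # identity covariance, zero mean: no information
  K <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  expect_equal(istac_info(K, rep(0, 5), diag(5)), 0, tolerance = 1e-12)

  # 1-D closed form 0.5 * (lambda - log lambda + mu^2 - 1), checked
  # against numerical integration of the Gaussian KL integrand
  lam <- 2.3; m <- 0.7
  closed <- 0.5 * (lam - log(lam) + m^2 - 1)
  expect_equal(istac_info(matrix(1), m, matrix(lam)), closed,
               tolerance = 1e-12)
  kl <- integrate(function(x) {
    q <- dnorm(x, m, sqrt(lam))
    q * (dnorm(x, m, sqrt(lam), log = TRUE) - dnorm(x, log = TRUE))
  }, -30, 30, rel.tol = 1e-10)$value
  expect_equal(closed, kl, tolerance = 1e-8)

  # complete basis reproduces the full-space divergence exactly
  mu <- rnorm(4) / 2
  A <- matrix(rnorm(16), 4)
  Lambda <- crossprod(A) / 4 + diag(4) * 0.5
  full <- 0.5 * (sum(diag(Lambda)) - determinant(Lambda)$modulus[1] +
                   sum(mu^2) - 4)
  expect_equal(istac_info(diag(4), mu, Lambda), full, tolerance = 1e-10)

  expect_error(istac_info(matrix(c(1, 0), 2), c(0, 0),
                          matrix(0, 2, 2)), "Degenerate")
})

test_that("greedy selection recovers a planted two-dimensional subspace", {
  set.seed(5)
  n <- 12
  u1 <- rnorm(n); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(n); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  # spike-triggered distribution differs from the white prior only along
  # u1 (mean shift) and u2 (variance change)
  mu <- 1.5 * u1
  Lambda <- diag(n) + 2.5 * outer(u2, u2)
  ste <- planted_ste(4000, mu, Lambda, seed = 6)
  sel <- select_subspaces(ste, d = 2)

  B <- cbind(sel$filters$nu1, sel$filters$nu2)
  planted <- cbind(u1, u2)
  ang <- acos(pmin(svd(crossprod(qr.Q(qr(B)), qr.Q(qr(planted))))$d, 1))
  expect_true(all(ang < 10 * pi / 180))

  # greedy information is monotonically non-decreasing
  expect_true(all(diff(sel$info) >= -1e-10))

  # d = n reproduces the full-space information
  mu_hat <- compute_sta(ste)$filter
  L_hat <- compute_stc(ste)$Lambda
  sel_full <- select_subspaces(ste, d = n)
  expect_equal(sel_full$info[n], sel_full$full_info, tolerance = 1e-8)

  expect_error(select_subspaces(ste, d = n + 1), "exceeds")
})

test_that("whitened selection is invariant to linear recoloring", {
  set.seed(8)
  n <- 6
  mu <- rnorm(n) / 2
  A <- matrix(rnorm(n * n), n)
  Lambda <- crossprod(A) / n + diag(n)
  prior <- list(mean = rep(0, n), cov = diag(n))

  sel <- select_subspaces(mu = mu, Lambda = Lambda, d = 2,
                          whiten = TRUE, prior = prior)

  # recolor the stimulus space with an invertible matrix
  R <- diag(n) + 0.3 * matrix(rnorm(n * n), n)
  selR <- select_subspaces(mu = as.numeric(R %*% mu),
                           Lambda = R %*% Lambda %*% t(R), d = 2,
                           whiten = TRUE,
                           prior = list(mean = rep(0, n),
                                        cov = R %*% t(R)))
  expect_equal(sel$info, selR$info, tolerance = 1e-8)
})

test_that("projections equal direct inner products", {
  ste <- planted_ste(20, rep(0, 8), diag(8), seed = 3)
  f1 <- rnorm(8); f2 <- rnorm(8)
  pr <- project_ensemble(ste, f1, f2)
  expect_equal(pr$x1, as.numeric(ste$X %*% f1), tolerance = 1e-12)
  expect_equal(pr$x2, as.numeric(ste$X %*% f2), tolerance = 1e-12)

  # rows equal to a unit-norm filter project to (1, <f1, f2>)
  u <- f1 / sqrt(sum(f1^2))
  rows <- structure(list(X = rbind(u, u), lags = seq(-7, 0), dt = 1,
                         spike_times = 1:2, n_dropped = 0L, stim_mean = 0,
                         centered = TRUE, tag = "toy"), class = "sdm_ste")
  pu <- project_ensemble(rows, u, f2)
  expect_equal(pu$x1, c(1, 1), tolerance = 1e-12)
  expect_equal(pu$x2, rep(sum(u * f2), 2), tolerance = 1e-12)

  expect_error(project_ensemble(ste, rnorm(5), f2), "lag grid")
})

test_that("STA is linear under ensemble concatenation", {
  a <- planted_ste(30, rep(0, 6), diag(6), seed = 10)
  b <- planted_ste(20, rep(1, 6), diag(6), seed = 11)
  ab <- a
  ab$X <- rbind(a$X, b$X)
  ab$spike_times <- c(a$spike_times, b$spike_times)
  pooled <- compute_sta(ab)$filter
  weighted <- (30 * compute_sta(a)$filter + 20 * compute_sta(b)$filter) / 50
  expect_equal(pooled, weighted, tolerance = 1e-12)
})

test_that("projections separate spike populations triggered by distinct
           features", {
  # planted instance: two spike populations, each triggered by a high
  # output of its own filter on a white-noise stimulus; the 2-D
  # projection must fall into two k-means-recoverable clusters
  set.seed(12)
  n <- 60000
  stim <- tibble::tibble(time = seq_len(n) - 1, current = rnorm(n))
  fA <- dnorm(seq(-19, 0), -10, 3); fA <- fA / sqrt(sum(fA^2))
  fB <- diff(dnorm(seq(-20, 0), -3, 1)); fB <- fB / sqrt(sum(fB^2))
  gA <- filter_stimulus(stim, fA, center = FALSE)$g
  gB <- filter_stimulus(stim, fB, center = FALSE)$g
  spA <- which(gA > quantile(gA, 0.995)); spA <- spA[spA > 20]
  spB <- which(gB > quantile(gB, 0.995)); spB <- spB[spB > 20]
  spikes <- c(spA, spB) - 1
  labs <- rep(c("A", "B"), c(length(spA), length(spB)))
  ste <- spike_triggered_matrix(stim, spikes, window = 20, center = FALSE)
  pr <- project_ensemble(ste, fA, fB)
  km <- kmeans(cbind(scale(pr$x1), scale(pr$x2)), centers = 2,
               nstart = 10)
  agree <- mean((km$cluster == 1) == (labs == "A"))
  expect_gt(max(agree, 1 - agree), 0.8)
})

test_that("sync and async clouds shift along the fast direction on the
           default simulation", {
  run <- default_run(1)
  sig <- run$stimulus$signals
  lab <- run$raster
  ste <- spike_triggered_matrix(sig, lab$time[lab$time > 100],
                                window = 100, lag_dt = 1)
  b <- run$filters
  pr <- project_ensemble(ste, b$nu1, b$nu2)
  labs <- lab$label[lab$time > 100]
  # synchronous spikes project higher on the event-edge direction
  expect_gt(mean(pr$x2[labs == "sync"]), mean(pr$x2[labs == "async"]))
  expect_gt(
    (mean(pr$x2[labs == "sync"]) - mean(pr$x2[labs == "async"])) /
      sd(pr$x2),
    0.25
  )
})
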