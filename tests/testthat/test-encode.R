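test_that("stimulus filtering matches the direct convolution sum", {
  set.seed(1)
  s <- rnorm(200)
  f <- rnorm(12)
  g <- filter_stimulus(s, f, dt = 1, center = FALSE)$g
  # direct O(N * L) oracle with zero-padded history
  L <- length(f)
  oracle <- vapply(seq_along(s), function(t) {
    acc <- 0
    for (l in seq_len(L)) {
      k <- t - L + l
      if (k >= 1) acc <- acc + f[l] * s[k]
    }
    acc
  }, numeric(1))
  expect_equal(g, oracle, tolerance = 1e-10)

  # long filters go through the FFT path; same answer
  f2 <- rnorm(100)
  g2 <- filter_stimulus(s, f2, dt = 1, center = FALSE)$g
  oracle2 <- vapply(seq_along(s), function(t) {
    ks <- (t - 100 + seq_len(100))
    ok <- ks >= 1
    sum(f2[ok] * s[ks[ok]])
  }, numeric(1))
  expect_equal(g2, oracle2, tolerance = 1e-8)

  # delta filter at lag zero is the identity
  delta <- c(rep(0, 9), 1)
  expect_equal(filter_stimulus(s, delta, dt = 1, center = FALSE)$g, s,
               tolerance = 1e-12)

  # constant stimulus: g = c * sum(f) once history fills
  cst <- filter_stimulus(rep(2, 50), f, dt = 1, center = FALSE)$g
  expect_equal(cst[L:50], rep(2 * sum(f), 50 - L + 1), tolerance = 1e-12)
})

test_that("raw nonlinearity estimation is a conditional mean", {
  set.seed(2)
  g <- rnorm(5000)

  # constant target: flat curve
  flat <- estimate_nonlinearity(g, rep(3, 5000), n_bins = 20)
  expect_true(all(abs(flat$y - 3) < 1e-12))

  # exact rectifier: curve reproduces it at bin centres
  y <- pmax(0, g)
  curve <- estimate_nonlinearity(g, y, n_bins = 50)
  expect_lt(max(abs(curve$y - pmax(0, curve$x))), 0.05)

  # shuffled target: flat at the grand mean within Monte-Carlo error
  ys <- sample(y)
  sh <- estimate_nonlinearity(g, ys, n_bins = 20)
  expect_lt(max(abs(sh$y - mean(y))), 5 * sd(y) / sqrt(250))

  expect_error(estimate_nonlinearity(g, y[-1]), "equal length")
  expect_error(estimate_nonlinearity(g, y, n_bins = 3), "at least 5")
})

test_that("parametric nonlinearities recover planted parameters", {
  set.seed(3)
  x <- seq(-1, 1, length.out = 400)

  # sigmoid max = 1, slope = 5, mid = 0.3 with small noise: within 10%
  y <- 1 / (1 + exp(-5 * (x - 0.3))) + rnorm(400, 0, 0.01)
  fit <- fit_static_nl(tibble::tibble(x = x, y = y), "sigmoid")
  expect_equal(unname(fit$par[["max"]]), 1, tolerance = 0.1)
  expect_equal(unname(fit$par[["slope"]]), 5, tolerance = 0.5)
  expect_equal(unname(fit$par[["mid"]]), 0.3, tolerance = 0.05)

  # rectifier y = max(0, 2 x): gain ~ 2, floor ~ 0
  y2 <- pmax(0, 2 * x) + rnorm(400, 0, 0.01)
  fit2 <- fit_static_nl(tibble::tibble(x = x, y = y2), "rectifier")
  expect_equal(unname(fit2$par[["gain"]]), 2, tolerance = 0.2)
  expect_lt(abs(fit2$par[["floor"]]), 0.05)

  # prediction composes with lnl_predict exactly
  st <- lnl_stream(tibble::tibble(lag = -3:0, filter = c(0, 0, 0, 1)), fit2)
  stim <- tibble::tibble(time = 0:99, current = rnorm(100))
  manual <- pmax(predict(fit2, filter_stimulus(stim, c(0, 0, 0, 1),
                                               dt = 1)$g), 0)
  expect_equal(lnl_predict(st, stim)$rate, manual, tolerance = 1e-12)
})

test_that("augmented-model weights are recovered and act linearly", {
  set.seed(4)
  n <- 20000
  dt <- 0.1
  tt <- seq(0, by = dt, length.out = n)
  a <- pmax(0, sdmux:::ou_trace(ou_params(50, 1, 1), n, dt))
  s <- pmax(0, sdmux:::ou_trace(ou_params(5, 0.5, 1), n, dt))
  target <- 0.7 * sdmux:::gauss_smooth(a, 5, dt) +
    0.3 * sdmux:::gauss_smooth(s, 2, dt)
  total <- tibble::tibble(time = tt, rate = target)
  rates <- list(async = tibble::tibble(time = tt, rate = a),
                sync = tibble::tibble(time = tt, rate = s))
  m <- fit_augmented(streams = list(async = NULL, sync = NULL),
                     total_psth = total, stream_rates = rates,
                     sigma_grid = c(0.5, 1, 2, 5, 10))
  expect_equal(unname(m$weights[["async"]]), 0.7, tolerance = 0.05 * 0.7)
  expect_equal(unname(m$weights[["sync"]]), 0.3, tolerance = 0.05 * 0.3)
  expect_equal(unname(m$sigmas), c(5, 2))

  # degenerate design: a silent sync stream leaves a univariate
  # regression for the async weight
  rates0 <- list(async = rates$async,
                 sync = tibble::tibble(time = tt, rate = rep(0, n)))
  suppressWarnings({
    m0 <- fit_augmented(streams = list(async = NULL, sync = NULL),
                        total_psth = total, stream_rates = rates0,
                        sigma_grid = c(5))
  })
  sa <- sdmux:::gauss_smooth(a, 5, dt)[seq_len(n / 2)]
  yy <- target[seq_len(n / 2)]
  expect_equal(unname(m0$weights[["async"]]), sum(sa * yy) / sum(sa^2),
               tolerance = 1e-6)

  # prediction is linear in the weights (exact superposition)
  m2 <- m
  m2$weights <- 2 * m$weights
  p1 <- predict_augmented(m)$rate
  p2 <- predict_augmented(m2)$rate
  expect_equal(p2, 2 * p1, tolerance = 1e-10)
  m3 <- m
  m3$weights[] <- 0
  expect_true(all(predict_augmented(m3)$rate == 0))
})

test_that("the Poisson GLM recovers planted filters from 20 s of counts", {
  set.seed(5)
  n <- 200000 # 20 s at dt = 0.1 ms
  g1 <- sdmux:::ou_trace(ou_params(100, 0, 1), n, 0.1)
  g2 <- sdmux:::ou_trace(ou_params(10, 0, 1), n, 0.1)
  beta <- c(-4.5, 0.8, 0.5)
  lam <- exp(beta[1] + beta[2] * g1 + beta[3] * g2)
  counts <- rpois(n, lam)
  raster <- new_raster_df(
    tibble::tibble(neuron = 1L,
                   time = rep((which(counts > 0) - 1) * 0.1,
                              counts[counts > 0])),
    n_neurons = 1, duration = 20000, dt = 0.1
  )
  stimdf <- tibble::tibble(time = seq(0, by = 0.1, length.out = n),
                           mixed = rnorm(n))
  fit <- fit_poisson_glm(
    stimdf, raster, filters = list(c(0, 1), c(0, 1)), train_frac = 0.5,
    g = list(tibble::tibble(g = g1), tibble::tibble(g = g2))
  )
  expect_equal(unname(fit$coefficients), beta, tolerance = 0.1)
  expect_gt(fit$log_lik, fit$null_log_lik)

  # intercept-only behaviour: with flat generators the predicted rate is
  # the mean count
  fit0 <- fit_poisson_glm(
    stimdf, raster, filters = list(c(0, 1), c(0, 1)), train_frac = 0.5,
    g = list(tibble::tibble(g = rep(0, n)), tibble::tibble(g = rep(0, n)))
  )
  expect_equal(mean(fit0$prediction$rate) * 1e-4,
               mean(counts[seq_len(n / 2)]), tolerance = 0.01)
})
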