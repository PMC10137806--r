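test_that("synaptic waveform peaks at 1 at the analytic peak time", {
  grid <- sdm_grid(dt = 0.1, duration = 100)
  w <- synaptic_waveform(0.5, 3, grid)

  expect_equal(max(w$w), 1, tolerance = 1e-6)
  expect_equal(w$w[1], 0)

  # analytic peak time against a dense grid-search maximisation oracle
  t_star <- 0.5 * 3 / (3 - 0.5) * log(3 / 0.5)
  tt <- seq(0, 10, by = 0.001)
  raw <- exp(-tt / 3) - exp(-tt / 0.5)
  expect_equal(t_star, tt[which.max(raw)], tolerance = 1e-2)
  expect_equal(w$time[which.max(w$w)], t_star, tolerance = 0.1)

  # truncated where amplitude is negligible
  expect_lt(tail(w$w, 1), 1e-5)
  expect_error(synaptic_waveform(3, 0.5), "tau_fall")
  expect_error(synaptic_waveform(1, 1), "tau_fall")
})

test_that("OU sampler has exact stationary moments and autocorrelation", {
  # noiseless process collapses to its mean
  grid <- sdm_grid(0.1, 100)
  flat <- gen_ou(ou_params(10, 3, 0), grid, seed = 1)
  expect_true(all(flat$current == 3))

  # slow-signal parameters over 100 s: mean within 15 +/- 3, sd within 10%
  long <- gen_ou(ou_params(100, 15, 60), sdm_grid(0.1, 1e5), seed = 2)
  expect_lt(abs(mean(long$current) - 15), 3)
  expect_lt(abs(sd(long$current) - 60) / 60, 0.1)

  # lag-tau autocorrelation ~ exp(-1), Monte-Carlo over 500 replicates
  tau <- 5; dt <- 0.5; n <- 4000; lag <- as.integer(tau / dt)
  set.seed(3) # one seed for the batch; replicates vary by RNG stream
  acs <- vapply(seq_len(500), function(s) {
    x <- sdmux:::ou_trace(ou_params(tau, 0, 1), n, dt)
    cor(x[seq_len(n - lag)], x[seq_len(n - lag) + lag])
  }, numeric(1))
  expect_equal(mean(acs), exp(-1), tolerance = 0.05)

  # seed determinism: bit-identical traces
  a <- gen_ou(ou_params(), grid, seed = 7)
  b <- gen_ou(ou_params(), grid, seed = 7)
  expect_identical(a, b)

  expect_error(ou_params(tau = -1), "tau")
  expect_error(ou_params(sigma = -1), "sigma")
})

test_that("fast-event trains are Poisson with unit-peak events", {
  grid <- sdm_grid(0.1, 20000)

  # rate 0: empty
  z <- gen_fast_train(fast_event_params(rate = 0), grid, seed = 1)
  expect_identical(z$event_times, numeric(0))
  expect_true(all(z$trace$current == 0))

  # isolated event peaks at a_fast = 85 pA
  one <- fast_event_params(rate = 1)
  tr <- sdmux:::fast_trace(5000, one, grid)
  expect_equal(max(tr), 85, tolerance = 85 * 0.01)

  # Poisson count statistics across 1000 seeds (coarse grid for speed)
  cg <- sdm_grid(1, 20000)
  counts <- vapply(seq_len(1000), function(s) {
    length(gen_fast_train(fast_event_params(), cg, seed = s)$event_times)
  }, numeric(1))
  expect_equal(mean(counts), 20, tolerance = 20 * 0.05)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)
})

test_that("mixed stimulus is exactly additive with independent noise", {
  grid <- sdm_grid(0.1, 20000)
  slow <- gen_ou(ou_params(100, 15, 60), grid, seed = 1)
  fast <- gen_fast_train(fast_event_params(), grid, seed = 2)
  stim <- make_mixed(slow, fast$trace, n_neurons = 4,
                     event_times = fast$event_times, seed = 3)

  expect_identical(stim$signals$mixed,
                   stim$signals$slow + stim$signals$fast)

  # noise traces: stated sd within 10%, pairwise correlation ~ 0
  sds <- apply(stim$noise, 2, sd)
  expect_true(all(abs(sds - 10) / 10 < 0.1))
  cors <- cor(stim$noise)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.05))

  # grid mismatch is an error
  short <- gen_ou(ou_params(), sdm_grid(0.1, 1000), seed = 1)
  expect_error(make_mixed(slow, short, n_neurons = 2), "grid")

  # zero fast signal: mixed equals slow
  zf <- gen_fast_train(fast_event_params(rate = 0), grid)
  stim0 <- make_mixed(slow, zf$trace, n_neurons = 1, seed = 1)
  expect_equal(stim0$signals$mixed, stim0$signals$slow)
})

test_that("stimulus bundles round-trip through delimited text", {
  stim <- tiny_stimulus(duration = 500, n_neurons = 3, seed = 5)
  stem <- file.path(withr::local_tempdir(), "stim")
  write_stimulus(stim, stem)
  back <- read_stimulus(stem)
  expect_equal(back$signals$mixed, stim$signals$mixed, tolerance = 1e-9)
  expect_equal(dim(back$noise), dim(stim$noise))
  expect_equal(back$event_times, stim$event_times, tolerance = 1e-9)
})
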