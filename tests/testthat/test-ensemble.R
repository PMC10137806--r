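test_that("gating functions evaluate to their half-activation identities", {
  p <- ml_params()
  g <- sdmux:::ml_gates(p$beta_m, p)
  expect_equal(g$m_inf, 0.5)
  g <- sdmux:::ml_gates(p$beta_w, p)
  expect_equal(g$w_inf, 0.5)
  expect_equal(g$tau_w, 1)

  expect_error(ml_params(g_Na = -1), "non-negative")
  expect_error(ml_params(C = 0), "positive")
})

test_that("resting potential matches a long settling simulation", {
  p <- ml_params()
  v_root <- sdmux:::ml_rest(p, I_input = 0)
  # settle the ODE for 2 s with zero input and no noise
  grid <- sdm_grid(0.1, 2000)
  zero <- tibble::tibble(time = grid$time, current = rep(0, grid$n_steps))
  stim <- make_mixed(zero, zero, n_neurons = 1,
                     noise_params = ou_params(5, 0, 0))
  r <- simulate_ensemble(stim, p, keep_voltage = TRUE)
  v_settled <- tail(attr(r, "voltage")[, 1], 1)
  expect_lt(abs(v_root - v_settled), 0.1)
  expect_equal(nrow(r), 0L) # quiescent at rest: no spikes
})

test_that("step current above rheobase drives repetitive spiking that
           converges under step halving", {
  p <- ml_params()
  mk <- function(dt) {
    grid <- sdm_grid(dt, 3000)
    step <- tibble::tibble(time = grid$time,
                           current = rep(150, grid$n_steps))
    zero <- tibble::tibble(time = grid$time,
                           current = rep(0, grid$n_steps))
    stim <- make_mixed(step, zero, n_neurons = 1,
                       noise_params = ou_params(5, 0, 0))
    nrow(simulate_ensemble(stim, p))
  }
  n1 <- mk(0.1)
  n2 <- mk(0.05)
  expect_gt(n1, 10)
  expect_lt(abs(n1 - n2) / n2, 0.05)
})

test_that("spike detection matches a direct scan with refractoriness", {
  # synthetic trace with 3 well-separated crossings
  v <- rep(-60, 1000)
  for (i in c(100, 400, 800)) v[i + (0:5)] <- 20
  got <- detect_spikes(v, threshold = 0, refractory = 2, dt = 0.1)
  scan <- which(v[-1] >= 0 & v[-length(v)] < 0) * 0.1
  expect_equal(got, scan)
  expect_length(got, 3)

  # two crossings 1 ms apart with a 2 ms refractory yield one spike
  v2 <- rep(-60, 100)
  v2[20 + (0:2)] <- 10
  v2[30 + (0:2)] <- 10
  expect_length(detect_spikes(v2, 0, refractory = 2, dt = 0.1), 1)
  expect_length(detect_spikes(v2, 0, refractory = 0.5, dt = 0.1), 2)

  expect_identical(detect_spikes(rep(-60, 50)), numeric(0))
  expect_error(detect_spikes(c(0, NA)), "finite")
})

test_that("the ensemble is homogeneous: permuting noise permutes the raster", {
  stim <- tiny_stimulus(duration = 1500, n_neurons = 4, seed = 9)
  perm <- c(3, 1, 4, 2)
  stim_p <- stim
  stim_p$noise <- stim$noise[, perm]
  r <- simulate_ensemble(stim)
  rp <- simulate_ensemble(stim_p)
  for (j in seq_along(perm)) {
    expect_equal(rp$time[rp$neuron == j], r$time[r$neuron == perm[j]])
  }
})

test_that("ensemble simulation is deterministic and responds to events", {
  stim <- tiny_stimulus(duration = 4000, n_neurons = 8, seed = 11)
  r1 <- simulate_ensemble(stim)
  r2 <- simulate_ensemble(stim)
  expect_identical(r1$time, r2$time)
  expect_true(all(diff(r1$time[r1$neuron == r1$neuron[1]]) >= 2))
  expect_true(all(r1$time >= 0 & r1$time <= 4000))
})

test_that("rasters round-trip through delimited text", {
  stim <- tiny_stimulus(duration = 1000, n_neurons = 3, seed = 2)
  r <- simulate_ensemble(stim)
  stem <- file.path(withr::local_tempdir(), "ras")
  write_raster(r, stem)
  back <- read_raster(stem)
  expect_equal(back$time, r$time, tolerance = 1e-9)
  expect_equal(attr(back, "n_neurons"), attr(r, "n_neurons"))
})
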