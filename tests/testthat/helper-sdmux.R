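# shared fixtures; heavier runs are memoised so several test files can
# reuse the same simulation

.sdmux_cache <- new.env(parent = emptyenv())

# full-size reference run (30 neurons, 20 s) under package defaults
default_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.sdmux_cache[[key]])) {
    .sdmux_cache[[key]] <- run_pipeline(sdm_config(seed = seed))
  }
  .sdmux_cache[[key]]
}

# small, fast stimulus for unit tests
tiny_stimulus <- function(duration = 2000, n_neurons = 5, seed = 42,
                          dt = 0.1) {
  simulate_stimulus(sdm_grid(dt, duration), n_neurons = n_neurons,
                    seed = seed)
}

# deterministic toy spike-triggered ensemble from a planted Gaussian
planted_ste <- function(n_spikes, mu, Lambda, seed = 1) {
  n <- length(mu)
  ec <- eigen(Lambda, symmetric = TRUE)
  sq <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0))) %*% t(ec$vectors)
  X <- withr::with_seed(seed, matrix(rnorm(n_spikes * n), n_spikes, n)) %*%
    sq + matrix(mu, n_spikes, n, byrow = TRUE)
  structure(
    list(X = X, lags = seq(-(n - 1), 0), dt = 1,
         spike_times = seq_len(n_spikes), n_dropped = 0L,
         stim_mean = 0, centered = TRUE, tag = "toy"),
    class = "sdm_ste"
  )
}
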