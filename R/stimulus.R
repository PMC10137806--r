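#' Ornstein-Uhlenbeck process parameters
#'
#' Parameter bundle for a mean-reverting Gaussian (Ornstein-Uhlenbeck)
#' current. The slow component of the mixed stimulus uses
#' `tau = 100` ms, `mu = 15` pA, `sigma = 60` pA; the per-neuron
#' background noise uses `tau = 5` ms, `mu = 0` pA, `sigma = 10` pA.
#'
#' @param tau Relaxation time constant (ms), positive.
#' @param mu Stationary mean (pA).
#' @param sigma Stationary standard deviation (pA), non-negative.
#' @return A list of class `ou_params`.
#' @examples
#' ou_params()              # slow-signal defaults
#' ou_params(5, 0, 10)      # background-noise defaults
#' @export
ou_params <- function(tau = 100, mu = 15, sigma = 60) {
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive (ms).")
  if (!is.numeric(sigma) || sigma < 0) abort("`sigma` must be non-negative (pA).")
  structure(list(tau = tau, mu = mu, sigma = sigma), class = "ou_params")
}

#' Fast synaptic event parameters
#'
#' Sparse, abrupt stimulus transients: Poisson-timed synaptic waveforms
#' (difference of exponentials, peak-normalised) scaled to `amplitude`.
#'
#' @param rate Event rate (Hz), non-negative.
#' @param amplitude Peak amplitude of each isolated event (pA).
#' @param tau_rise,tau_fall Rise and fall time constants (ms); requires
#'   `tau_fall > tau_rise > 0`.
#' @return A list of class `fast_event_params`.
#' @export
fast_event_params <- function(rate = 1, amplitude = 85,
                              tau_rise = 0.5, tau_fall = 3) {
  if (!is.numeric(rate) || rate < 0) abort("`rate` must be non-negative (Hz).")
  if (!is.numeric(tau_rise) || !is.numeric(tau_fall) ||
      tau_rise <= 0 || tau_fall <= tau_rise) {
    abort("Require `tau_fall > tau_rise > 0` (ms).")
  }
  structure(
    list(rate = rate, amplitude = amplitude,
         tau_rise = tau_rise, tau_fall = tau_fall),
    class = "fast_event_params"
  )
}

#' Peak-normalised double-exponential synaptic waveform
#'
#' \eqn{w(t) \propto e^{-t/\tau_{fall}} - e^{-t/\tau_{rise}}}, rescaled so
#' the maximum is exactly 1, sampled on the grid's time step and truncated
#' where the amplitude falls below `1e-6` of the peak. The analytic peak
#' time is \eqn{t^* = \tau_r \tau_f / (\tau_f - \tau_r) \log(\tau_f/\tau_r)}.
#'
#' @param tau_rise,tau_fall Time constants (ms), `tau_fall > tau_rise > 0`.
#' @param grid A [sdm_grid()]; only `dt` is used.
#' @return A tibble with columns `time` and `w`.
#' @examples
#' w <- synaptic_waveform(0.5, 3, sdm_grid(dt = 0.1, duration = 100))
#' max(w$w)  # 1
#' @export
synaptic_waveform <- function(tau_rise = 0.5, tau_fall = 3,
                              grid = sdm_grid()) {
  if (!is.numeric(tau_rise) || !is.numeric(tau_fall) ||
      tau_rise <= 0 || tau_fall <= tau_rise) {
    abort("Require `tau_fall > tau_rise > 0` (ms).")
  }
  dt <- grid$dt
  t_peak <- tau_rise * tau_fall / (tau_fall - tau_rise) * log(tau_fall / tau_rise)
  peak <- exp(-t_peak / tau_fall) - exp(-t_peak / tau_rise)
  # beyond the peak the waveform decays like exp(-t/tau_fall)/peak
  t_max <- -tau_fall * log(1e-6 * peak)
  tt <- seq(0, t_max, by = dt)
  w <- exp(-tt / tau_fall) - exp(-tt / tau_rise)
  w <- w / max(w) # unit peak on the sampling grid
  keep <- w >= 1e-6 | tt <= t_peak
  tibble(time = tt[keep], w = w[keep])
}

#' Sample an Ornstein-Uhlenbeck current trace
#'
#' Uses the exact stationary discretisation
#' \eqn{x_{t+dt} = \mu + (x_t - \mu) e^{-dt/\tau} +
#' \sigma \sqrt{1 - e^{-2 dt/\tau}}\,\xi}, which has the exact OU
#' stationary mean, variance and autocorrelation at any step size.
#' The chain is initialised at `mu`.
#'
#' @param params An [ou_params()] bundle.
#' @param grid A [sdm_grid()].
#' @param seed Optional integer seed; when given, the RNG state is
#'   restored afterwards.
#' @return A tibble with columns `time` and `current` (pA).
#' @examples
#' x <- gen_ou(ou_params(100, 15, 60), sdm_grid(0.1, 1000), seed = 1)
#' @export
gen_ou <- function(params = ou_params(), grid = sdm_grid(), seed = NULL) {
  stopifnot(inherits(params, "ou_params"))
  draw <- function() ou_trace(params, grid$n_steps, grid$dt)
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(time = grid$time, current = x)
}

# raw OU vector; AR(1) recursion runs in C via stats::filter
ou_trace <- function(params, n, dt, x0 = params$mu) {
  if (params$sigma == 0) return(rep(params$mu, n))
  f <- ou_ar1(params$tau, params$sigma, dt)
  eps <- rnorm(n) * f$b
  # x_k - mu = a (x_{k-1} - mu) + eps_k, x_0 = x0
  dev <- stats::filter(eps, f$a, method = "recursive", init = x0 - params$mu)
  as.numeric(dev) + params$mu
}

#' Generate the sparse fast-event current
#'
#' Draws homogeneous-Poisson event times in continuous time, snaps them to
#' the nearest grid point, and convolves the resulting delta train with the
#' peak-normalised synaptic waveform so that each isolated event peaks at
#' `params$amplitude`. Overlapping events superpose linearly.
#'
#' @param params A [fast_event_params()] bundle.
#' @param grid A [sdm_grid()].
#' @param seed Optional integer seed.
#' @return A list with `trace` (tibble `time`, `current`) and
#'   `event_times` (ms, sorted).
#' @export
gen_fast_train <- function(params = fast_event_params(), grid = sdm_grid(),
                           seed = NULL) {
  stopifnot(inherits(params, "fast_event_params"))
  draw <- function() {
    n_ev <- rpois(1, params$rate * grid$duration / 1000)
    sort(runif(n_ev, 0, grid$duration))
  }
  events <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  trace <- fast_trace(events, params, grid)
  list(trace = tibble(time = grid$time, current = trace), event_times = events)
}

fast_trace <- function(events, params, grid) {
  x <- numeric(grid$n_steps)
  if (length(events)) {
    idx <- pmin(pmax(round(events / grid$dt) + 1L, 1L), grid$n_steps)
    for (i in idx) x[i] <- x[i] + 1
    w <- synaptic_waveform(params$tau_rise, params$tau_fall, grid)$w
    # causal convolution: an event contributes from its own bin onward;
    # pad the front so early bins are defined
    nw <- length(w)
    padded <- as.numeric(stats::filter(c(numeric(nw - 1L), x), w, sides = 1))
    x <- padded[nw:(nw + grid$n_steps - 1L)]
  }
  x * params$amplitude
}

#' Assemble the mixed stimulus and per-neuron noise
#'
#' The mixed signal is the elementwise sum of the slow and fast traces;
#' each of `n_neurons` receives an additional private OU noise current.
#'
#' @param slow,fast Tibbles with `time` and `current` on a shared grid
#'   (as returned by [gen_ou()] and [gen_fast_train()]).
#' @param n_neurons Ensemble size.
#' @param noise_params [ou_params()] for the private noise
#'   (default tau = 5 ms, mu = 0, sigma = 10 pA).
#' @param event_times Optional event times carried through for provenance.
#' @param seed Optional integer seed for the noise draws.
#' @return An object of class `sdm_stimulus`: a list with `signals`
#'   (tibble `time`, `slow`, `fast`, `mixed`), `noise` (matrix, one column
#'   per neuron), `event_times`, `grid`, and the parameter bundles used.
#' @export
make_mixed <- function(slow, fast, n_neurons = 30,
                       noise_params = ou_params(5, 0, 10),
                       event_times = numeric(), seed = NULL) {
  if (!identical(nrow(slow), nrow(fast)) ||
      max(abs(slow$time - fast$time)) > 1e-9) {
    abort("`slow` and `fast` must share one time grid.")
  }
  grid <- infer_grid(slow$time)
  draw <- function() {
    vapply(seq_len(n_neurons),
           function(i) ou_trace(noise_params, grid$n_steps, grid$dt,
                                x0 = noise_params$mu),
           numeric(grid$n_steps))
  }
  noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  mixed <- slow$current + fast$current
  structure(
    list(
      signals = tibble(
        time = slow$time,
        slow = slow$current,
        fast = fast$current,
        mixed = mixed
      ),
      noise = noise,
      event_times = event_times,
      grid = grid,
      noise_params = noise_params,
      seed = seed
    ),
    class = "sdm_stimulus"
  )
}

#' Generate the default mixed stimulus in one call
#'
#' Convenience wrapper: slow OU signal plus Poisson fast events plus
#' per-neuron OU noise, all from one seed.
#'
#' @param grid A [sdm_grid()].
#' @param slow_params,noise_params [ou_params()] bundles.
#' @param fast_params A [fast_event_params()] bundle.
#' @param n_neurons Ensemble size.
#' @param seed Integer seed (required for reproducibility).
#' @return An `sdm_stimulus` object, see [make_mixed()].
#' @examples
#' stim <- simulate_stimulus(sdm_grid(0.1, 2000), n_neurons = 5, seed = 1)
#' @export
simulate_stimulus <- function(grid = sdm_grid(),
                              slow_params = ou_params(100, 15, 60),
                              fast_params = fast_event_params(),
                              noise_params = ou_params(5, 0, 10),
                              n_neurons = 30, seed = 1) {
  seeds <- child_seeds(seed, 3)
  slow <- gen_ou(slow_params, grid, seed = seeds[1])
  fast <- gen_fast_train(fast_params, grid, seed = seeds[2])
  stim <- make_mixed(slow, fast$trace, n_neurons = n_neurons,
                     noise_params = noise_params,
                     event_times = fast$event_times, seed = seeds[3])
  stim$slow_params <- slow_params
  stim$fast_params <- fast_params
  stim$seed <- seed
  stim
}

# deterministic per-stage child seeds below 2^31
child_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000003L) * 1009L + seq_len(n) * 7919L
}

#' @export
as_tibble.sdm_stimulus <- function(x, ...) x$signals

#' @export
print.sdm_stimulus <- function(x, ...) {
  cat(sprintf(
    "<sdm_stimulus> %.1f ms at dt = %g ms, %d neurons, %d fast events\n",
    x$grid$duration, x$grid$dt, ncol(x$noise), length(x$event_times)
  ))
  print(x$signals, n = 5)
  invisible(x)
}

#' Write / read a stimulus bundle as delimited text
#'
#' `write_stimulus()` writes `<stem>_signals.tsv` (time, slow, fast,
#' mixed), `<stem>_noise.tsv` (one column per neuron) and a JSON sidecar
#' `<stem>_meta.json` with parameters, event times and seed.
#' `read_stimulus()` reads the bundle back.
#'
#' @param stim An `sdm_stimulus`.
#' @param stem Path stem (no extension).
#' @return `write_stimulus()` returns `stem` invisibly; `read_stimulus()`
#'   returns an `sdm_stimulus`.
#' @export
write_stimulus <- function(stim, stem) {
  write.table(stim$signals, paste0(stem, "_signals.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(stim$noise), paste0(stem, "_noise.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    dt = stim$grid$dt, duration = stim$grid$duration,
    event_times = stim$event_times,
    noise_params = unclass(stim$noise_params),
    slow_params = if (!is.null(stim$slow_params)) unclass(stim$slow_params),
    fast_params = if (!is.null(stim$fast_params)) unclass(stim$fast_params),
    seed = stim$seed
  )
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(stem) {
  signals <- as_tibble(read.table(paste0(stem, "_signals.tsv"),
                                  header = TRUE, sep = "\t"))
  noise <- as.matrix(read.table(paste0(stem, "_noise.tsv"),
                                header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  structure(
    list(
      signals = signals,
      noise = unname(noise),
      event_times = as.numeric(meta$event_times %||% numeric()),
      grid = sdm_grid(meta$dt, meta$duration),
      noise_params = do.call(ou_params, as.list(meta$noise_params)),
      seed = meta$seed
    ),
    class = "sdm_stimulus"
  )
}
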