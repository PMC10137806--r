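# internal helpers shared across modules

#' Define a simulation time grid
#'
#' All traces produced by one run of the toolkit live on a single regular
#' time grid. Times are in milliseconds throughout the package.
#'
#' @param dt Time step (ms). Must be positive.
#' @param duration Total duration (ms). Must be a positive multiple of `dt`
#'   (up to rounding).
#' @return A list with elements `dt`, `duration`, `n_steps`, and `time`
#'   (vector of bin start times, beginning at 0).
#' @examples
#' g <- sdm_grid(dt = 0.1, duration = 100)
#' g$n_steps
#' @export
sdm_grid <- function(dt = 0.1, duration = 20000) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort("`dt` must be a single positive number (ms).")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a single positive number (ms).")
  }
  n_steps <- as.integer(round(duration / dt))
  list(
    dt = dt,
    duration = n_steps * dt,
    n_steps = n_steps,
    time = seq(0, by = dt, length.out = n_steps)
  )
}

# infer a grid from a time column; errors if irregular
infer_grid <- function(time, tol = 1e-8) {
  if (length(time) < 2) abort("Need at least two time points to infer a grid.")
  dts <- diff(time)
  dt <- median(dts)
  if (any(abs(dts - dt) > tol * max(1, dt))) {
    abort("`time` column is not a regular grid.")
  }
  sdm_grid(dt = dt, duration = length(time) * dt)
}

# stationary-exact AR(1) update factors for an OU process
ou_ar1 <- function(tau, sigma, dt) {
  a <- exp(-dt / tau)
  list(a = a, b = sigma * sqrt(1 - a^2))
}

# Gaussian smoothing of a regularly sampled trace; kernel normalised to
# unit mass in continuous time (sum(k) * dt == 1). Zero-padded ends.
gauss_smooth <- function(x, sigma, dt) {
  if (sigma <= 0) abort("`sigma` must be positive (ms).")
  half <- max(1L, ceiling(4 * sigma / dt))
  tk <- seq(-half, half) * dt
  k <- exp(-0.5 * (tk / sigma)^2)
  k <- k / (sum(k) * dt)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  out <- filter_fft(xp, k)
  out[(half + 1):(half + n)]
}

# linear convolution via FFT, aligned so that out[i] = sum_j k[j] * x[i + j - half - 1]
# with k centred (odd length). Used by gauss_smooth only.
filter_fft <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1L, 2)
  X <- fft(c(x, numeric(m - n)))
  K <- fft(c(k, numeric(m - length(k))))
  full <- Re(fft(X * K, inverse = TRUE)) / m
  full[(half + 1L):(half + n)]
}

# causal convolution with zero-padded history via FFT:
# out[t] = sum_l f[l] * s[t - L + l], f ordered oldest lag first
causal_conv_fft <- function(s, f) {
  n <- length(s)
  L <- length(f)
  m <- stats::nextn(n + L - 1L, 2)
  S <- fft(c(numeric(L - 1L), s, numeric(m - n - L + 1L)))
  FK <- fft(c(rev(f), numeric(m - L)))
  full <- Re(fft(S * FK, inverse = TRUE)) / m
  full[L:(L + n - 1L)]
}

# map spike times onto 1-based grid bins, robust to float division
time_bin <- function(times, dt, n_bins) {
  pmin(pmax(floor(times / dt + 1e-9) + 1L, 1L), n_bins)
}

# split row indices into train (first frac) and test (rest)
split_interval <- function(n, train_frac = 0.5) {
  n_train <- floor(n * train_frac)
  list(train = seq_len(n_train), test = seq.int(n_train + 1L, n))
}
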