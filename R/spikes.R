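#' Kernel-smoothed population firing rate (PSTH)
#'
#' Pools spikes over neurons, bins them on the raster's time grid and
#' convolves with a Gaussian kernel of width `sigma`. With
#' `normalization = "per_neuron"` (default) the result is the
#' instantaneous rate per neuron in spikes/s, so that
#' `sum(rate) * dt/1000 * n_neurons` equals the total spike count
#' (up to edge truncation of the kernel). `"population"` keeps the
#' pooled rate in spikes/s; `"peak"` rescales to maximum 1.
#'
#' @param raster An `sdm_raster` tibble (`neuron`, `time`), or any tibble
#'   with a `time` column; attributes `dt`, `duration`, `n_neurons` are
#'   used when present.
#' @param sigma Kernel standard deviation (ms), positive.
#' @param normalization One of `"per_neuron"`, `"population"`, `"peak"`.
#' @param dt,duration,n_neurons Overrides for rasters without attributes.
#' @return A tibble `time`, `rate` with attributes `sigma` and
#'   `normalization` (class `sdm_rate`).
#' @examples
#' r <- new_raster_df(tibble::tibble(neuron = 1L, time = 50), 1, 100, 0.1)
#' psth <- kernel_rate(r, sigma = 1)
#' @export
kernel_rate <- function(raster, sigma = 1, normalization = "per_neuron",
                        dt = NULL, duration = NULL, n_neurons = NULL) {
  normalization <- arg_match(normalization,
                             c("per_neuron", "population", "peak"))
  meta <- raster_meta(raster)
  dt <- dt %||% meta$dt
  duration <- duration %||% meta$duration
  n_neurons <- n_neurons %||% meta$n_neurons
  grid <- sdm_grid(dt, duration)
  counts <- bin_spikes(raster$time, grid)
  rate <- gauss_smooth(counts, sigma, dt) * 1000 # spikes/ms -> spikes/s
  rate <- pmax(rate, 0)
  rate <- switch(normalization,
    per_neuron = rate / max(n_neurons, 1L),
    population = rate,
    peak = if (max(rate) > 0) rate / max(rate) else rate
  )
  out <- tibble(time = grid$time, rate = rate)
  attr(out, "sigma") <- sigma
  attr(out, "normalization") <- normalization
  attr(out, "n_neurons") <- n_neurons
  class(out) <- c("sdm_rate", class(out))
  out
}

# spike counts per grid bin (bin i covers [t_i, t_i + dt))
bin_spikes <- function(times, grid) {
  counts <- numeric(grid$n_steps)
  if (length(times)) {
    idx <- time_bin(times, grid$dt, grid$n_steps)
    counts <- as.numeric(tabulate(idx, nbins = grid$n_steps))
  }
  counts
}

#' Construct a raster tibble from scratch
#'
#' Convenience constructor for tests and user-supplied spike data.
#'
#' @param df Tibble/data frame with columns `neuron`, `time` (ms).
#' @param n_neurons,duration,dt Grid metadata.
#' @return An `sdm_raster`.
#' @export
new_raster_df <- function(df, n_neurons, duration, dt = 0.1) {
  new_raster(df, n_neurons = n_neurons, duration = duration, dt = dt)
}

#' Default synchrony threshold on the narrow-kernel rate
#'
#' The classification threshold is expressed as the narrow-kernel
#' population rate reached when `n_cofire` of the `n_neurons` neurons
#' fire coincidently: each such spike contributes its kernel peak
#' `dnorm(0) / sigma` spikes/ms, so the threshold is
#' `n_cofire * dnorm(0)/sigma * 1000 / n_neurons` in per-neuron
#' spikes/s. The default `n_cofire = n_neurons / 2` asks for half the
#' ensemble: under common slow drive a homogeneous ensemble also
#' produces loose rate volleys when the input crosses rheobase, and a
#' lower bar (e.g. 30 percent of the ensemble) labels many of those
#' common-drive spikes as synchronous.
#'
#' @param n_cofire Number of coincident neurons deemed synchronous
#'   (default: half the ensemble).
#' @param n_neurons Ensemble size.
#' @param sigma Narrow kernel width (ms).
#' @return Threshold rate (spikes/s per neuron).
#' @export
synchrony_threshold <- function(n_cofire = n_neurons / 2, n_neurons = 30,
                                sigma = 1) {
  n_cofire * dnorm(0) / sigma * 1000 / n_neurons
}

#' Classify spikes as synchronous or asynchronous
#'
#' Computes the narrow-kernel population rate and labels every spike that
#' falls in a bin where the rate is at or above `threshold` as
#' synchronous; all other spikes are asynchronous. The two sets partition
#' the raster by construction, and labels are kept for all downstream
#' analyses.
#'
#' @param raster An `sdm_raster`.
#' @param narrow_sigma Narrow kernel width (ms); 1 ms by default.
#' @param threshold Rate threshold (spikes/s per neuron), or `"auto"` to
#'   use [synchrony_threshold()] with the raster's ensemble size.
#' @param n_cofire Co-firing count used when `threshold = "auto"`;
#'   default half the ensemble.
#' @return The raster with an added factor column `label`
#'   (`"sync"`/`"async"`); attributes `threshold` and `narrow_sigma`
#'   record the rule used.
#' @export
classify_synchrony <- function(raster, narrow_sigma = 1, threshold = "auto",
                               n_cofire = NULL) {
  meta <- raster_meta(raster)
  if (identical(threshold, "auto")) {
    n_cofire <- n_cofire %||% (meta$n_neurons / 2)
    threshold <- synchrony_threshold(n_cofire, meta$n_neurons, narrow_sigma)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be a positive rate (spikes/s per neuron).")
  }
  rate <- kernel_rate(raster, sigma = narrow_sigma,
                      normalization = "per_neuron")
  grid <- sdm_grid(meta$dt, meta$duration)
  idx <- time_bin(raster$time, grid$dt, grid$n_steps)
  lab <- ifelse(rate$rate[idx] >= threshold, "sync", "async")
  out <- raster
  out$label <- factor(lab, levels = c("sync", "async"))
  attr(out, "threshold") <- threshold
  attr(out, "narrow_sigma") <- narrow_sigma
  out
}

# pull the spike times of one class from a labelled raster
class_spikes <- function(labelled, which = c("all", "sync", "async")) {
  which <- match.arg(which)
  if (which == "all") return(labelled$time)
  if (is.null(labelled$label)) abort("Raster has no `label` column.")
  labelled$time[labelled$label == which]
}

#' Write a labelled raster
#'
#' Same layout as [write_raster()]; the `label` column is included when
#' present.
#'
#' @param labelled A labelled raster from [classify_synchrony()].
#' @param stem Path stem.
#' @export
write_classification <- function(labelled, stem) {
  write_raster(labelled, stem)
}
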