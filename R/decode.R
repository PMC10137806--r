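#' Linear stimulus reconstruction from spike trains
#'
#' Convolves each spike set with its temporal filter (the filter's lag
#' structure places the estimate in the pre-spike window, i.e. the
#' contribution of a spike at time \eqn{t_s} to the reconstruction at
#' time \eqn{t \le t_s} is the filter value at lag \eqn{t - t_s}), then
#' fits mixing weights to the original trace by least squares on the
#' training interval. Scores (Pearson r, RMSE, MAE) are reported on the
#' test interval.
#'
#' @param spike_sets Named list of spike-time vectors (ms); one stream
#'   per element.
#' @param filters Named list (same names) of filters
#'   (tibble `lag` + value column); lags must be a regular grid.
#' @param original Tibble `time` + signal column (`mixed`/`current`) on
#'   the reconstruction grid.
#' @param train_frac Fraction of initial samples used to fit weights.
#' @param signal Column of `original` to reconstruct.
#' @param method Free-form tag stored in the result.
#' @return Object of class `sdm_reconstruction`: `trace` (tibble `time`,
#'   `original`, `reconstructed`), `weights`, `scores` (tibble split x
#'   r/rmse/mae), `method`.
#' @export
reconstruct_signal <- function(spike_sets, filters, original,
                               train_frac = 0.5, signal = NULL,
                               method = "custom") {
  sig_col <- signal %||%
    (if ("mixed" %in% names(original)) "mixed" else "current")
  y <- original[[sig_col]]
  grid <- infer_grid(original$time)
  if (!identical(names(spike_sets), names(filters))) {
    # allow unnamed positional matching
    if (length(spike_sets) != length(filters)) {
      abort("`spike_sets` and `filters` must match one-to-one.")
    }
  }
  streams <- purrr::map2(spike_sets, filters, function(sp, f) {
    reconstruct_stream(sp, f, grid)
  })
  A <- do.call(cbind, streams)
  nz <- apply(A, 2, function(col) any(col != 0))
  idx <- split_interval(grid$n_steps, train_frac)
  w <- numeric(ncol(A))
  if (any(nz)) {
    w[nz] <- as.numeric(ls_weights(A[idx$train, nz, drop = FALSE],
                                   y[idx$train]))
  }
  rec <- as.numeric(A %*% w)
  scores <- purrr::map_dfr(
    list(train = idx$train, test = idx$test),
    function(ii) {
      tibble(
        r = if (sd(rec[ii]) > 0) cor(rec[ii], y[ii]) else NA_real_,
        rmse = sqrt(mean((rec[ii] - y[ii])^2)),
        mae = mean(abs(rec[ii] - y[ii]))
      )
    },
    .id = "split"
  )
  structure(
    list(
      trace = tibble(time = original$time, original = y,
                     reconstructed = rec),
      weights = setNames(w, names(streams)),
      scores = scores,
      method = method,
      train_frac = train_frac
    ),
    class = "sdm_reconstruction"
  )
}

# spike train convolved with a lag filter: filter column ordered oldest
# lag (most negative) to lag 0; a spike contributes f(lag) at t_s + lag
reconstruct_stream <- function(spikes, f, grid) {
  fv <- filter_vec(f)
  if (is.data.frame(f) && "lag" %in% names(f) &&
      abs(infer_grid(f$lag)$dt - grid$dt) > 1e-9) {
    abort("Filter lag step must match the reconstruction grid.")
  }
  x <- bin_spikes(spikes, grid)
  L <- length(fv)
  # acausal: out[t] = sum_l f[l] * x[t + L - l] (a spike in the near
  # future projects back through its pre-spike filter)
  padded <- as.numeric(stats::filter(c(x, numeric(L - 1L)), fv, sides = 1))
  out <- padded[(L - 1L) + seq_len(grid$n_steps)]
  out[is.na(out)] <- 0
  out
}

#' @export
print.sdm_reconstruction <- function(x, ...) {
  te <- x$scores[x$scores$split == "test", ]
  cat(sprintf("<sdm_reconstruction> %s: test r = %.3f, rmse = %.3f\n",
              x$method, te$r, te$rmse))
  invisible(x)
}

#' PSTH prediction error metrics
#'
#' Mean absolute error and root mean squared error between a predicted
#' and an observed rate over an index interval.
#'
#' @param predicted,observed Rate tibbles (`time`, `rate`) on a shared
#'   grid, or bare numeric vectors.
#' @param interval Integer index vector (default: all samples).
#' @return Tibble with `mae`, `rmse`, `n`.
#' @export
score_psth <- function(predicted, observed, interval = NULL) {
  p <- if (is.data.frame(predicted)) predicted$rate else as.numeric(predicted)
  o <- if (is.data.frame(observed)) observed$rate else as.numeric(observed)
  if (length(p) != length(o)) abort("Traces must share one grid.")
  interval <- interval %||% seq_along(p)
  d <- p[interval] - o[interval]
  tibble(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), n = length(interval))
}
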