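#' Filter a stimulus with a temporal lag filter
#'
#' Causal convolution: the generator signal at time `t` is the inner
#' product of the filter with the stimulus slice over
#' `[t - window, t]`, exactly matching the row convention of
#' [spike_triggered_matrix()]. The first `n_lags - 1` samples, where the
#' window would extend before the recording, use zero-padded history.
#'
#' @param stimulus Tibble with `time` and a signal column (`mixed` or
#'   `current`, or pass `signal`); or a bare numeric vector with `dt`.
#' @param filter Filter as returned by [compute_sta()] (tibble with
#'   `lag` + value column) or a numeric vector ordered oldest lag first.
#' @param signal Stimulus column name.
#' @param dt Sample step (ms) when `stimulus` is a bare vector.
#' @param center Subtract the stimulus mean before filtering, matching
#'   the centred spike-triggered ensemble (default TRUE).
#' @return Tibble `time`, `g`.
#' @export
filter_stimulus <- function(stimulus, filter, signal = NULL, dt = NULL,
                            center = TRUE) {
  if (is.numeric(stimulus)) {
    s <- stimulus
    if (is.null(dt)) abort("Provide `dt` for a bare numeric stimulus.")
    tt <- seq(0, by = dt, length.out = length(s))
  } else {
    sig_col <- signal %||%
      (if ("mixed" %in% names(stimulus)) "mixed" else "current")
    s <- stimulus[[sig_col]]
    tt <- stimulus$time
    dt <- infer_grid(tt)$dt
  }
  f <- filter_vec(filter)
  if (is.data.frame(filter) && "lag" %in% names(filter)) {
    f_dt <- infer_grid(filter$lag)$dt
    if (abs(f_dt - dt) > 1e-9) {
      abort("Filter and stimulus must share one time step.")
    }
  }
  if (center) s <- s - mean(s)
  L <- length(f)
  g <- if (L > 64L) causal_conv_fft(s, f) else {
    padded <- as.numeric(stats::filter(c(numeric(L - 1L), s), rev(f),
                                       sides = 1))
    padded[L:(L + length(s) - 1L)]
  }
  tibble(time = tt, g = g)
}

#' Raw (binned) static nonlinearity estimate
#'
#' Quantile-bins the generator signal `g` and returns the conditional
#' mean of the observed rate in each bin: the nonparametric estimate of
#' the static nonlinearity mapping filtered stimulus to firing rate.
#'
#' @param g Generator signal: tibble from [filter_stimulus()] or vector.
#' @param psth Observed rate: `sdm_rate` tibble or vector, same length.
#' @param n_bins Number of quantile bins (at least 5).
#' @return Tibble `x` (bin centre = mean of `g` in bin), `y` (mean
#'   rate), `n` (points per bin).
#' @export
estimate_nonlinearity <- function(g, psth, n_bins = 50) {
  gv <- if (is.data.frame(g)) g$g else as.numeric(g)
  yv <- if (is.data.frame(psth)) psth$rate else as.numeric(psth)
  if (length(gv) != length(yv)) abort("`g` and `psth` must be equal length.")
  if (n_bins < 5) abort("`n_bins` must be at least 5.")
  br <- unique(quantile(gv, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(gv, breaks = br, include.lowest = TRUE)
  tibble(g = gv, rate = yv, bin = bin) %>%
    group_by(bin) %>%
    summarise(x = mean(g), y = mean(rate), n = n(), .groups = "drop") %>%
    arrange(x) %>%
    dplyr::select(x, y, n)
}

#' Fit a parametric static nonlinearity
#'
#' Rectifier: `y = pmax(floor, gain * (x - offset))`. Sigmoid:
#' `y = baseline + max / (1 + exp(-slope * (x - mid)))`. Both are fitted
#' by least squares to the raw binned curve (or to a raw `(g, psth)`
#' pair, binned first); the residual sum of squares is reported.
#'
#' @param curve Tibble from [estimate_nonlinearity()] (columns `x`, `y`,
#'   optionally `n` used as weights), or a list `list(g =, psth =)`.
#' @param kind `"rectifier"` or `"sigmoid"`.
#' @param n_bins Bins used when raw signals are supplied.
#' @return Object of class `sdm_nl`: list with `kind`, `par` (named),
#'   `rss`, and the fitted `curve`.
#' @export
fit_static_nl <- function(curve, kind = c("rectifier", "sigmoid"),
                          n_bins = 50) {
  kind <- match.arg(kind)
  if (is.list(curve) && !is.data.frame(curve) &&
      all(c("g", "psth") %in% names(curve))) {
    curve <- estimate_nonlinearity(curve$g, curve$psth, n_bins)
  }
  x <- curve$x; y <- curve$y
  wts <- if ("n" %in% names(curve)) curve$n else rep(1, length(x))
  if (kind == "rectifier") {
    # initial values from the upper half of the curve
    hi <- x >= median(x)
    slope0 <- if (sum(hi) >= 2 && var(x[hi]) > 0) {
      max(coef(lm(y ~ x, weights = wts, subset = hi))[2], 1e-6)
    } else 1
    floor0 <- min(y)
    off0 <- x[which.max(y > floor0 + 1e-12)] %||% median(x)
    obj <- function(p) {
      sum(wts * (pmax(p[3], p[1] * (x - p[2])) - y)^2)
    }
    fit <- optim(c(slope0, off0, floor0), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    par <- c(gain = fit2$par[1], offset = fit2$par[2], floor = fit2$par[3])
    rss <- fit2$value
    pred <- function(xx) pmax(par[["floor"]],
                              par[["gain"]] * (xx - par[["offset"]]))
  } else {
    rng <- max(y) - min(y)
    df <- tibble(x = x, y = y, w = wts)
    base_slope <- 4 / max(diff(range(x)), 1e-9)
    mid0 <- x[which.min(abs(y - (min(y) + rng / 2)))]
    starts <- list(
      list(max = rng, slope = base_slope, mid = mid0, baseline = min(y)),
      list(max = rng, slope = 10 * base_slope,
           mid = quantile(x, 0.9, names = FALSE), baseline = min(y)),
      list(max = max(rng, 1e-6), slope = base_slope / 4,
           mid = median(x), baseline = min(y))
    )
    fit <- NULL
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ baseline + max / (1 + exp(-slope * (x - mid))),
          data = df, weights = df$w, start = st,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (!is.null(fit)) {
      cf <- coef(fit)
    } else {
      # direct least squares as a fallback for flat or sparse curves
      obj <- function(p) {
        sum(wts * (p[4] + p[1] / (1 + exp(-p[2] * (x - p[3]))) - y)^2)
      }
      p0 <- unlist(starts[[1]])
      op <- optim(p0, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
      if (!is.finite(op$value)) {
        abort("Sigmoid fit failed to converge.")
      }
      cf <- setNames(op$par, c("max", "slope", "mid", "baseline"))
    }
    if (cf[["slope"]] < 0) {
      # re-express a decreasing fit as increasing with negated range
      cf <- c(max = -cf[["max"]], slope = -cf[["slope"]], mid = cf[["mid"]],
              baseline = cf[["baseline"]] + cf[["max"]])
    }
    par <- c(max = cf[["max"]], slope = cf[["slope"]], mid = cf[["mid"]],
             baseline = cf[["baseline"]])
    pred <- function(xx) par[["baseline"]] +
      par[["max"]] / (1 + exp(-par[["slope"]] * (xx - par[["mid"]])))
    rss <- sum(wts * (pred(x) - y)^2)
  }
  structure(
    list(kind = kind, par = par, rss = rss, curve = curve, fn = pred),
    class = "sdm_nl"
  )
}

#' @export
predict.sdm_nl <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$g else as.numeric(newdata)
  object$fn(x)
}

#' @export
print.sdm_nl <- function(x, ...) {
  cat(sprintf("<sdm_nl> %s: %s (rss %.4g)\n", x$kind,
              paste(names(x$par), signif(x$par, 4),
                    sep = " = ", collapse = ", "), x$rss))
  invisible(x)
}

#' One LNL stream: filter + static nonlinearity
#'
#' Bundles a temporal filter with a fitted nonlinearity and the spike
#' class it targets.
#'
#' @param filter Tibble `lag` + value column.
#' @param nl An `sdm_nl`.
#' @param tag Target spike class (`"async"`, `"sync"`, ...).
#' @return Object of class `sdm_lnl_stream`.
#' @export
lnl_stream <- function(filter, nl, tag = "async") {
  structure(list(filter = filter, nl = nl, tag = tag),
            class = "sdm_lnl_stream")
}

#' Predict a rate from one LNL stream
#'
#' Composition `f(filter * s)`, floored at zero.
#'
#' @param stream An `sdm_lnl_stream`.
#' @param stimulus Stimulus tibble (see [filter_stimulus()]).
#' @param ... Passed to [filter_stimulus()].
#' @return Tibble `time`, `rate`.
#' @export
lnl_predict <- function(stream, stimulus, ...) {
  g <- filter_stimulus(stimulus, stream$filter, ...)
  tibble(time = g$time, rate = pmax(predict(stream$nl, g), 0))
}

#' Fit the two-stream augmented LNL encoder
#'
#' Given fitted sync and async streams, finds the per-stream Gaussian
#' smoothing widths (grid search) and combination weights (closed-form
#' least squares given the widths) that minimise the squared error of
#' \deqn{\widehat{PSTH}(t) = \sum_{i \in \{sync, async\}} \omega_i\,
#'   (G_{\sigma_i} * f_i(\mu_i * s))(t)}
#' against the target PSTH on the training interval.
#'
#' @param streams List `list(async =, sync =)` of `sdm_lnl_stream`s.
#' @param total_psth Target rate (`sdm_rate` tibble) on the full grid.
#' @param stimulus Stimulus tibble shared by both streams.
#' @param train_frac Fraction of initial samples used for fitting.
#' @param sigma_grid Candidate kernel widths (ms) per stream.
#' @param stream_rates Optional precomputed list of per-stream rate
#'   tibbles on the `total_psth` grid (bypasses `lnl_predict`).
#' @return Object of class `sdm_augmented`: streams, `weights`,
#'   `sigmas`, `train_frac`, smoothed stream matrix and target for
#'   reuse, and the training error.
#' @export
fit_augmented <- function(streams, total_psth, stimulus = NULL,
                          train_frac = 0.5,
                          sigma_grid = c(0.5, 1, 2, 5, 10, 25, 50),
                          stream_rates = NULL) {
  target <- total_psth$rate
  dt <- infer_grid(total_psth$time)$dt
  if (is.null(stream_rates)) {
    stream_rates <- purrr::map(streams, function(st) {
      r <- lnl_predict(st, stimulus)
      resample_rate(r, total_psth$time)
    })
  }
  base <- purrr::map(stream_rates, ~ .x$rate)
  idx <- split_interval(length(target), train_frac)$train

  smooth_one <- function(x, s) gauss_smooth(x, s, dt)
  cache <- purrr::map(base, function(x) {
    purrr::map(sigma_grid, ~ smooth_one(x, .x))
  })

  best <- NULL
  for (i in seq_along(sigma_grid)) {
    for (j in seq_along(sigma_grid)) {
      A <- cbind(cache[[1]][[i]][idx], cache[[2]][[j]][idx])
      sol <- ls_weights(A, target[idx])
      err <- sum((A %*% sol - target[idx])^2)
      if (is.null(best) || err < best$err - 1e-12) {
        best <- list(err = err, i = i, j = j, w = sol)
      }
    }
  }
  sigmas <- c(sigma_grid[best$i], sigma_grid[best$j])
  names(sigmas) <- names(streams)
  weights <- as.numeric(best$w)
  names(weights) <- names(streams)
  structure(
    list(streams = streams, weights = weights, sigmas = sigmas,
         train_frac = train_frac, dt = dt,
         train_sse = best$err,
         stream_rates = stream_rates,
         time = total_psth$time),
    class = "sdm_augmented"
  )
}

# least-squares weights with a ridge fallback for collinear designs
ls_weights <- function(A, y) {
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  sol <- tryCatch(solve(AtA, Aty), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    warn("Collinear streams; falling back to ridge-regularised weights.")
    sol <- solve(AtA + diag(1e-8 * max(diag(AtA)), ncol(A)), Aty)
  }
  sol
}

#' Predict the augmented-model rate
#'
#' Weighted sum of the Gaussian-smoothed stream predictions, floored at
#' zero.
#'
#' @param model An `sdm_augmented`.
#' @param stimulus Optional stimulus tibble; when omitted, the stream
#'   rates stored at fit time are reused.
#' @return Tibble `time`, `rate`.
#' @export
predict_augmented <- function(model, stimulus = NULL) {
  rates <- if (is.null(stimulus)) {
    model$stream_rates
  } else {
    purrr::map(model$streams, function(st) lnl_predict(st, stimulus))
  }
  sm <- purrr::imap(rates, function(r, nm) {
    gauss_smooth(r$rate, model$sigmas[[nm]], model$dt)
  })
  pred <- Reduce(`+`, purrr::imap(sm, ~ .x * model$weights[[.y]]))
  tibble(time = rates[[1]]$time, rate = pmax(pred, 0))
}

# linear interpolation of a rate tibble onto a target time grid
resample_rate <- function(rate, time) {
  if (length(rate$time) == length(time) &&
      max(abs(rate$time - time)) < 1e-9) {
    return(rate)
  }
  tibble(time = time,
         rate = approx(rate$time, rate$rate, xout = time, rule = 2)$y)
}

#' Fit the one-stream Poisson GLM baseline
#'
#' Regresses the binned, neuron-pooled spike counts on the two filtered
#' stimulus signals with an exponential inverse link (canonical Poisson
#' GLM), using iteratively reweighted least squares. The prediction is
#' returned as a rate on the stimulus grid.
#'
#' @param stimulus Stimulus tibble.
#' @param raster An `sdm_raster`.
#' @param filters List of two filters (tibbles `lag` + value), typically
#'   the first two iSTAC directions.
#' @param train_frac Fraction of initial samples used for fitting.
#' @param g Optional precomputed list of generator tibbles on the
#'   stimulus grid (bypasses [filter_stimulus()]).
#' @return Object of class `sdm_pglm`: coefficients, the `glm` fit
#'   summary pieces, generator signals and metadata.
#' @export
fit_poisson_glm <- function(stimulus, raster, filters, train_frac = 0.5,
                            g = NULL) {
  meta <- raster_meta(raster)
  grid <- infer_grid(stimulus$time)
  counts <- bin_spikes(raster$time, grid)
  if (is.null(g)) {
    g <- purrr::map(filters, ~ filter_stimulus(stimulus, .x))
  }
  g1 <- g[[1]]$g; g2 <- g[[2]]$g
  idx <- split_interval(grid$n_steps, train_frac)$train
  df <- tibble(y = counts[idx], g1 = g1[idx], g2 = g2[idx])
  fit <- glm(y ~ g1 + g2, family = poisson(), data = df,
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("Poisson GLM failed to converge; check filter scaling.")
  }
  cf <- coef(fit)
  cf[is.na(cf)] <- 0 # degenerate (constant) generators drop out
  lam <- exp(cf[1] + cf[2] * g1 + cf[3] * g2)
  rate <- lam / (grid$dt / 1000) / max(meta$n_neurons, 1L) # spikes/s/neuron
  structure(
    list(coefficients = cf,
         filters = filters,
         log_lik = as.numeric(logLik(fit)),
         null_log_lik = {
           mu0 <- mean(df$y)
           sum(stats::dpois(df$y, mu0, log = TRUE))
         },
         deviance = fit$deviance,
         train_frac = train_frac,
         dt = grid$dt,
         n_neurons = meta$n_neurons,
         prediction = tibble(time = stimulus$time, rate = rate)),
    class = "sdm_pglm"
  )
}

#' @export
predict.sdm_pglm <- function(object, stimulus = NULL, ...) {
  if (is.null(stimulus)) return(object$prediction)
  g <- purrr::map(object$filters, ~ filter_stimulus(stimulus, .x))
  cf <- object$coefficients
  lam <- exp(cf[1] + cf[2] * g[[1]]$g + cf[3] * g[[2]]$g)
  tibble(time = stimulus$time,
         rate = lam / (object$dt / 1000) / max(object$n_neurons, 1L))
}

#' @export
print.sdm_pglm <- function(x, ...) {
  cat(sprintf(
    "<sdm_pglm> log-lik %.1f (null %.1f); coef: %s\n",
    x$log_lik, x$null_log_lik,
    paste(signif(x$coefficients, 4), collapse = ", ")
  ))
  invisible(x)
}
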