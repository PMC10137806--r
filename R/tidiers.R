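#' Tidy a fitted static nonlinearity
#'
#' @param x An `sdm_nl`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.sdm_nl <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.sdm_nl
#' @export
glance.sdm_nl <- function(x, ...) {
  tibble(kind = x$kind, rss = x$rss, n_bins = nrow(x$curve))
}

#' Tidy an augmented LNL model
#'
#' @param x An `sdm_augmented`.
#' @param ... Unused.
#' @return One row per stream with weight, smoothing width and
#'   nonlinearity kind.
#' @export
tidy.sdm_augmented <- function(x, ...) {
  purrr::imap_dfr(x$streams, function(st, nm) {
    tibble(stream = nm, weight = x$weights[[nm]],
           sigma = x$sigmas[[nm]], nonlinearity = st$nl$kind)
  })
}

#' @rdname tidy.sdm_augmented
#' @export
glance.sdm_augmented <- function(x, ...) {
  tibble(train_sse = x$train_sse, train_frac = x$train_frac,
         sigma_async = x$sigmas[["async"]], sigma_sync = x$sigmas[["sync"]])
}

#' Tidy the Poisson GLM baseline
#'
#' @param x An `sdm_pglm`.
#' @param ... Unused.
#' @export
tidy.sdm_pglm <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname tidy.sdm_pglm
#' @export
glance.sdm_pglm <- function(x, ...) {
  tibble(log_lik = x$log_lik, null_log_lik = x$null_log_lik,
         deviance = x$deviance, train_frac = x$train_frac)
}

#' Tidy an iSTAC subspace fit
#'
#' @param x An `sdm_istac`.
#' @param ... Unused.
#' @return Long tibble `lag`, `filter`, `value`.
#' @export
tidy.sdm_istac <- function(x, ...) {
  tidyr::pivot_longer(x$filters, -lag, names_to = "filter",
                      values_to = "value")
}

#' @rdname tidy.sdm_istac
#' @export
glance.sdm_istac <- function(x, ...) {
  tibble(d = length(x$info), info = x$info[length(x$info)],
         full_info = x$full_info,
         picked = paste(x$picked, collapse = "+"),
         whitened = x$whitened)
}

#' Tidy a stimulus reconstruction
#'
#' @param x An `sdm_reconstruction`.
#' @param ... Unused.
#' @export
tidy.sdm_reconstruction <- function(x, ...) {
  tibble(stream = names(x$weights), weight = unname(x$weights))
}

#' @rdname tidy.sdm_reconstruction
#' @export
glance.sdm_reconstruction <- function(x, ...) {
  te <- x$scores[x$scores$split == "test", ]
  tibble(method = x$method, r = te$r, rmse = te$rmse, mae = te$mae)
}

#' Tidy a full run: the evaluation table
#'
#' @param x An `sdm_run`.
#' @param ... Unused.
#' @export
tidy.sdm_run <- function(x, ...) x$eval

#' @rdname tidy.sdm_run
#' @export
glance.sdm_run <- function(x, ...) {
  tibble(
    n_neurons = attr(x$raster, "n_neurons"),
    duration = x$config$duration,
    n_spikes = nrow(x$raster),
    n_sync = sum(x$raster$label == "sync"),
    n_async = sum(x$raster$label == "async"),
    n_events = length(x$stimulus$event_times),
    seed = x$config$seed
  )
}
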