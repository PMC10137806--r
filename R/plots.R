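#' Plot a mixed stimulus
#'
#' Slow, fast and mixed current traces stacked in facets.
#'
#' @param object An `sdm_stimulus`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_stimulus <- function(object, ...) {
  df <- tidyr::pivot_longer(object$signals, -time,
                            names_to = "component", values_to = "current")
  df$component <- factor(df$component, levels = c("slow", "fast", "mixed"))
  ggplot2::ggplot(df, ggplot2::aes(time, current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(component)) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)")
}

#' Plot a spike raster
#'
#' One row per neuron; colour encodes the synchrony label when present.
#'
#' @param object An `sdm_raster` (labelled or not).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_raster <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(time, neuron))
  if (!is.null(object$label)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = label),
                                 shape = "|", size = 2) +
      ggplot2::scale_colour_manual(values = c(sync = "red", async = "blue"))
  } else {
    p <- p + ggplot2::geom_point(shape = "|", size = 2)
  }
  p + ggplot2::labs(x = "time (ms)", y = "neuron")
}

#' Plot a kernel-smoothed rate
#'
#' @param object An `sdm_rate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_rate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(time, rate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (ms)",
      y = sprintf("rate (%s, sigma = %g ms)",
                  attr(object, "normalization"), attr(object, "sigma"))
    )
}

#' Plot a filter bank
#'
#' All temporal filters overlaid against pre-spike lag.
#'
#' @param object An `sdm_filter_bank`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_filter_bank <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -lag,
                            names_to = "filter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(lag, value, colour = filter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "filter value")
}

#' Plot a fitted static nonlinearity
#'
#' Raw binned curve (points) with the parametric fit (line).
#'
#' @param object An `sdm_nl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_nl <- function(object, ...) {
  xx <- seq(min(object$curve$x), max(object$curve$x), length.out = 200)
  fit <- tibble(x = xx, y = object$fn(xx))
  ggplot2::ggplot(object$curve, ggplot2::aes(x, y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "black") +
    ggplot2::labs(x = "filtered stimulus", y = "rate (spikes/s)",
                  title = object$kind)
}

#' Plot a stimulus reconstruction
#'
#' Original and reconstructed traces overlaid.
#'
#' @param object An `sdm_reconstruction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_reconstruction <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -time,
                            names_to = "trace", values_to = "current")
  ggplot2::ggplot(df, ggplot2::aes(time, current, colour = trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(original = "black", reconstructed = "purple")) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)",
                  title = object$method)
}

#' Plot predicted against observed PSTHs for a run
#'
#' Test-interval traces for each fitted encoder against the all-spike
#' PSTH.
#'
#' @param object An `sdm_run`.
#' @param window Optional time window (ms, length 2) to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_run <- function(object, window = NULL, ...) {
  obs <- object$psth$mixed
  df <- purrr::imap_dfr(object$predictions, function(p, nm) {
    tibble(time = p$time, rate = p$rate, model = nm)
  })
  df <- bind_rows(df, tibble(time = obs$time, rate = obs$rate,
                             model = "observed"))
  if (!is.null(window)) {
    df <- df[df$time >= window[1] & df$time <= window[2], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(time, rate, colour = model)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "rate (spikes/s per neuron)")
}

#' Projection scatter of a spike-triggered ensemble
#'
#' 2-D projection onto two filters, optionally coloured by spike labels.
#'
#' @param proj Tibble from [project_ensemble()].
#' @param labels Optional factor of the same length (e.g. sync/async).
#' @return A ggplot.
#' @export
plot_projection <- function(proj, labels = NULL) {
  if (!is.null(labels)) proj$label <- labels
  p <- ggplot2::ggplot(proj, ggplot2::aes(x1, x2))
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = label), alpha = 0.5) +
      ggplot2::scale_colour_manual(values = c(sync = "red", async = "blue"))
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.5)
  }
  p + ggplot2::labs(x = "projection on filter 1", y = "projection on filter 2")
}
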