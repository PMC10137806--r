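#' Spike-triggered stimulus ensemble
#'
#' Collects, for every spike later than `window` from the start, the
#' stimulus slice of length `window` ending at the spike time. Rows are
#' ordered like the retained spikes; spikes earlier than the window are
#' dropped (count reported in the object). The stimulus may optionally be
#' decimated to a coarser lag resolution before slicing, which is the
#' usual practice when the integration step is much finer than the
#' timescale of the filters.
#'
#' @param stimulus Tibble with columns `time` and a signal column
#'   (default `mixed`; falls back to `current`, or pass `signal`).
#' @param spikes Spike times (ms).
#' @param window Pre-spike window length (ms).
#' @param signal Name of the stimulus column to use.
#' @param lag_dt Lag resolution (ms). Defaults to the stimulus step; when
#'   coarser, the stimulus is decimated by point sampling.
#' @param center Subtract the raw stimulus mean from every row (the
#'   estimators assume a zero-mean stimulus distribution). Default TRUE.
#' @param tag Free-form label for the triggering spike set.
#' @return An object of class `sdm_ste`: list with `X` (n_spikes x
#'   n_lags matrix, columns ordered oldest lag to lag 0), `lags`
#'   (negative lags, ms), `dt`, `spike_times`, `n_dropped`,
#'   `stim_mean`, `tag`.
#' @export
spike_triggered_matrix <- function(stimulus, spikes, window = 100,
                                   signal = NULL, lag_dt = NULL,
                                   center = TRUE, tag = "all") {
  if (window <= 0) abort("`window` must be positive (ms).")
  sig_col <- signal %||%
    (if ("mixed" %in% names(stimulus)) "mixed" else "current")
  s <- stimulus[[sig_col]]
  grid <- infer_grid(stimulus$time)
  lag_dt <- lag_dt %||% grid$dt
  dec <- as.integer(round(lag_dt / grid$dt))
  if (abs(dec * grid$dt - lag_dt) > 1e-9) {
    abort("`lag_dt` must be a multiple of the stimulus step.")
  }
  if (dec > 1L) {
    s <- s[seq(1L, length(s), by = dec)]
  }
  dt <- grid$dt * dec
  n_lags <- as.integer(round(window / dt))
  # spike at time t triggers the slice ending at the bin containing t
  end_idx <- floor(spikes / dt + 1e-9) + 1L
  keep <- end_idx >= n_lags & end_idx <= length(s)
  n_dropped <- sum(!keep)
  if (!any(keep)) abort("No spikes fall inside the usable interval.")
  end_idx <- end_idx[keep]
  offs <- seq.int(-(n_lags - 1L), 0L)
  X <- t(vapply(end_idx, function(e) s[e + offs], numeric(n_lags)))
  stim_mean <- mean(s)
  if (center) X <- X - stim_mean
  structure(
    list(
      X = X,
      lags = offs * dt,
      dt = dt,
      spike_times = spikes[keep],
      n_dropped = n_dropped,
      stim_mean = stim_mean,
      centered = center,
      tag = tag
    ),
    class = "sdm_ste"
  )
}

#' @export
print.sdm_ste <- function(x, ...) {
  cat(sprintf(
    "<sdm_ste> %d spikes (%s) x %d lags at dt = %g ms (%d dropped)\n",
    nrow(x$X), x$tag, ncol(x$X), x$dt, x$n_dropped
  ))
  invisible(x)
}

#' Spike-triggered average
#'
#' The mean pre-spike stimulus window, \eqn{\mu = n_{sp}^{-1} \sum_i s_i}
#' over the spike-triggered ensemble.
#'
#' @param ens An `sdm_ste`.
#' @return Tibble `lag`, `filter`.
#' @export
compute_sta <- function(ens) {
  stopifnot(inherits(ens, "sdm_ste"))
  if (!nrow(ens$X)) abort("Empty spike-triggered ensemble.")
  tibble(lag = ens$lags, filter = colMeans(ens$X))
}

#' Spike-triggered covariance
#'
#' \eqn{\Lambda = n_{sp}^{-1} \sum_i (s_i - \mu)(s_i - \mu)^T} about the
#' STA, with its eigendecomposition sorted by decreasing eigenvalue.
#' Note the `1/n` normalisation (not `1/(n-1)`), matching the moment
#' definition used by the information criterion.
#'
#' @param ens An `sdm_ste` with at least 2 rows.
#' @return List with `Lambda` (matrix), `values`, `vectors` (columns are
#'   unit-norm eigenvectors), `lags`.
#' @export
compute_stc <- function(ens) {
  stopifnot(inherits(ens, "sdm_ste"))
  n <- nrow(ens$X)
  if (n < 2) abort("Need at least 2 spikes for a covariance.")
  mu <- colMeans(ens$X)
  Xc <- sweep(ens$X, 2, mu)
  Lambda <- crossprod(Xc) / n
  Lambda <- (Lambda + t(Lambda)) / 2
  eig <- eigen(Lambda, symmetric = TRUE)
  list(Lambda = Lambda, values = eig$values, vectors = eig$vectors,
       lags = ens$lags)
}

#' Gaussian-KL information of a stimulus subspace
#'
#' For orthonormal basis `K` (columns), STA `mu` and STC `Lambda`
#' measured in a whitened (or trusted-as-white) stimulus space, the
#' information retained by the subspace is
#' \deqn{D_K = \tfrac12\left(\mathrm{Tr}\!\left[K^T(\Lambda + \mu\mu^T)K\right]
#'   - \log\det\!\left(K^T \Lambda K\right) - d\right),}
#' the KL divergence between the Gaussian approximation of the
#' spike-triggered distribution restricted to the subspace and a standard
#' normal prior. With `K` a complete orthonormal basis this reduces to
#' the full-space divergence
#' \eqn{\tfrac12(\mathrm{Tr}\Lambda - \log\det\Lambda + \mu^T\mu - n)}.
#'
#' @param K Matrix with `d` orthonormal columns (or a vector for d = 1).
#' @param mu STA vector.
#' @param Lambda STC matrix.
#' @return Information (nats).
#' @export
istac_info <- function(K, mu, Lambda) {
  K <- as.matrix(K)
  d <- ncol(K)
  G <- crossprod(K, Lambda %*% K)
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-12)) {
    abort("Degenerate subspace: K' Lambda K is (numerically) singular.")
  }
  proj_mu <- crossprod(K, mu)
  0.5 * (sum(diag(G)) + sum(proj_mu^2) - sum(log(ev)) - d)
}

#' Greedy iSTAC subspace selection
#'
#' Candidate directions are the (normalised) STA and all eigenvectors of
#' the STC matrix. Starting from the empty basis, the candidate whose
#' addition maximises [istac_info()] of the accumulated, incrementally
#' orthonormalised basis is appended at each step, `d` times. Ties are
#' broken by the larger single-direction information, then by candidate
#' order (STA first, then eigenvectors by decreasing eigenvalue).
#'
#' @param ens An `sdm_ste`, or `NULL` when `mu`/`Lambda` given directly.
#' @param d Number of directions to select.
#' @param mu,Lambda Optional moments (bypass `ens`).
#' @param whiten Whiten by the raw-stimulus covariance first? When TRUE,
#'   supply `prior` as a list with `mean` and `cov` of the raw stimulus
#'   windows, or let the function estimate them from `stimulus` slices
#'   passed via `prior`. Selected filters are mapped back to the
#'   original (unwhitened) space for interpretability.
#' @param prior List `list(mean =, cov =)` of raw-stimulus window
#'   moments, required when `whiten = TRUE`.
#' @return A list of class `sdm_istac`: `filters` (tibble `lag`, `nu1`,
#'   ..., `nud`), `info` (per-step cumulative information), `basis`
#'   (orthonormal matrix in estimation space), `picked` (candidate
#'   labels), `full_info` (complete-basis information), and the
#'   `mu`/`Lambda` used.
#' @export
select_subspaces <- function(ens = NULL, d = 2, mu = NULL, Lambda = NULL,
                             whiten = FALSE, prior = NULL) {
  if (is.null(mu) || is.null(Lambda)) {
    stopifnot(inherits(ens, "sdm_ste"))
    mu <- compute_sta(ens)$filter
    Lambda <- compute_stc(ens)$Lambda
    lags <- ens$lags
  } else {
    mu <- as.numeric(mu)
    lags <- seq_along(mu)
  }
  if (!is.null(ens)) lags <- ens$lags

  W <- NULL
  if (whiten) {
    if (is.null(prior)) abort("`whiten = TRUE` requires `prior` moments.")
    ec <- eigen((prior$cov + t(prior$cov)) / 2, symmetric = TRUE)
    if (any(ec$values <= 1e-10 * max(ec$values))) {
      abort("Raw-stimulus covariance is singular; cannot whiten.")
    }
    W <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
    # ensemble rows are already centred by the raw stimulus mean, so the
    # prior mean is (numerically) zero under stationarity
    mu <- as.numeric(W %*% mu)
    Lambda <- W %*% Lambda %*% W
    Lambda <- (Lambda + t(Lambda)) / 2
  }

  n <- length(mu)
  stc <- eigen(Lambda, symmetric = TRUE)
  cand <- cbind(mu / sqrt(sum(mu^2)), stc$vectors)
  labels <- c("sta", paste0("stc", seq_len(n)))
  if (d > ncol(cand)) abort("`d` exceeds the number of candidates.")
  if (d > n) abort("`d` exceeds the stimulus dimensionality.")

  single_info <- vapply(seq_len(ncol(cand)), function(j) {
    tryCatch(istac_info(cand[, j, drop = FALSE], mu, Lambda),
             error = function(e) -Inf)
  }, numeric(1))

  basis <- matrix(0, n, 0)
  picked <- character()
  info <- numeric()
  avail <- rep(TRUE, ncol(cand))
  for (step in seq_len(d)) {
    best <- -Inf; best_j <- NA_integer_; best_v <- NULL
    for (j in which(avail)) {
      v <- cand[, j]
      if (ncol(basis)) v <- v - basis %*% crossprod(basis, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) { avail[j] <- FALSE; next }
      v <- v / nv
      val <- tryCatch(istac_info(cbind(basis, v), mu, Lambda),
                      error = function(e) -Inf)
      better <- val > best + 1e-12 ||
        (abs(val - best) <= 1e-12 && !is.na(best_j) &&
           single_info[j] > single_info[best_j] + 1e-12)
      if (is.na(best_j) || better) {
        best <- val; best_j <- j; best_v <- v
      }
    }
    if (is.na(best_j)) abort("Ran out of independent candidates.")
    basis <- cbind(basis, best_v)
    picked <- c(picked, labels[best_j])
    info <- c(info, best)
    avail[best_j] <- FALSE
  }

  filters_mat <- basis
  if (whiten) {
    # map back: directions in whitened space correspond to W %*% v in
    # the original space (row space of the whitening transform)
    filters_mat <- W %*% basis
    filters_mat <- sweep(filters_mat, 2,
                         sqrt(colSums(filters_mat^2)), "/")
  }
  filters <- as_tibble(setNames(
    as.data.frame(filters_mat), paste0("nu", seq_len(d))
  ))
  filters <- bind_cols(tibble(lag = lags), filters)

  full_info <- 0.5 * (sum(diag(Lambda)) -
                        determinant(Lambda, logarithm = TRUE)$modulus[1] +
                        sum(mu^2) - n)
  structure(
    list(filters = filters, info = info, basis = basis, picked = picked,
         full_info = full_info, mu = mu, Lambda = Lambda,
         eigenvalues = stc$values, whitened = whiten),
    class = "sdm_istac"
  )
}

#' @export
print.sdm_istac <- function(x, ...) {
  cat(sprintf(
    "<sdm_istac> %d directions (%s); info %s of full %.3f nats\n",
    length(x$info), paste(x$picked, collapse = ", "),
    paste(sprintf("%.3f", x$info), collapse = " -> "), x$full_info
  ))
  invisible(x)
}

#' Project a spike-triggered ensemble on two filters
#'
#' Inner products of every row with `f1` and `f2`.
#'
#' @param ens An `sdm_ste`.
#' @param f1,f2 Filters on the ensemble lag grid (numeric vectors or
#'   tibbles with a `filter` column).
#' @return Tibble `spike_time`, `x1`, `x2`.
#' @export
project_ensemble <- function(ens, f1, f2) {
  stopifnot(inherits(ens, "sdm_ste"))
  f1 <- filter_vec(f1); f2 <- filter_vec(f2)
  if (length(f1) != ncol(ens$X) || length(f2) != ncol(ens$X)) {
    abort("Filters must live on the ensemble lag grid.")
  }
  tibble(
    spike_time = ens$spike_times,
    x1 = as.numeric(ens$X %*% f1),
    x2 = as.numeric(ens$X %*% f2)
  )
}

filter_vec <- function(f) {
  if (is.data.frame(f)) {
    cols <- setdiff(names(f), "lag")
    as.numeric(f[[cols[1]]])
  } else {
    as.numeric(f)
  }
}

# raw-stimulus window moments (prior for whitening): mean and covariance
# of all sliding windows of the stimulus, estimated from a subsample
stimulus_prior <- function(stimulus, window = 100, signal = NULL,
                           lag_dt = NULL, stride = 10L) {
  sig_col <- signal %||%
    (if ("mixed" %in% names(stimulus)) "mixed" else "current")
  s <- stimulus[[sig_col]]
  grid <- infer_grid(stimulus$time)
  lag_dt <- lag_dt %||% grid$dt
  dec <- as.integer(round(lag_dt / grid$dt))
  if (dec > 1L) s <- s[seq(1L, length(s), by = dec)]
  dt <- grid$dt * dec
  n_lags <- as.integer(round(window / dt))
  starts <- seq(n_lags, length(s), by = stride)
  offs <- seq.int(-(n_lags - 1L), 0L)
  X <- t(vapply(starts, function(e) s[e + offs], numeric(n_lags)))
  list(mean = colMeans(X), cov = stats::cov(X) * (nrow(X) - 1) / nrow(X))
}

#' Assemble a filter bank
#'
#' Collects named temporal filters on one lag grid into a wide tibble,
#' unit-norm by convention for subspace filters and raw scale for STAs.
#'
#' @param ... Named filters (tibbles with `lag` and one value column, or
#'   numeric vectors).
#' @param lags Lag grid (ms), required when vectors are given.
#' @return Tibble of class `sdm_filter_bank`: `lag` plus one column per
#'   filter.
#' @export
filter_bank <- function(..., lags = NULL) {
  fl <- list(...)
  if (!length(fl)) abort("Supply at least one filter.")
  if (is.null(lags)) {
    first <- fl[[which(vapply(fl, is.data.frame, logical(1)))[1]]]
    lags <- first$lag
  }
  cols <- purrr::map(fl, filter_vec)
  lens <- lengths(cols)
  if (any(lens != length(lags))) abort("All filters must share one lag grid.")
  out <- bind_cols(tibble(lag = lags), as_tibble(cols))
  class(out) <- c("sdm_filter_bank", class(out))
  out
}

#' Write / read a filter bank
#'
#' Delimited text with a `lag` column and one column per filter; a JSON
#' sidecar records provenance.
#'
#' @param bank An `sdm_filter_bank`.
#' @param stem Path stem.
#' @param meta Optional named list written to the sidecar.
#' @export
write_filter_bank <- function(bank, stem, meta = list()) {
  write.table(as.data.frame(bank), paste0(stem, "_filters.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(stem, "_filters_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(stem) {
  df <- as_tibble(read.table(paste0(stem, "_filters.tsv"),
                             header = TRUE, sep = "\t"))
  class(df) <- c("sdm_filter_bank", class(df))
  df
}
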