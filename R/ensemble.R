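#' Morris-Lecar neuron parameters
#'
#' Conductance-based model with a fast activation variable \eqn{m_\infty(V)},
#' a recovery variable \eqn{w}, and a slow AHP (adaptation) variable
#' \eqn{z} gating a potassium current:
#' \deqn{C \dot V = I - \bar g_{Na} m_\infty(V)(V - E_{Na}) - \bar g_K w (V - E_K)
#'   - g_L (V - E_L) - \bar g_{AHP} z (V - E_K) - g_{exc}(V - E_{exc})
#'   - g_{inh}(V - E_{inh})}
#' with \eqn{\dot w = \phi\,(w_\infty(V) - w)/\tau_w(V)},
#' \eqn{\dot z = (z_\infty(V) - z)/\tau_z},
#' \eqn{m_\infty(V) = 0.5(1 + \tanh((V-\beta_m)/\gamma_m))},
#' \eqn{w_\infty(V) = 0.5(1 + \tanh((V-\beta_w)/\gamma_w))},
#' \eqn{\tau_w(V) = 1/\cosh((V-\beta_w)/(2\gamma_w))}, and
#' \eqn{z_\infty(V) = 1/(1 + e^{(\beta_z - V)/\gamma_z})}.
#'
#' Defaults put the cell in the hybrid operating regime between a pure
#' integrator and a pure coincidence detector, so that a slowly varying
#' current modulates the firing rate while fast transients evoke
#' precisely timed spikes. Two defaults deviate deliberately from naive
#' settings and deserve attention:
#' \itemize{
#'   \item `g_L = 2` mS/cm2. A leak an order of magnitude larger
#'     (e.g. 20) makes the cell electrically leaky enough that
#'     physiological current amplitudes (tens of pA at 200 um2) cannot
#'     reach threshold at all; 2 mS/cm2 is the standard hybrid-mode
#'     value in the Morris-Lecar literature.
#'   \item `g_exc = g_inh = 0`. Constant (tonic) synaptic conductances of
#'     about 1.2/1.9 mS/cm2 load the membrane so heavily that repetitive
#'     firing disappears (the cell becomes a pure onset detector). They
#'     can be switched on explicitly, or modulated as OU conductance
#'     noise via `simulate_ensemble(conductance_noise = )`.
#' }
#'
#' @param C Membrane capacitance (uF/cm2).
#' @param g_Na,g_K,g_L,g_AHP,g_exc,g_inh Maximal conductances (mS/cm2).
#' @param E_Na,E_K,E_L,E_exc,E_inh Reversal potentials (mV).
#' @param beta_m,gamma_m,beta_w,gamma_w,beta_z,gamma_z Half-activation and
#'   slope voltages (mV) of the gating functions.
#' @param tau_z AHP time constant (ms).
#' @param phi Recovery rate scale (dimensionless).
#' @param area Membrane area (um2); input currents in pA are converted to
#'   densities (uA/cm2) by dividing by `area * 1e-2`.
#' @return A list of class `ml_params`.
#' @export
ml_params <- function(C = 2,
                      g_Na = 20, g_K = 20, g_L = 2, g_AHP = 25,
                      g_exc = 0, g_inh = 0,
                      E_Na = 50, E_K = -100, E_L = -60,
                      E_exc = 0, E_inh = -70,
                      beta_m = -1.2, gamma_m = 18,
                      beta_w = -19, gamma_w = 10,
                      beta_z = 0, gamma_z = 2,
                      tau_z = 20, phi = 0.15,
                      area = 200) {
  p <- list(C = C, g_Na = g_Na, g_K = g_K, g_L = g_L, g_AHP = g_AHP,
            g_exc = g_exc, g_inh = g_inh,
            E_Na = E_Na, E_K = E_K, E_L = E_L, E_exc = E_exc, E_inh = E_inh,
            beta_m = beta_m, gamma_m = gamma_m,
            beta_w = beta_w, gamma_w = gamma_w,
            beta_z = beta_z, gamma_z = gamma_z,
            tau_z = tau_z, phi = phi, area = area)
  conds <- c("g_Na", "g_K", "g_L", "g_AHP", "g_exc", "g_inh")
  if (any(unlist(p[conds]) < 0)) abort("Conductances must be non-negative.")
  if (C <= 0) abort("`C` must be positive.")
  if (area <= 0) abort("`area` must be positive.")
  structure(p, class = "ml_params")
}

# pA -> uA/cm2 for a cell of `area` um2
current_density <- function(I_pA, area) I_pA * 1e-6 / (area * 1e-8)

#' Morris-Lecar state derivative
#'
#' Right-hand side of the model at a single state, vectorised over
#' neurons. Mostly useful for testing and for locating fixed points.
#'
#' @param state List or named vector with `V` (mV), `w`, `z`.
#' @param I_input Applied current (pA, converted via `params$area`).
#' @param params An [ml_params()] bundle.
#' @return A list with `dV` (mV/ms), `dw`, `dz`.
#' @export
ml_derivative <- function(state, I_input = 0, params = ml_params()) {
  V <- state$V; w <- state$w; z <- state$z
  p <- params
  g <- ml_gates(V, p)
  I <- current_density(I_input, p$area)
  dV <- (I - p$g_Na * g$m_inf * (V - p$E_Na) -
           p$g_K * w * (V - p$E_K) -
           p$g_L * (V - p$E_L) -
           p$g_AHP * z * (V - p$E_K) -
           p$g_exc * (V - p$E_exc) -
           p$g_inh * (V - p$E_inh)) / p$C
  dw <- p$phi * (g$w_inf - w) / g$tau_w
  dz <- (g$z_inf - z) / p$tau_z
  list(dV = dV, dw = dw, dz = dz)
}

ml_gates <- function(V, p) {
  list(
    m_inf = 0.5 * (1 + tanh((V - p$beta_m) / p$gamma_m)),
    w_inf = 0.5 * (1 + tanh((V - p$beta_w) / p$gamma_w)),
    tau_w = 1 / cosh((V - p$beta_w) / (2 * p$gamma_w)),
    z_inf = 1 / (1 + exp((p$beta_z - V) / p$gamma_z))
  )
}

# resting potential with constant input: solves dV/dt = 0 with w = w_inf(V),
# z = z_inf(V) by bracketed root finding
ml_rest <- function(params = ml_params(), I_input = 0) {
  f <- function(V) {
    g <- ml_gates(V, params)
    ml_derivative(list(V = V, w = g$w_inf, z = g$z_inf),
                  I_input, params)$dV
  }
  stats::uniroot(f, c(-90, -20), tol = 1e-10)$root
}

#' Simulate the homogeneous Morris-Lecar ensemble
#'
#' Integrates every neuron with forward Euler at the stimulus time step.
#' All neurons share the mixed signal and the parameter set
#' (homogeneous ensemble); each receives its private noise column from
#' the stimulus. Spikes are upward crossings of `threshold` separated by
#' at least `refractory`.
#'
#' @param stim An `sdm_stimulus` (see [simulate_stimulus()]).
#' @param params An [ml_params()] bundle.
#' @param threshold Spike detection threshold (mV).
#' @param refractory Minimum inter-spike interval (ms).
#' @param keep_voltage Keep the voltage matrix (`n_steps x n_neurons`)?
#'   Off by default (large).
#' @param conductance_noise Optional list
#'   `list(exc = ou_params(), inh = ou_params())` giving OU dynamics for
#'   the synaptic conductances (units mS/cm2); when supplied, `g_exc` /
#'   `g_inh` fluctuate (floored at 0) instead of staying constant.
#' @param seed Seed for the conductance-noise draws (unused otherwise;
#'   the integration itself is deterministic given the stimulus).
#' @return An `sdm_raster`: tibble with columns `neuron`, `time`, plus
#'   attributes `n_neurons`, `duration`, `dt` (and `voltage` if kept).
#' @examples
#' stim <- simulate_stimulus(sdm_grid(0.1, 1000), n_neurons = 3, seed = 1)
#' r <- simulate_ensemble(stim)
#' @export
simulate_ensemble <- function(stim, params = ml_params(),
                              threshold = 0, refractory = 2,
                              keep_voltage = FALSE,
                              conductance_noise = NULL, seed = NULL) {
  stopifnot(inherits(stim, "sdm_stimulus"))
  p <- params
  grid <- stim$grid
  dt <- grid$dt
  n_neur <- ncol(stim$noise)
  mixed <- stim$signals$mixed
  if (length(mixed) != nrow(stim$noise)) {
    abort("Stimulus signals and noise must share one grid.")
  }

  V0 <- ml_rest(p)
  V <- rep(V0, n_neur)
  g0 <- ml_gates(V0, p)
  w <- rep(g0$w_inf, n_neur)
  z <- rep(g0$z_inf, n_neur)

  ge <- rep(p$g_exc, n_neur)
  gi <- rep(p$g_inh, n_neur)
  cn <- conductance_noise
  if (!is.null(cn)) {
    fe <- ou_ar1(cn$exc$tau, cn$exc$sigma, dt)
    fi <- ou_ar1(cn$inh$tau, cn$inh$sigma, dt)
    ge <- rep(cn$exc$mu, n_neur)
    gi <- rep(cn$inh$mu, n_neur)
    if (!is.null(seed)) withr::local_seed(seed)
  }

  conv <- 1e-6 / (p$area * 1e-8)
  noise <- stim$noise
  n_steps <- grid$n_steps
  counts <- integer(n_neur)
  last_spike <- rep(-Inf, n_neur)
  keepV <- if (keep_voltage) matrix(NA_real_, n_steps, n_neur) else NULL
  # pre-allocate generous spike buffers
  buf <- matrix(NA_real_, 4096L, n_neur)

  for (t in seq_len(n_steps)) {
    I <- (mixed[t] + noise[t, ]) * conv
    m_inf <- 0.5 * (1 + tanh((V - p$beta_m) / p$gamma_m))
    w_inf <- 0.5 * (1 + tanh((V - p$beta_w) / p$gamma_w))
    tau_w <- 1 / cosh((V - p$beta_w) / (2 * p$gamma_w))
    z_inf <- 1 / (1 + exp((p$beta_z - V) / p$gamma_z))
    dV <- (I - p$g_Na * m_inf * (V - p$E_Na) -
             p$g_K * w * (V - p$E_K) -
             p$g_L * (V - p$E_L) -
             p$g_AHP * z * (V - p$E_K) -
             pmax(ge, 0) * (V - p$E_exc) -
             pmax(gi, 0) * (V - p$E_inh)) / p$C
    w <- w + dt * p$phi * (w_inf - w) / tau_w
    z <- z + dt * (z_inf - z) / p$tau_z
    Vn <- V + dt * dV
    if (!is.null(cn)) {
      ge <- cn$exc$mu + (ge - cn$exc$mu) * fe$a + fe$b * rnorm(n_neur)
      gi <- cn$inh$mu + (gi - cn$inh$mu) * fi$a + fi$b * rnorm(n_neur)
    }
    if (any(abs(Vn) > 200)) {
      bad <- which.max(abs(Vn))
      abort(sprintf(
        "Integration failure: |V| > 200 mV for neuron %d at t = %.3f ms.",
        bad, t * dt
      ))
    }
    tnow <- t * dt # time of the post-crossing sample
    fired <- which(V < threshold & Vn >= threshold &
                     (tnow - last_spike) >= refractory)
    if (length(fired)) {
      counts[fired] <- counts[fired] + 1L
      if (max(counts) > nrow(buf)) {
        buf <- rbind(buf, matrix(NA_real_, nrow(buf), n_neur))
      }
      buf[cbind(counts[fired], fired)] <- tnow
      last_spike[fired] <- tnow
    }
    V <- Vn
    if (keep_voltage) keepV[t, ] <- V
  }

  raster <- purrr::map_dfr(seq_len(n_neur), function(j) {
    tibble(neuron = j, time = buf[seq_len(counts[j]), j])
  })
  new_raster(raster, n_neurons = n_neur, duration = grid$duration,
             dt = dt, voltage = keepV)
}

new_raster <- function(df, n_neurons, duration, dt, voltage = NULL) {
  out <- as_tibble(df)
  attr(out, "n_neurons") <- as.integer(n_neurons)
  attr(out, "duration") <- duration
  attr(out, "dt") <- dt
  if (!is.null(voltage)) attr(out, "voltage") <- voltage
  class(out) <- c("sdm_raster", class(out))
  out
}

raster_meta <- function(raster) {
  list(
    n_neurons = attr(raster, "n_neurons") %||% max(raster$neuron, 0L),
    duration = attr(raster, "duration") %||%
      (if (nrow(raster)) max(raster$time) else 0),
    dt = attr(raster, "dt") %||% 0.1
  )
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold`, with crossings closer than
#' `refractory` to the previous accepted spike discarded.
#'
#' @param V Voltage trace (mV).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation between accepted spikes (ms).
#' @param dt Sample interval of `V` (ms).
#' @return Spike times (ms), on the grid of `V` (time of the first sample
#'   at or above threshold).
#' @export
detect_spikes <- function(V, threshold = 0, refractory = 2, dt = 0.1) {
  if (any(!is.finite(V))) abort("`V` must be finite.")
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (!length(up)) return(numeric())
  times <- up * dt # crossing lands on sample up + 1, zero-based time up*dt
  keep <- numeric(length(times))
  k <- 0L
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      k <- k + 1L
      keep[k] <- tt
      last <- tt
    }
  }
  keep[seq_len(k)]
}

#' Write / read a spike raster as delimited text
#'
#' One row per spike (`neuron`, `time`, and `label` if present), plus a
#' JSON sidecar carrying `n_neurons`, `duration` and `dt`.
#'
#' @param raster An `sdm_raster` tibble.
#' @param stem Path stem (no extension).
#' @export
write_raster <- function(raster, stem) {
  write.table(as.data.frame(raster), paste0(stem, "_raster.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- raster_meta(raster)
  jsonlite::write_json(meta, paste0(stem, "_raster_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_raster
#' @export
read_raster <- function(stem) {
  df <- as_tibble(read.table(paste0(stem, "_raster.tsv"),
                             header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(stem, "_raster_meta.json"),
                              simplifyVector = TRUE)
  new_raster(df, meta$n_neurons, meta$duration, meta$dt)
}
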