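#' Simulate the aEIF neuron with stochastic input
#'
#' Euler-Maruyama integration of the membrane and adaptation equations with
#' white or Ornstein-Uhlenbeck current noise.  Spikes are detected when the
#' membrane potential reaches `V_up` within a step; the potential is then
#' reset to `V_r` and the adaptation current incremented by `b`.  The OU
#' current (when `tau_s > 0`) is advanced by its exact discrete-time
#' solution so its statistics are correct for any `dt / tau_s`.
#'
#' @param p A [neuron_params()] object.
#' @param d A [drive_spec()] object.
#' @param dt Time step (ms), default 0.05.
#' @param duration Total simulated time (ms).
#' @param discard Initial transient to drop from analyses (ms).
#' @param seed Optional RNG seed (`set.seed` is called when given).
#' @param record_trace Record `V`, `w` (and `I` for colored noise) at every
#'   step.
#' @param V0,w0 Initial conditions (default `E_L`, 0).
#' @return An object of class `aeif_sim`: list with `spikes` (ms), `dt`,
#'   `duration`, `discard`, and (if recorded) a `trace` data frame with
#'   columns `t`, `V`, `w` and, for colored noise, `I`.
#' @export
simulate_aeif <- function(p, d, dt = 0.05, duration = 50000, discard = 5000,
                          seed = NULL, record_trace = FALSE,
                          V0 = p$E_L, w0 = 0) {
  stopifnot(inherits(p, "neuron_params"), inherits(d, "drive_spec"),
            dt > 0, duration > 0, discard < duration)
  if (!is.null(seed)) set.seed(seed)
  raw <- simulate_aeif_cpp(p$C, p$g_L, p$E_L, p$Delta_T, p$V_T, p$V_r,
                           p$V_up, p$tau_w, p$b,
                           d$mu_Isyn, d$sigma_Isyn, d$tau_s,
                           dt, duration, record_trace, V0, w0)
  out <- list(spikes = raw$spikes, dt = dt, duration = duration,
              discard = discard, drive = d, params = p)
  if (record_trace) {
    tr <- data.frame(t = seq_len(length(raw$V)) * dt, V = raw$V, w = raw$w)
    if (!is.null(raw$I)) tr$I <- raw$I
    out$trace <- tr
  }
  structure(out, class = "aeif_sim")
}

#' @export
print.aeif_sim <- function(x, ...) {
  cat(sprintf("aEIF simulation: %.3g s at dt = %g ms, %d spikes (%.4g Hz)\n",
              x$duration / 1000, x$dt, length(x$spikes),
              steady_state_rate(x)))
  invisible(x)
}

#' Steady-state firing rate of a spike train
#'
#' Spike count after the transient divided by the analysed span.
#'
#' @param sim An `aeif_sim` object, or a numeric vector of spike times (ms).
#' @param duration Total duration (ms); taken from `sim` when omitted.
#' @param discard Transient to drop (ms); taken from `sim` when omitted.
#' @return Rate in Hz.
#' @export
steady_state_rate <- function(sim, duration = NULL, discard = NULL) {
  if (inherits(sim, "aeif_sim")) {
    spikes <- sim$spikes
    if (is.null(duration)) duration <- sim$duration
    if (is.null(discard)) discard <- sim$discard
  } else spikes <- sim
  span <- duration - discard
  if (span <= 0) stop("analysed span must be positive")
  1000 * sum(spikes > discard) / span
}

#' Subthreshold membrane-potential standard deviation
#'
#' Standard deviation of the recorded membrane potential after excising a
#' window of +/- `window` ms around every spike and dropping the initial
#' transient.
#'
#' @param sim An `aeif_sim` with a recorded trace.
#' @param window Half-width of the excision window (ms), default 10.
#' @return SD in mV.
#' @export
subthreshold_sigma_v <- function(sim, window = 10) {
  stopifnot(inherits(sim, "aeif_sim"))
  if (is.null(sim$trace)) stop("simulation was run without record_trace")
  t <- sim$trace$t
  keep <- t > sim$discard
  n <- length(t)
  dt <- sim$dt
  for (ts in sim$spikes) {
    lo <- max(1L, ceiling((ts - window) / dt))
    hi <- min(n, floor((ts + window) / dt))
    if (lo <= hi) keep[lo:hi] <- FALSE
  }
  if (!any(keep)) stop("no samples survive spike excision")
  stats::sd(sim$trace$V[keep])
}

#' Interspike-interval statistics
#'
#' Sample mean, variance and coefficient of variation of the consecutive
#' spike-time differences.
#'
#' @param sim An `aeif_sim` object or a numeric vector of spike times (ms);
#'   for an `aeif_sim` only spikes after the transient are used.
#' @return List with `mean` (ms), `variance` (ms^2), `cv` and `n`.
#' @export
isi_statistics <- function(sim) {
  spikes <- if (inherits(sim, "aeif_sim"))
    sim$spikes[sim$spikes > sim$discard] else sim
  if (length(spikes) < 2) stop("need at least 2 spikes for ISI statistics")
  isi <- diff(spikes)
  m <- mean(isi)
  v <- stats::var(isi)
  list(mean = m, variance = v, cv = sqrt(v) / m, n = length(isi))
}
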