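#' Construct an aEIF parameter set
#'
#' Bundles the parameters of the exponential integrate-and-fire neuron with
#' spike-triggered adaptation (aEIF with `a = 0`): the membrane equation
#' combines a leak, an exponential spike-initiation term with slope factor
#' `Delta_T`, and an adaptation current `w` that decays with time constant
#' `tau_w` and jumps by `b` at every spike.  When the membrane potential
#' reaches the detection threshold `V_up` it is reset to `V_r`.
#'
#' Units are pF (capacitance), nS (conductance), mV (voltages), ms (time
#' constants) and pA (currents) throughout the package.
#'
#' @param C Membrane capacitance (pF), positive.
#' @param g_L Leak conductance (nS), positive.
#' @param E_L Leak reversal potential (mV).
#' @param Delta_T Spike slope factor (mV), positive.
#' @param V_T Exponential threshold (mV).
#' @param V_r Reset potential (mV), below `V_up`.
#' @param tau_w Adaptation time constant (ms), positive.
#' @param b Spike-triggered adaptation increment (pA), non-negative.
#' @param V_up Upper (spike detection) threshold (mV).  The default
#'   `V_T + 10 * Delta_T` places it far up the exponential upswing, where
#'   the computed rates are insensitive to its exact value.
#' @param cell Optional cell identifier stored alongside the parameters.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params(C = 48.4, g_L = 4.3, E_L = -75.5, Delta_T = 3.1,
#'                    V_T = -64.1, V_r = -98.5, tau_w = 25.4, b = 66.5)
#' membrane_time_constant(p)
#' rheobase(p)
#' @export
neuron_params <- function(C, g_L, E_L, Delta_T, V_T, V_r, tau_w, b,
                          V_up = V_T + 10 * Delta_T, cell = NA_character_) {
  p <- list(C = C, g_L = g_L, E_L = E_L, Delta_T = Delta_T, V_T = V_T,
            V_r = V_r, V_up = V_up, tau_w = tau_w, b = b,
            cell = as.character(cell))
  for (f in c("C", "g_L", "E_L", "Delta_T", "V_T", "V_r", "V_up",
              "tau_w", "b")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  if (p$C <= 0) stop("C must be positive")
  if (p$g_L <= 0) stop("g_L must be positive")
  if (p$Delta_T <= 0) stop("Delta_T must be positive")
  if (p$tau_w <= 0) stop("tau_w must be positive")
  if (p$b < 0) stop("b must be non-negative")
  if (p$V_r >= p$V_up) stop("V_r must lie below V_up")
  if (p$V_T >= p$V_up) stop("V_T must lie below V_up")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("aEIF parameters", if (!is.na(x$cell)) paste0("(", x$cell, ")"), "\n")
  cat(sprintf("  C = %.6g pF, g_L = %.6g nS  (tau_m = %.6g ms)\n",
              x$C, x$g_L, membrane_time_constant(x)))
  cat(sprintf("  E_L = %.6g mV, Delta_T = %.6g mV, V_T = %.6g mV\n",
              x$E_L, x$Delta_T, x$V_T))
  cat(sprintf("  V_r = %.6g mV, V_up = %.6g mV\n", x$V_r, x$V_up))
  cat(sprintf("  tau_w = %.6g ms, b = %.6g pA  (rheobase = %.6g pA)\n",
              x$tau_w, x$b, rheobase(x)))
  invisible(x)
}

#' Membrane time constant
#'
#' @param p A [neuron_params()] object.
#' @return `C / g_L` in ms.
#' @export
membrane_time_constant <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  p$C / p$g_L
}

#' Rheobase current
#'
#' Smallest constant input current at which the deterministic, non-adapting
#' membrane equation loses its subthreshold fixed points (the saddle-node at
#' `V = V_T`) and fires repetitively: `g_L * (V_T - E_L - Delta_T)`.
#'
#' @param p A [neuron_params()] object.
#' @return Current in pA.
#' @export
rheobase <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  p$g_L * (p$V_T - p$E_L - p$Delta_T)
}

#' Synaptic drive specification
#'
#' Describes the Gaussian model of the total synaptic current:
#' `I(t) = mu_Isyn + sigma_Isyn * xi(t)` with `xi` unit-variance Gaussian
#' white noise, delta-correlated with time measured in ms
#' (`<xi(t) xi(t')> = delta(t - t')` in 1/ms).  A positive `tau_s` instead
#' makes the fluctuating part an Ornstein-Uhlenbeck process with that
#' correlation time and the same zero-frequency spectral density, so the
#' white-noise drive is recovered continuously as `tau_s -> 0`.
#'
#' @param mu_Isyn Mean input current (pA).
#' @param sigma_Isyn White-noise amplitude (pA sqrt(ms)).
#' @param tau_s Synaptic correlation time (ms); 0 means white noise.
#' @return An object of class `drive_spec`.
#' @export
drive_spec <- function(mu_Isyn, sigma_Isyn = 0, tau_s = 0) {
  stopifnot(is.numeric(mu_Isyn), is.numeric(sigma_Isyn), is.numeric(tau_s))
  if (sigma_Isyn < 0) stop("sigma_Isyn must be non-negative")
  if (tau_s < 0) stop("tau_s must be non-negative")
  structure(list(mu_Isyn = mu_Isyn, sigma_Isyn = sigma_Isyn, tau_s = tau_s),
            class = "drive_spec")
}

#' Convert a current drive to voltage-scaled theory units
#'
#' The Fokker-Planck machinery works with the voltage-scaled drive
#' `mu = mu_Isyn / g_L` (mV) and noise `sigma = sigma_Isyn / C *
#' sqrt(2 tau_m)` (mV).  For a colored drive (`tau_s > 0`) apply
#' [sigma_reduced()] first; this conversion itself assumes white noise.
#'
#' @param d A [drive_spec()] object.
#' @param p A [neuron_params()] object.
#' @return An object of class `theory_drive` with fields `mu` and `sigma`
#'   (both mV).
#' @export
convert_drive <- function(d, p) {
  stopifnot(inherits(d, "drive_spec"), inherits(p, "neuron_params"))
  tau_m <- membrane_time_constant(p)
  structure(list(mu = d$mu_Isyn / p$g_L,
                 sigma = d$sigma_Isyn / p$C * sqrt(2 * tau_m)),
            class = "theory_drive")
}

#' Total deterministic membrane drift (voltage-scaled)
#'
#' `f(V) = -(V - E_L) + Delta_T * exp((V - V_T)/Delta_T) + mu`, the
#' right-hand side of the membrane equation in units of mV (i.e. multiplied
#' by `tau_m / C`).  The exponential argument is clamped so the evaluation
#' is overflow-safe arbitrarily far above threshold.
#'
#' @param V Membrane potential(s), mV.
#' @param p A [neuron_params()] object.
#' @param mu Voltage-scaled mean drive (mV), default 0.
#' @return Drift in mV (vectorised over `V`).
#' @export
eif_f <- function(V, p, mu = 0) {
  stopifnot(inherits(p, "neuron_params"))
  -(V - p$E_L) + p$Delta_T * exp(pmin((V - p$V_T) / p$Delta_T, 700)) + mu
}

# Antiderivative of eif_f minus a constant adaptation offset w_bar/g_L,
# used in every exponentiated potential.  Constant of integration is
# irrelevant: only differences are exponentiated.
.eif_F <- function(V, p, mu_eff) {
  -(V - p$E_L)^2 / 2 +
    p$Delta_T^2 * exp(pmin((V - p$V_T) / p$Delta_T, 700)) +
    mu_eff * (V - p$E_L)
}

#' Canonical cortical cell parameter sets
#'
#' The four average parameter sets packaged with the library: layer-3 (L3)
#' and layer-5 (L5) pyramidal cells and fast-spiking (FS) and bitufted (BT)
#' interneurons, grand means of simplified-AdEx fits to rodent prefrontal
#' cortex recordings.
#'
#' @param cell Optional cell id (`"L3"`, `"L5"`, `"FS"`, `"BT"`); if given,
#'   the single [neuron_params()] object is returned.
#' @return A named list of [neuron_params()] (or one of them).
#' @export
canonical_cells <- function(cell = NULL) {
  path <- system.file("extdata", "canonical_cells.csv", package = "aeifrate",
                      mustWork = TRUE)
  cells <- load_params_csv(path)
  if (!is.null(cell)) {
    if (!cell %in% names(cells)) stop("unknown cell id '", cell, "'")
    return(cells[[cell]])
  }
  cells
}
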