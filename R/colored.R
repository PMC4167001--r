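#' Variance reduction for synaptically filtered (colored) noise
#'
#' An Ornstein-Uhlenbeck input current with correlation time `tau_s`
#' produces the same subthreshold voltage variance as white noise with the
#' amplitude reduced to `sigma / sqrt(1 + tau_s / tau_m)` (exact for the
#' leaky integrator), which lets the white-noise rate theory be reused for
#' colored input.
#'
#' @param sigma Noise amplitude (any consistent units).
#' @param tau_s Synaptic correlation time (ms).
#' @param tau_m Membrane time constant (ms).
#' @return Reduced amplitude, same units as `sigma`.
#' @export
sigma_reduced <- function(sigma, tau_s, tau_m) {
  stopifnot(tau_s >= 0, tau_m > 0)
  sigma / sqrt(1 + tau_s / tau_m)
}

#' Colored-noise firing rate via variance reduction
#'
#' Replaces the drive's noise amplitude by [sigma_reduced()] and dispatches
#' to the requested white-noise method.  With `tau_s = 0` this reproduces
#' the white-noise result exactly.
#'
#' @param d A [drive_spec()] (with `tau_s` possibly positive).
#' @param p A [neuron_params()] object.
#' @param method One of `"fw"`, `"fullfp"`, `"eifw"`.
#' @param ... Passed to the dispatched method.
#' @return A `rate_result` from the dispatched method.
#' @export
nu_colored_reduced <- function(d, p, method = c("fw", "fullfp", "eifw"),
                               ...) {
  method <- match.arg(method)
  stopifnot(inherits(d, "drive_spec"), inherits(p, "neuron_params"))
  tau_m <- membrane_time_constant(p)
  d_red <- drive_spec(d$mu_Isyn,
                      sigma_reduced(d$sigma_Isyn, d$tau_s, tau_m),
                      tau_s = 0)
  td <- convert_drive(d_red, p)
  switch(method,
         fw = nu_eif_fw(td, p, ...),
         fullfp = nu_fullfp(td, p, ...),
         eifw = nu0_selfconsistent(td, p, ...))
}

#' Second-order colored-noise rate correction
#'
#' The `k^2`-order correction (`k^2 = tau_s / tau_m`) to the EIF rate from
#' the expansion of the Fokker-Planck equation in the synaptic time scale:
#' `nu2 = nu0 * int dV int_V^Vup du exp(-(2/sigma^2) int_V^u f) *
#' (Q0/Delta_T + Q0') f'(u)` with `Q0` the stationary density normalised
#' to one and `f` including the mean-adaptation offset.
#'
#' @param td The [convert_drive()] result (white-noise-scaled drive).
#' @param p A [neuron_params()] object.
#' @param sd A [stationary_density()] at the self-consistent rate for this
#'   drive.
#' @return Rate correction in 1/ms (to be multiplied by `k^2`).
#' @export
nu2_cn <- function(td, p, sd) {
  stopifnot(inherits(sd, "stationary_density"))
  if (sd$nu0_ms <= 0) return(0)
  V <- sd$V
  n <- length(V)
  Q0n <- sd$nu0_ms * sd$Q0                 # probability density
  dQ0 <- numeric(n)
  dQ0[2:(n - 1)] <- (Q0n[3:n] - Q0n[1:(n - 2)]) / (V[3:n] - V[1:(n - 2)])
  dQ0[1] <- (Q0n[2] - Q0n[1]) / (V[2] - V[1])
  dQ0[n] <- (Q0n[n] - Q0n[n - 1]) / (V[n] - V[n - 1])
  fprime <- -1 + exp(pmin((V - p$V_T) / p$Delta_T, 700))
  H <- (Q0n / p$Delta_T + dQ0) * fprime
  inner <- ew_cumint(-sd$psi, H, V, FALSE)  # int_V^{Vup} e^{psi(V)-psi(u)} H
  sd$nu0_ms * .trapz(V, inner)
}

#' Colored-noise firing rate with explicit second-order correction
#'
#' Averages the per-adaptation-value corrected rate
#' `nu0(mu - w, sigma) + k^2 nu2` over the truncated-Gamma adaptation
#' distribution, with the same fixed-point structure as [nu_eif_fw()].
#' The `k`-expansion is used for `tau_s <= tau_m`; beyond that the
#' variance-reduction route is used instead, with a warning.
#'
#' @param d A [drive_spec()] with `tau_s >= 0`.
#' @param p A [neuron_params()] object.
#' @param n_grid,vlb_sigmas Grid controls, see [v_grid()].
#' @param gl_nodes Quadrature order over the adaptation distribution.
#' @param tol,max_iter Fixed-point controls.
#' @return A `rate_result` with method `"fw_cn2"`.
#' @export
nu_colored_secondorder <- function(d, p, n_grid = 8192, vlb_sigmas = 10,
                                   gl_nodes = 32, tol = 1e-6,
                                   max_iter = 100) {
  stopifnot(inherits(d, "drive_spec"), inherits(p, "neuron_params"))
  tau_m <- membrane_time_constant(p)
  k2 <- d$tau_s / tau_m
  if (k2 > 1) {
    warning("tau_s > tau_m: k-expansion unreliable, ",
            "using the variance-reduction route")
    return(nu_colored_reduced(d, p, method = "fw", n_grid = n_grid,
                              vlb_sigmas = vlb_sigmas))
  }
  td <- convert_drive(drive_spec(d$mu_Isyn, d$sigma_Isyn, 0), p)
  if (d$tau_s == 0) {
    r <- nu_eif_fw(td, p, n_grid = n_grid, vlb_sigmas = vlb_sigmas,
                   tol = tol, max_iter = max_iter)
    r$method <- "fw_cn2"
    return(r)
  }
  corrected_rate <- function(w_bar) {
    mu_eff <- td$mu - w_bar / p$g_L
    nu0 <- .eif_rate_white_ms(p, mu_eff, td$sigma, n_grid = n_grid,
                              vlb_sigmas = vlb_sigmas)
    if (nu0 <= 0) return(0)
    td_eff <- structure(list(mu = mu_eff, sigma = td$sigma),
                        class = "theory_drive")
    p0 <- p
    p0$b <- 0
    sd <- stationary_density(td_eff, p0, 1000 * nu0, n_grid = n_grid,
                             vlb_sigmas = vlb_sigmas)
    max(nu0 + k2 * nu2_cn(td_eff, p0, sd), 0)
  }
  if (p$b == 0) {
    return(.rate_result("fw_cn2", corrected_rate(0), iterations = 0L,
                        diagnostics = list(k2 = k2)))
  }
  r0 <- nu0_selfconsistent(td, p, n_grid = n_grid, vlb_sigmas = vlb_sigmas)
  nu <- max(r0$nu_Hz / 1000, 1e-6)
  gl <- .gauss_legendre(gl_nodes)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wd <- w_distribution(1000 * nu, td, p, n_grid = n_grid,
                         vlb_sigmas = vlb_sigmas)
    half <- (wd$w_max - wd$w_min) / 2
    mid <- (wd$w_max + wd$w_min) / 2
    x <- mid + half * gl$nodes
    wts <- half * gl$weights
    pdf <- truncated_gamma_pdf(x, wd)
    z <- sum(wts * pdf)
    rate_nodes <- vapply(x, corrected_rate, numeric(1))
    nu_raw <- sum(wts * pdf * rate_nodes) / z
    nu_new <- 0.5 * nu + 0.5 * nu_raw
    done <- abs(nu_new - nu) < tol
    nu <- nu_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  .rate_result("fw_cn2", nu, nu0_ms = r0$nu_Hz / 1000,
               iterations = it, converged = converged,
               diagnostics = list(k2 = k2))
}
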