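#' Second-order rate correction of the 2-D Fokker-Planck expansion
#'
#' Evaluates the second-order correction `nu2` of the perturbation
#' expansion of the aEIF firing rate in `eps = tau_m / tau_w`, from
#' compositions of the integral operators J and K applied to the
#' zeroth-order stationary density.  Internally the calculation is carried
#' out in nondimensional form: rates as spikes per membrane time constant
#' (`nu * tau_m`) and the adaptation increment as the voltage equivalent
#' `b * tau_w / (g_L * tau_m)` (mV), so that their product is the mean
#' adaptation potential `<w>/g_L`.
#'
#' @param sd A [stationary_density()] computed at the self-consistent rate.
#' @param p The [neuron_params()] used to build `sd`.
#' @param td The [convert_drive()] result used to build `sd`.
#' @return List of intermediates: `eps`, `z2_0` (stationary variance of the
#'   scaled adaptation fluctuation), `Ra`, `IR1`, the operator compositions
#'   `KJQ0`, `KJKQ0`, `KJ2Q0`, `KJ2KQ0` evaluated at `V_up`, and `nu2_ms`
#'   (1/ms).
#' @export
nu2_correction <- function(sd, p, td) {
  stopifnot(inherits(sd, "stationary_density"), inherits(p, "neuron_params"))
  tau_m <- sd$tau_m
  eps <- tau_m / p$tau_w
  if (p$b == 0 || sd$nu0_ms <= 0) {
    return(list(eps = eps, z2_0 = NA_real_, Ra = NA_real_, IR1 = NA_real_,
                KJQ0 = NA_real_, KJKQ0 = NA_real_, KJ2Q0 = NA_real_,
                KJ2KQ0 = NA_real_, nu2_ms = 0))
  }
  V <- sd$V
  psi <- sd$psi
  Jt <- function(g) 2 / .s2eff(sd$sigma) * ew_cumint(-psi, g, V, FALSE)
  nut0 <- sd$nu0_ms * tau_m                  # dimensionless rate
  bt <- p$b * p$tau_w / (p$g_L * tau_m)      # adaptation increment, mV
  Q0t <- sd$Q0 / tau_m                       # dimensionless-normalised Q0
  JQ0 <- Jt(Q0t)
  KQ0 <- .cumtrapz(V, Q0t)
  JKQ0 <- Jt(KQ0)
  KJQ0 <- .trapz(V, JQ0)
  KJKQ0 <- .trapz(V, JKQ0)
  KJ2Q0 <- .trapz(V, Jt(JQ0))
  KJ2KQ0 <- .trapz(V, Jt(JKQ0))
  z2_0 <- (nut0 * KJKQ0 - 1 / (2 * nut0)) /
          (1 / nut0 + bt * nut0 * KJQ0)
  D <- KJKQ0 - 1 / (2 * nut0^2)
  Ra <- KJQ0 / D
  IR1 <- bt * KJQ0 - z2_0 * KJKQ0 + bt^2 * nut0 * KJ2Q0 -
         bt * nut0 * z2_0 * KJ2KQ0
  num <- bt * z2_0 * (nut0 * KJ2KQ0 - bt * z2_0 * nut0 * KJ2Q0 -
                        Ra * z2_0 / 2 * IR1)
  den <- KJKQ0 + bt^2 * z2_0^2 * Ra * KJQ0 + bt * z2_0^2 * Ra / nut0^2 -
         1 / (2 * nut0^2)
  nut2 <- num / den
  list(eps = eps, z2_0 = z2_0, Ra = Ra, IR1 = IR1,
       KJQ0 = KJQ0, KJKQ0 = KJKQ0, KJ2Q0 = KJ2Q0, KJ2KQ0 = KJ2KQ0,
       nu2_ms = nut2 / tau_m)
}

#' Full Fokker-Planck firing-rate approximation
#'
#' Composes the self-consistent adapted EIF rate, the stationary density
#' and the second-order correction into
#' `nu = nu0 + eps^2 * nu2` with `eps = tau_m / tau_w`.  A negative total
#' is clamped to zero and flagged in the diagnostics.
#'
#' @inheritParams eif_rate_white
#' @param n_grid,vlb_sigmas Grid controls, see [v_grid()].
#' @return A `rate_result` with method `"fullfp"`, carrying `nu0_Hz`,
#'   `nu2_Hz`, `eps` and the correction intermediates in `diagnostics`.
#' @export
nu_fullfp <- function(td, p, n_grid = 8192, vlb_sigmas = 10) {
  r0 <- nu0_selfconsistent(td, p, n_grid = n_grid, vlb_sigmas = vlb_sigmas)
  nu0_ms <- r0$nu_Hz / 1000
  eps <- membrane_time_constant(p) / p$tau_w
  if (nu0_ms <= 0 || p$b == 0) {
    return(.rate_result("fullfp", nu0_ms, nu0_ms = nu0_ms, nu2_ms = 0,
                        eps = eps, converged = r0$converged,
                        iterations = r0$iterations))
  }
  sd <- stationary_density(td, p, r0$nu_Hz, n_grid = n_grid,
                           vlb_sigmas = vlb_sigmas)
  corr <- nu2_correction(sd, p, td)
  nu_ms <- nu0_ms + corr$eps^2 * corr$nu2_ms
  clamped <- nu_ms < 0
  if (clamped) nu_ms <- 0
  .rate_result("fullfp", nu_ms, nu0_ms = nu0_ms, nu2_ms = corr$nu2_ms,
               eps = corr$eps, converged = r0$converged,
               iterations = r0$iterations,
               diagnostics = c(corr[c("z2_0", "Ra", "IR1", "KJQ0", "KJKQ0",
                                      "KJ2Q0", "KJ2KQ0")],
                               list(clamped = clamped)))
}
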