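#' Voltage grid for the Fokker-Planck quadratures
#'
#' Builds an (almost) uniform grid on `[V_lb, V_up]` that contains `V_r`
#' and `V_T` exactly.  The lower bound truncates the formally infinite
#' integration domain where the Gaussian tail of the stationary density is
#' negligible: `V_lb = min(V_r, E_L + mu_eff) - vlb_sigmas * sigma`.
#'
#' @param p A [neuron_params()] object.
#' @param mu_eff Effective voltage-scaled drive (mV), including any mean
#'   adaptation offset.
#' @param sigma Voltage-scaled noise amplitude (mV), positive.
#' @param n Number of grid points (default 8192).
#' @param vlb_sigmas Lower-bound margin in units of `sigma` (default 10).
#' @return List with `V` (sorted voltages, last point `V_up`) and `n`.
#' @export
v_grid <- function(p, mu_eff, sigma, n = 8192, vlb_sigmas = 10) {
  stopifnot(inherits(p, "neuron_params"), sigma > 0, n >= 16)
  V_lb <- min(p$V_r, p$E_L + mu_eff) - vlb_sigmas * sigma
  V <- seq(V_lb, p$V_up, length.out = n)
  V <- sort(unique(c(V, p$V_r, p$V_T)))
  list(V = V, n = length(V))
}

# trapezoid weights / integrals on an arbitrary sorted grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}
.revcumtrapz <- function(x, y) {           # int_{x_i}^{x_n} y dx
  ct <- .cumtrapz(x, y)
  ct[length(ct)] - ct
}

# Effective squared noise amplitude entering the Fokker-Planck formulas.
# The interface-level sigma follows the sigma_V = sigma/2 normalisation of
# the subthreshold voltage fluctuations (sigma = sigma_Isyn/C *
# sqrt(2 tau_m)); for the unit-variance delta-correlated noise source the
# diffusion coefficient of the voltage equation is sigma^2/4, so every
# exponentiated potential and prefactor carries sigma_eff^2 = sigma^2/2.
.s2eff <- function(sigma) sigma^2 / 2

# Exponentiated potential psi(V) = (2/sigma_eff^2) * F(V; mu_eff).
.psi <- function(V, p, mu_eff, sigma) 2 / .s2eff(sigma) * .eif_F(V, p, mu_eff)

# Heaviside restriction Theta(V - V_r) as grid values.  Used both inside
# the stationary density and in the rate normalisation so that the two
# discretisations agree identically.
.theta_vr <- function(V, V_r) as.numeric(V >= V_r)

# White-noise EIF rate in 1/ms at effective drive mu_eff = mu - w_bar/g_L.
# 1/nu = (2 tau_m / sigma^2) * int_{V_r}^{V_up} du e^{-psi(u)} A(u),
# A(u) = int_{V_lb}^{u} e^{psi}, evaluated by the stable local-difference
# recurrence (ew_cumint); rates below 1e-8 / ms are clamped to zero.
.eif_rate_white_ms <- function(p, mu_eff, sigma, n_grid = 8192,
                               vlb_sigmas = 10, grid = NULL) {
  g <- if (is.null(grid)) v_grid(p, mu_eff, sigma, n = n_grid,
                                 vlb_sigmas = vlb_sigmas) else grid
  V <- g$V
  psi <- .psi(V, p, mu_eff, sigma)
  a <- ew_cumint(psi, rep(1, length(V)), V, TRUE)
  tau_m <- membrane_time_constant(p)
  inv_nu <- 2 * tau_m / .s2eff(sigma) * .trapz(V, a * .theta_vr(V, p$V_r))
  if (!is.finite(inv_nu) || inv_nu <= 0) return(0)
  nu <- 1 / inv_nu
  if (nu < 1e-8) 0 else nu
}

#' White-noise EIF firing rate with a fixed adaptation offset
#'
#' Steady-state rate of the exponential integrate-and-fire neuron driven by
#' Gaussian white noise, with the mean input reduced by a fixed adaptation
#' current `w_bar` (pA).  This is the non-self-consistent kernel used by
#' all higher-level approximations.
#'
#' @param td A [convert_drive()] result (voltage-scaled drive).
#' @param p A [neuron_params()] object.
#' @param w_bar Fixed adaptation current offset (pA), default 0.
#' @param n_grid Number of voltage-grid points.
#' @param vlb_sigmas Lower integration bound margin, see [v_grid()].
#' @return Firing rate in Hz.
#' @export
eif_rate_white <- function(td, p, w_bar = 0, n_grid = 8192, vlb_sigmas = 10) {
  stopifnot(inherits(td, "theory_drive"), inherits(p, "neuron_params"))
  if (td$sigma <= 0) stop("sigma must be positive for the Fokker-Planck rate")
  1000 * .eif_rate_white_ms(p, td$mu - w_bar / p$g_L, td$sigma,
                            n_grid = n_grid, vlb_sigmas = vlb_sigmas)
}

.rate_result <- function(method, nu_ms, nu0_ms = NULL, nu2_ms = NULL,
                         eps = NULL, converged = TRUE, iterations = NA_integer_,
                         diagnostics = list()) {
  structure(list(method = method,
                 nu_Hz = 1000 * nu_ms,
                 nu0_Hz = if (is.null(nu0_ms)) NULL else 1000 * nu0_ms,
                 nu2_Hz = if (is.null(nu2_ms)) NULL else 1000 * nu2_ms,
                 eps = eps, converged = converged, iterations = iterations,
                 diagnostics = diagnostics),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("aEIF rate [%s]: %.6g Hz", x$method, x$nu_Hz))
  if (!is.null(x$nu0_Hz)) cat(sprintf("  (nu0 = %.6g Hz)", x$nu0_Hz))
  if (!is.null(x$eps)) cat(sprintf("  eps = %.4g", x$eps))
  if (!isTRUE(x$converged)) cat("  [NOT CONVERGED]")
  cat("\n")
  invisible(x)
}

#' Self-consistent adapted EIF rate (EIF-\eqn{\langle w\rangle} approach)
#'
#' Solves `nu = Phi(nu)` where `Phi(nu)` is the white-noise EIF rate with
#' the mean input reduced by the mean adaptation current
#' `b * nu * tau_w`.  `Phi` is non-increasing in `nu`, so the root on
#' `[0, Phi(0)]` is unique and is found by bracketed root finding.
#'
#' @inheritParams eif_rate_white
#' @param tol Convergence tolerance on the rate (1/ms), default 1e-12.
#' @param max_iter Maximum root-finder iterations.
#' @return A `rate_result` with method `"eifw"`; `diagnostics$residual_ms`
#'   holds the self-consistency residual `|nu - Phi(nu)|` in 1/ms.
#' @export
nu0_selfconsistent <- function(td, p, n_grid = 8192, vlb_sigmas = 10,
                               tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(td, "theory_drive"), inherits(p, "neuron_params"))
  if (td$sigma <= 0) stop("sigma must be positive for the Fokker-Planck rate")
  phi <- function(nu_ms)
    .eif_rate_white_ms(p, td$mu - p$b * nu_ms * p$tau_w / p$g_L, td$sigma,
                       n_grid = n_grid, vlb_sigmas = vlb_sigmas)
  phi0 <- phi(0)
  if (p$b == 0 || phi0 == 0) {
    return(.rate_result("eifw", phi0, iterations = 0L,
                        diagnostics = list(residual_ms = 0)))
  }
  root <- stats::uniroot(function(nu) nu - phi(nu),
                         interval = c(0, phi0 * (1 + 1e-12)),
                         tol = tol, maxiter = max_iter)
  nu <- root$root
  res <- abs(nu - phi(nu))
  .rate_result("eifw", nu, iterations = as.integer(root$iter),
               converged = res < 1e-6,
               diagnostics = list(residual_ms = res))
}

#' Zeroth-order stationary voltage density
#'
#' The marginal stationary density `Q0(V)` of the adapted EIF on the
#' voltage grid, normalised so that its integral equals `1 / nu0` with
#' `nu0` in 1/ms (equivalently, `nu0 * Q0` is a probability density).
#'
#' @inheritParams eif_rate_white
#' @param nu0_Hz Self-consistent rate from [nu0_selfconsistent()] for the
#'   same drive and parameters (Hz).
#' @param n_grid,vlb_sigmas Grid controls, see [v_grid()].
#' @return An object of class `stationary_density` with fields `V`, `Q0`,
#'   `psi`, `nu0_ms`, `mu_eff`, `sigma`.
#' @export
stationary_density <- function(td, p, nu0_Hz, n_grid = 8192,
                               vlb_sigmas = 10) {
  stopifnot(inherits(td, "theory_drive"), inherits(p, "neuron_params"))
  nu0_ms <- nu0_Hz / 1000
  mu_eff <- td$mu - p$b * nu0_ms * p$tau_w / p$g_L
  g <- v_grid(p, mu_eff, td$sigma, n = n_grid, vlb_sigmas = vlb_sigmas)
  V <- g$V
  psi <- .psi(V, p, mu_eff, td$sigma)
  tau_m <- membrane_time_constant(p)
  theta <- .theta_vr(V, p$V_r)
  Q0 <- 2 * tau_m / .s2eff(td$sigma) * ew_cumint(-psi, theta, V, FALSE)
  sd <- structure(list(V = V, Q0 = Q0, psi = psi, nu0_ms = nu0_ms,
                       mu_eff = mu_eff, sigma = td$sigma, tau_m = tau_m),
                  class = "stationary_density")
  if (nu0_ms > 0) {
    # discretisation identity: the integral of Q0 equals the inverse rate
    # evaluated on the same grid (holds to rounding error); the rate the
    # caller supplied may come from a different resolution, so it is only
    # checked loosely
    a <- ew_cumint(psi, rep(1, length(V)), V, TRUE)
    inv_nu_grid <- 2 * tau_m / .s2eff(td$sigma) * .trapz(V, a * theta)
    norm <- .trapz(V, Q0)
    if (abs(norm - inv_nu_grid) > 1e-6 * inv_nu_grid)
      stop("grid too coarse: density normalisation check failed (",
           format(norm / inv_nu_grid), " != 1)")
    if (abs(inv_nu_grid - 1 / nu0_ms) > 0.01 / nu0_ms)
      stop("supplied nu0 is inconsistent with this drive and grid")
  }
  sd
}

#' Integral operator J on the voltage grid
#'
#' `J g (V) = (2 tau_m / sigma^2) * int_V^{V_up} exp(-(2/sigma^2)
#' int_V^u (f(x) - w_bar/g_L) dx) g(u) du`, evaluated with the stationary
#' density's own exponentiated potential.
#'
#' @param g Function values on `sd$V`.
#' @param sd A [stationary_density()] object.
#' @param p The [neuron_params()] used to build `sd`.
#' @return Values of `J g` on the same grid.
#' @export
apply_J <- function(g, sd, p) {
  stopifnot(inherits(sd, "stationary_density"), length(g) == length(sd$V))
  2 * sd$tau_m / .s2eff(sd$sigma) * ew_cumint(-sd$psi, g, sd$V, FALSE)
}

#' Integral operator K (cumulative integral from the lower bound)
#'
#' `K g (V) = int_{V_lb}^{V} g(u) du`; the value "at `V_up`" is the last
#' grid value.
#'
#' @param g Function values on `sd$V`.
#' @param sd A [stationary_density()] object (supplies the grid).
#' @return Values of `K g` on the same grid.
#' @export
apply_K <- function(g, sd) {
  stopifnot(inherits(sd, "stationary_density"), length(g) == length(sd$V))
  .cumtrapz(sd$V, g)
}
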