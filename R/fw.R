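#' Theoretical interspike-interval moments of the adapted EIF
#'
#' First-passage-time mean and variance from reset to the detection
#' threshold for the EIF with the mean input reduced by the mean adaptation
#' current `b * nu * tau_w`.  Both moments are obtained by quadrature of
#' the first-passage moment hierarchy
#' `sigma^2/2 T_k'' + f T_k' = -k tau_m T_{k-1}` with reflecting lower and
#' absorbing upper boundary, using the same stable exponentially weighted
#' cumulative integrals as the rate formula; the mean is exactly the
#' inverse of the white-noise EIF rate at the effective drive.
#'
#' @inheritParams eif_rate_white
#' @param nu Firing rate used for the mean-adaptation offset (Hz); pass the
#'   self-consistent rate for this drive.
#' @param n_grid,vlb_sigmas Grid controls, see [v_grid()].
#' @return List with `mean` (ms), `variance` (ms^2), `cv`, and the implied
#'   Gamma parameterisation `k` (shape) and `theta` (scale, ms).
#' @export
isi_moments <- function(td, p, nu, n_grid = 8192, vlb_sigmas = 10) {
  stopifnot(inherits(td, "theory_drive"), inherits(p, "neuron_params"))
  if (td$sigma <= 0) stop("sigma must be positive")
  nu_ms <- nu / 1000
  mu_eff <- td$mu - p$b * nu_ms * p$tau_w / p$g_L
  g <- v_grid(p, mu_eff, td$sigma, n = n_grid, vlb_sigmas = vlb_sigmas)
  V <- g$V
  psi <- .psi(V, p, mu_eff, td$sigma)
  tau_m <- membrane_time_constant(p)
  pref <- 2 * tau_m / .s2eff(td$sigma)
  ones <- rep(1, length(V))
  a <- ew_cumint(psi, ones, V, TRUE)         # e^{-psi} * int e^{psi}
  T1 <- pref * .revcumtrapz(V, a)            # mean FPT from each V
  ir <- which(V == p$V_r)[1]
  m1 <- T1[ir]
  bvec <- ew_cumint(psi, T1, V, TRUE)        # e^{-psi} * int e^{psi} T1
  T2 <- 2 * pref * .revcumtrapz(V, bvec)
  m2 <- T2[ir]
  vv <- max(m2 - m1^2, 0)
  nu_hat <- 1 / m1
  list(mean = m1, variance = vv, cv = sqrt(vv) / m1,
       k = 1 / (nu_hat^2 * vv), theta = nu_hat * vv)
}

#' Laplace transform of the Gamma ISI density at 1/tau_w
#'
#' For interspike intervals modeled as Gamma with shape `k` and scale
#' `theta` (from the ISI mean and variance), the Laplace transform at
#' `1/tau_w` is `(tau_w / (theta + tau_w))^k`.  A zero ISI variance
#' degenerates to the point-mass limit `exp(-1/(nu tau_w))`.
#'
#' @param isi Result of [isi_moments()] (or any list with `mean`,
#'   `variance`, `k`, `theta`).
#' @param tau_w Adaptation time constant (ms).
#' @return Dimensionless value in (0, 1).
#' @export
isi_beta1 <- function(isi, tau_w) {
  if (isi$variance <= 0 || !is.finite(isi$k)) return(exp(-isi$mean / tau_w))
  (tau_w / (isi$theta + tau_w))^isi$k
}

#' Stationary mean and variance of the adaptation current
#'
#' Moments of the exponentially filtered spike train with increment `b` and
#' filter time constant `tau_w`: mean `b * nu * tau_w`, and variance
#' `b^2 tau_w nu / 2 * ((1 + beta1)/(1 - beta1) - 2 tau_w nu)` where
#' `beta1` is the Laplace transform of the ISI density at `1/tau_w`.  For
#' nearly periodic trains the variance expression can turn non-positive;
#' it is then replaced by the uniform-density variance `b^2 / 12` on the
#' periodic-train bounds (flagged in the result).
#'
#' @param nu Firing rate (Hz).
#' @param beta1 Laplace transform of the ISI density at `1/tau_w`.
#' @param p A [neuron_params()] object.
#' @return List with `mean` (pA), `variance` (pA^2) and `fallback`
#'   (logical; `TRUE` when the uniform-density fallback was used).
#' @export
w_moments <- function(nu, beta1, p) {
  stopifnot(inherits(p, "neuron_params"))
  nu_ms <- nu / 1000
  m <- p$b * nu_ms * p$tau_w
  bracket <- (1 + beta1) / (1 - beta1) - 2 * p$tau_w * nu_ms
  v <- p$b^2 * p$tau_w * nu_ms / 2 * bracket
  fallback <- !is.finite(v) || v <= 0
  if (fallback) v <- p$b^2 / 12
  list(mean = m, variance = v, fallback = fallback)
}

#' Periodic-train bounds of the adaptation current
#'
#' Steady-state minimum and maximum of the exponentially filtered spike
#' train for a perfectly periodic train at rate `nu`; their difference is
#' exactly `b`.
#'
#' @param nu Firing rate (Hz).
#' @param p A [neuron_params()] object.
#' @return List with `w_min` and `w_max` (pA).
#' @export
w_bounds <- function(nu, p) {
  stopifnot(inherits(p, "neuron_params"))
  nu_ms <- nu / 1000
  if (nu_ms <= 0) return(list(w_min = 0, w_max = p$b))
  e1 <- exp(-1 / (p$tau_w * nu_ms))
  list(w_min = p$b * e1 / (1 - e1), w_max = p$b / (1 - e1))
}

#' Truncated-Gamma model of the adaptation-current distribution
#'
#' Combines the filtered-spike-train moments with the periodic-train
#' truncation bounds into a Gamma density with shape `<w>^2 / var(w)` and
#' scale `var(w) / <w>`, renormalised on `[w_min, w_max]`.
#'
#' @param nu Firing rate (Hz).
#' @param td,p Drive and parameters (the drive supplies the effective input
#'   for the ISI moments).
#' @param isi Optional precomputed [isi_moments()]; computed when missing.
#' @param n_grid,vlb_sigmas Grid controls for the ISI quadrature.
#' @return An object of class `w_distribution`: `mean`, `variance`,
#'   `shape`, `scale`, `w_min`, `w_max`, `beta1`, `fallback`.
#' @export
w_distribution <- function(nu, td, p, isi = NULL, n_grid = 8192,
                           vlb_sigmas = 10) {
  if (is.null(isi))
    isi <- isi_moments(td, p, nu, n_grid = n_grid, vlb_sigmas = vlb_sigmas)
  b1 <- isi_beta1(isi, p$tau_w)
  wm <- w_moments(nu, b1, p)
  wb <- w_bounds(nu, p)
  structure(list(mean = wm$mean, variance = wm$variance,
                 shape = wm$mean^2 / wm$variance,
                 scale = wm$variance / wm$mean,
                 w_min = wb$w_min, w_max = wb$w_max,
                 beta1 = b1, fallback = wm$fallback),
            class = "w_distribution")
}

#' Truncated-Gamma adaptation density
#'
#' @param x Adaptation current value(s) (pA).
#' @param wd A [w_distribution()] object.
#' @return Density values (1/pA); zero outside `[w_min, w_max]`.
#' @export
truncated_gamma_pdf <- function(x, wd) {
  stopifnot(inherits(wd, "w_distribution"))
  if (wd$shape <= 0 || wd$scale <= 0)
    stop("non-positive Gamma shape or scale")
  mass <- stats::pgamma(wd$w_max, shape = wd$shape, scale = wd$scale) -
          stats::pgamma(wd$w_min, shape = wd$shape, scale = wd$scale)
  out <- numeric(length(x))
  inside <- x >= wd$w_min & x <= wd$w_max
  if (mass > 1e-300) {
    out[inside] <- stats::dgamma(x[inside], shape = wd$shape,
                                 scale = wd$scale) / mass
  } else {
    # numerically degenerate truncation window: renormalise the log-density
    # on the window itself
    xs <- x[inside]
    ref <- seq(wd$w_min, wd$w_max, length.out = 257)
    lp <- stats::dgamma(ref, shape = wd$shape, scale = wd$scale, log = TRUE)
    sh <- max(lp)
    z <- .trapz(ref, exp(lp - sh))
    out[inside] <- exp(stats::dgamma(xs, shape = wd$shape, scale = wd$scale,
                                     log = TRUE) - sh) / z
  }
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1)] <- beta
  Jm[cbind(i + 1, i)] <- beta
  e <- eigen(Jm, symmetric = TRUE)
  nodes <- rev(e$values)
  weights <- rev(2 * e$vectors[1, ]^2)
  out <- list(nodes = nodes, weights = weights)
  .gl_cache[[key]] <- out
  out
}

#' EIF-F(w) firing-rate approximation
#'
#' Averages the white-noise EIF rate over the truncated-Gamma model of the
#' adaptation-current distribution,
#' `nu = int F(w) nu_EIF(mu - w/g_L, sigma) dw`, solved as a damped fixed
#' point in the rate that parameterises `F(w)`.
#'
#' @inheritParams eif_rate_white
#' @param n_grid,vlb_sigmas Grid controls, see [v_grid()].
#' @param gl_nodes Gauss-Legendre quadrature order over `[w_min, w_max]`.
#' @param tol Convergence tolerance on the rate (1/ms).
#' @param max_iter Maximum fixed-point iterations.
#' @return A `rate_result` with method `"fw"`; diagnostics carry the final
#'   `w_distribution` and the iteration trace.
#' @export
nu_eif_fw <- function(td, p, n_grid = 8192, vlb_sigmas = 10, gl_nodes = 64,
                      tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(td, "theory_drive"), inherits(p, "neuron_params"))
  if (td$sigma <= 0) stop("sigma must be positive")
  nu_white <- .eif_rate_white_ms(p, td$mu, td$sigma, n_grid = n_grid,
                                 vlb_sigmas = vlb_sigmas)
  if (p$b == 0) {
    return(.rate_result("fw", nu_white, nu0_ms = nu_white, iterations = 0L))
  }
  r0 <- nu0_selfconsistent(td, p, n_grid = n_grid, vlb_sigmas = vlb_sigmas)
  nu0_ms <- r0$nu_Hz / 1000
  if (nu0_ms <= 0 && nu_white <= 0) {
    return(.rate_result("fw", 0, nu0_ms = 0, iterations = 0L))
  }
  gl <- .gauss_legendre(gl_nodes)
  nu <- max(nu0_ms, 1e-6)
  trace <- numeric(0)
  converged <- FALSE
  wd <- NULL
  for (it in seq_len(max_iter)) {
    wd <- w_distribution(1000 * nu, td, p, n_grid = n_grid,
                         vlb_sigmas = vlb_sigmas)
    half <- (wd$w_max - wd$w_min) / 2
    mid <- (wd$w_max + wd$w_min) / 2
    x <- mid + half * gl$nodes
    wts <- half * gl$weights
    pdf <- truncated_gamma_pdf(x, wd)
    z <- sum(wts * pdf)
    rate_nodes <- vapply(x, function(wv)
      .eif_rate_white_ms(p, td$mu - wv / p$g_L, td$sigma, n_grid = n_grid,
                         vlb_sigmas = vlb_sigmas), numeric(1))
    nu_raw <- sum(wts * pdf * rate_nodes) / z
    nu_new <- 0.5 * nu + 0.5 * nu_raw
    trace <- c(trace, nu_new)
    if (abs(nu_new - nu) < tol) {
      nu <- nu_new
      converged <- TRUE
      break
    }
    nu <- nu_new
  }
  .rate_result("fw", nu, nu0_ms = nu0_ms, iterations = length(trace),
               converged = converged,
               diagnostics = list(w_dist = wd, trace_ms = trace))
}
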