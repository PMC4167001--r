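#' Relative rate-prediction error
#'
#' Mean over drive conditions of `|nu_sim - nu_model| / nu_sim`, excluding
#' points where the simulated rate is zero.
#'
#' @param nu_sim Simulated rates (Hz).
#' @param nu_model Predicted rates (Hz), same length.
#' @return Mean relative error (fraction).
#' @export
err_rel <- function(nu_sim, nu_model) {
  stopifnot(length(nu_sim) == length(nu_model))
  keep <- nu_sim > 0 & is.finite(nu_model)
  if (!any(keep)) stop("no points with positive simulated rate")
  mean(abs(nu_sim[keep] - nu_model[keep]) / nu_sim[keep])
}

.theory_rate <- function(method, d, p, n_grid, vlb_sigmas) {
  td <- convert_drive(d, p)
  switch(method,
         eifw = nu0_selfconsistent(td, p, n_grid = n_grid,
                                   vlb_sigmas = vlb_sigmas),
         fullfp = nu_fullfp(td, p, n_grid = n_grid,
                            vlb_sigmas = vlb_sigmas),
         fw = nu_eif_fw(td, p, n_grid = n_grid, vlb_sigmas = vlb_sigmas),
         stop("unknown method '", method, "'"))
}

#' Theory-versus-simulation rate sweep
#'
#' Runs the stochastic simulator and the requested rate approximations
#' over a grid of mean drives and noise amplitudes, and summarises the
#' agreement with [err_rel()].
#'
#' @param cells Named list of [neuron_params()] (e.g. [canonical_cells()]).
#' @param mu_offsets Mean-drive grid relative to each cell's rheobase (pA);
#'   ignored when `mu_abs` is given.
#' @param mu_abs Optional absolute mean-drive grid (pA).
#' @param sigma Noise-amplitude grid (pA sqrt(ms)).
#' @param b_override Optional adaptation increment(s) overriding each
#'   cell's `b` (pA); the sweep crosses cells with every value.
#' @param methods Character vector from `"eifw"`, `"fullfp"`, `"fw"`.
#' @param replicates Simulation replicates per grid point.
#' @param duration,dt,discard Simulation controls (ms).
#' @param seed Base seed; replicate `r` of point `i` uses
#'   `seed + 1000 * i + r`.
#' @param n_grid,vlb_sigmas Theory grid controls.
#' @return List of class `fi_curve`: `points` (per-condition data frame
#'   with simulated mean rate, its standard error and each method's
#'   prediction) and `errors` (per cell, `b` and method [err_rel()],
#'   averaged over the sigma grid).
#' @export
fi_curve <- function(cells, mu_offsets = c(-20, -10, -5, 0, 5, 10, 20, 50),
                     mu_abs = NULL, sigma = 150, b_override = NULL,
                     methods = c("eifw", "fullfp", "fw"), replicates = 5,
                     duration = 50000, dt = 0.05, discard = 5000,
                     seed = 1, n_grid = 8192, vlb_sigmas = 10) {
  stopifnot(length(cells) >= 1, replicates >= 1)
  if (is.null(names(cells)))
    names(cells) <- vapply(cells, function(p) p$cell, character(1))
  b_grid <- if (is.null(b_override)) NA_real_ else b_override
  rows <- list()
  idx <- 0L
  for (cn in names(cells)) {
    for (bv in b_grid) {
      p <- cells[[cn]]
      if (!is.na(bv)) p$b <- bv
      r0 <- rheobase(p)
      mu_grid <- if (is.null(mu_abs)) r0 + mu_offsets else mu_abs
      for (sg in sigma) for (mu in mu_grid) {
        idx <- idx + 1L
        d <- drive_spec(mu, sg)
        rates <- vapply(seq_len(replicates), function(r) {
          sim <- simulate_aeif(p, d, dt = dt, duration = duration,
                               discard = discard,
                               seed = seed + 1000L * idx + r)
          steady_state_rate(sim)
        }, numeric(1))
        row <- data.frame(cell = cn, b = p$b, mu_Isyn = mu, sigma_Isyn = sg,
                          nu_sim = mean(rates),
                          nu_sim_se = stats::sd(rates) / sqrt(replicates),
                          stringsAsFactors = FALSE)
        for (m in methods)
          row[[paste0("nu_", m)]] <-
            .theory_rate(m, d, p, n_grid, vlb_sigmas)$nu_Hz
        rows[[idx]] <- row
      }
    }
  }
  pts <- do.call(rbind, rows)
  err_rows <- list()
  for (cn in unique(pts$cell)) for (bv in unique(pts$b[pts$cell == cn])) {
    sub <- pts[pts$cell == cn & pts$b == bv & pts$nu_sim > 0, , drop = FALSE]
    if (!nrow(sub)) next
    for (m in methods) {
      err_rows[[length(err_rows) + 1L]] <-
        data.frame(cell = cn, b = bv, method = m,
                   err_rel = err_rel(sub$nu_sim, sub[[paste0("nu_", m)]]),
                   abs_err_Hz = mean(abs(sub$nu_sim -
                                           sub[[paste0("nu_", m)]])),
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(points = pts, errors = do.call(rbind, err_rows),
                 seed = seed),
            class = "fi_curve")
}

#' Subthreshold voltage-fluctuation table
#'
#' For each cell and noise amplitude, simulates the aEIF at its rheobase
#' and reports the spike-excised subthreshold voltage SD.
#'
#' @param cells Named list of [neuron_params()].
#' @param sigma Noise-amplitude grid (pA sqrt(ms)).
#' @param duration,dt,discard Simulation controls (ms).
#' @param window Spike-excision half-window (ms).
#' @param seed Base seed.
#' @return Data frame: one row per `sigma_Isyn`, one column per cell (mV).
#' @export
sigma_v_table <- function(cells, sigma = c(50, 150, 250, 350, 500, 700),
                          duration = 50000, dt = 0.05, discard = 5000,
                          window = 10, seed = 1) {
  if (is.null(names(cells)))
    names(cells) <- vapply(cells, function(p) p$cell, character(1))
  out <- data.frame(sigma_Isyn = sigma)
  for (cn in names(cells)) {
    p <- cells[[cn]]
    vals <- vapply(seq_along(sigma), function(i) {
      sim <- simulate_aeif(p, drive_spec(rheobase(p), sigma[i]),
                           dt = dt, duration = duration, discard = discard,
                           seed = seed + 37L * i, record_trace = TRUE)
      subthreshold_sigma_v(sim, window = window)
    }, numeric(1))
    out[[cn]] <- vals
  }
  out
}

#' Accuracy of the slow-adaptation expansion versus its small parameter
#'
#' Varies `eps = tau_m / tau_w` while holding the mean adaptation current
#' fixed (by co-scaling `b` so that `b * tau_w` is constant) and compares
#' the full Fokker-Planck prediction with simulation at each `eps`.
#'
#' @param p A [neuron_params()] object (its `b`, `tau_w` set the fixed
#'   `b * tau_w` product).
#' @param d A [drive_spec()] object.
#' @param eps_grid Values of `tau_m / tau_w` in (0, 1].
#' @param replicates Simulation replicates per `eps`.
#' @param duration,dt,discard Simulation controls (ms).
#' @param seed Base seed.
#' @param n_grid Theory grid control.
#' @return Data frame with per-`eps` simulated rate (and SE), `nu0`,
#'   `nu_fullfp`, and relative errors of both predictions.
#' @export
epsilon_sweep <- function(p, d, eps_grid = c(0.1, 0.2, 0.44),
                          replicates = 5, duration = 50000, dt = 0.05,
                          discard = 5000, seed = 1, n_grid = 8192) {
  stopifnot(inherits(p, "neuron_params"), inherits(d, "drive_spec"))
  tau_m <- membrane_time_constant(p)
  btau <- p$b * p$tau_w
  rows <- lapply(seq_along(eps_grid), function(i) {
    eps <- eps_grid[i]
    pe <- p
    pe$tau_w <- tau_m / eps
    pe$b <- btau / pe$tau_w
    rates <- vapply(seq_len(replicates), function(r) {
      sim <- simulate_aeif(pe, d, dt = dt, duration = duration,
                           discard = discard, seed = seed + 1000L * i + r)
      steady_state_rate(sim)
    }, numeric(1))
    td <- convert_drive(d, pe)
    rf <- nu_fullfp(td, pe, n_grid = n_grid)
    data.frame(eps = eps, nu_sim = mean(rates),
               nu_sim_se = stats::sd(rates) / sqrt(replicates),
               nu0 = rf$nu0_Hz, nu_fullfp = rf$nu_Hz,
               err_nu0 = abs(mean(rates) - rf$nu0_Hz) / mean(rates),
               err_fullfp = abs(mean(rates) - rf$nu_Hz) / mean(rates))
  })
  do.call(rbind, rows)
}
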