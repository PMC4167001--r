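test_that("white-noise EIF rate matches brute-force quadrature of the
           double integral", {
  fs <- cell_fixtures()$FS
  fs$b <- 0
  d <- drive_spec(rheobase(fs), 150)
  td <- convert_drive(d, fs)
  sig2 <- td$sigma^2 / 2              # effective squared amplitude
  mu <- td$mu
  G <- function(x) -(x - fs$E_L)^2 / 2 +
    fs$Delta_T^2 * exp((x - fs$V_T) / fs$Delta_T) + mu * (x - fs$E_L)
  inner <- function(V) stats::integrate(function(u)
    exp(-(2 / sig2) * (G(u) - G(V))), max(V, fs$V_r), fs$V_up,
    rel.tol = 1e-10)$value
  Vlb <- min(fs$V_r, fs$E_L + mu) - 10 * td$sigma
  I <- stats::integrate(Vectorize(inner), Vlb, fs$V_up,
                        rel.tol = 1e-9)$value
  nu_bf <- 1000 / (2 * membrane_time_constant(fs) / sig2 * I)
  expect_equal(eif_rate_white(td, fs), nu_bf, tolerance = 5e-4)
})

test_that("deeply subthreshold drive yields a vanishing rate", {
  fs <- cell_fixtures()$FS
  td <- convert_drive(drive_spec(rheobase(fs), 150), fs)
  td$mu <- rheobase(fs) / fs$g_L - 20 * td$sigma
  expect_lt(eif_rate_white(td, fs), 1e-6)
})

test_that("rate agrees with the LIF first-passage (Siegert) formula in the
           vanishing-Delta_T limit", {
  fs <- cell_fixtures()$FS
  p <- fs
  p$b <- 0
  p$Delta_T <- 0.01
  p$V_up <- p$V_T                      # hard threshold
  sigI_C <- 120 / p$C                 # current amplitude / C, mV/sqrt(ms)
  tau_m <- membrane_time_constant(p)
  V0 <- p$E_L + 8                      # resting + drive, below threshold
  s_inf <- sigI_C * sqrt(tau_m / 2)    # stationary OU voltage SD
  siegert_T <- tau_m * sqrt(pi) * stats::integrate(function(x)
    exp(x^2) * (1 + pracma::erf(x)),
    (p$V_r - V0) / (sqrt(2) * s_inf),
    (p$V_T - V0) / (sqrt(2) * s_inf), rel.tol = 1e-10)$value
  td <- convert_drive(drive_spec((V0 - p$E_L) * p$g_L, 120), p)
  expect_equal(eif_rate_white(td, p, n_grid = 32768), 1000 / siegert_T,
               tolerance = 0.02)
})

test_that("self-consistent adapted rate solves its fixed point and reduces
           to the white rate for b = 0", {
  cells <- cell_fixtures()
  for (p in cells) {
    td <- convert_drive(drive_spec(rheobase(p), 150), p)
    p0 <- p
    p0$b <- 0
    expect_equal(nu0_selfconsistent(td, p0)$nu_Hz, eif_rate_white(td, p0))
    r <- nu0_selfconsistent(td, p)
    expect_true(r$converged)
    expect_lt(r$diagnostics$residual_ms, 1e-6)
    # residual against an independent re-evaluation
    phi <- eif_rate_white(td, p, w_bar = p$b * r$nu_Hz / 1000 * p$tau_w)
    expect_equal(r$nu_Hz, phi, tolerance = 1e-6)
  }
})

test_that("the adapted rate is monotone in drive, noise and adaptation
           strength", {
  fs <- cell_fixtures()$FS
  r0 <- rheobase(fs) / fs$g_L
  base <- convert_drive(drive_spec(rheobase(fs), 150), fs)
  mus <- r0 + seq(-4, 2, length.out = 4)
  sigs <- base$sigma * c(0.7, 0.9, 1.1, 1.3)
  rates <- outer(mus, sigs, Vectorize(function(m, s) {
    td <- structure(list(mu = m, sigma = s), class = "theory_drive")
    nu0_selfconsistent(td, fs)$nu_Hz
  }))
  expect_true(all(diff(rates) > 0))                # increasing in mu
  sub <- mus < r0
  expect_true(all(t(diff(t(rates[sub, ]))) > 0))   # increasing in sigma below rheobase
  bs <- c(0, 20, 60, 120)
  rb <- vapply(bs, function(bv) {
    p <- fs
    p$b <- bv
    nu0_selfconsistent(base, p)$nu_Hz
  }, numeric(1))
  expect_true(all(diff(rb) < 0))                   # non-increasing in b
})

test_that("rate is insensitive to grid refinement and to the detection
           threshold placement", {
  fs <- cell_fixtures()$FS
  td <- convert_drive(drive_spec(rheobase(fs), 150), fs)
  n1 <- nu0_selfconsistent(td, fs, n_grid = 8192)$nu_Hz
  n2 <- nu0_selfconsistent(td, fs, n_grid = 16384)$nu_Hz
  expect_lt(abs(n2 - n1) / n1, 1e-3)
  p2 <- fs
  p2$V_up <- fs$V_T + 20 * fs$Delta_T
  n3 <- nu0_selfconsistent(convert_drive(drive_spec(rheobase(fs), 150), p2),
                           p2)$nu_Hz
  expect_lt(abs(n3 - n1) / n1, 5e-3)
})

test_that("rate matches simulation without adaptation across fixtures and
           noise levels", {
  for (cn in c("L3", "L5", "FS", "BT")) {
    p <- cell_fixtures()[[cn]]
    p$b <- 0
    for (sg in c(100, 300)) {
      d <- drive_spec(rheobase(p), sg)
      # extrapolate the small linear-in-dt discretisation bias away
      s1 <- sim_rate(p, d, seeds = 100 + 1:4, dt = 0.01)
      s2 <- sim_rate(p, d, seeds = 120 + 1:4, dt = 0.02)
      est <- 2 * s1$mean - s2$mean
      se <- sqrt(4 * s1$se^2 + s2$se^2)
      th <- eif_rate_white(convert_drive(d, p), p)
      expect_lt(abs(th - est), 3 * se)
    }
  }
})

test_that("stationary density is normalised, vanishes at threshold, and
           matches the simulated voltage histogram", {
  fs <- cell_fixtures()$FS
  fs$b <- 0
  d <- drive_spec(rheobase(fs), 300)
  td <- convert_drive(d, fs)
  r <- nu0_selfconsistent(td, fs)
  sd0 <- stationary_density(td, fs, r$nu_Hz)
  expect_equal(sd0$Q0[length(sd0$Q0)], 0)
  expect_true(all(sd0$Q0 >= 0))
  expect_equal(aeifrate:::.trapz(sd0$V, sd0$Q0), 1000 / r$nu_Hz,
               tolerance = 1e-6)
  sim <- simulate_aeif(fs, d, duration = 50000, seed = 5,
                       record_trace = TRUE)
  V <- sim$trace$V[sim$trace$t > 5000]
  h <- hist(V, breaks = seq(min(V) - 1, max(V) + 1, by = 1), plot = FALSE)
  qi <- stats::approx(sd0$V, sd0$Q0 * sd0$nu0_ms, xout = h$mids)$y
  expect_lt(max(abs(h$density - qi), na.rm = TRUE), 0.05)
})

test_that("operator J reproduces nested quadrature and its defining
           identity for the stationary density", {
  fs <- cell_fixtures()$FS
  td <- convert_drive(drive_spec(rheobase(fs), 150), fs)
  r <- nu0_selfconsistent(td, fs)
  sd0 <- stationary_density(td, fs, r$nu_Hz)
  expect_equal(apply_J(rep(0, length(sd0$V)), sd0, fs),
               rep(0, length(sd0$V)))
  # Q0 is J applied to the reset indicator
  theta <- as.numeric(sd0$V >= fs$V_r)
  expect_equal(apply_J(theta, sd0, fs), sd0$Q0, tolerance = 1e-10)
  # direct nested quadrature at 5 interior grid points
  sig2 <- aeifrate:::.s2eff(td$sigma)
  G <- function(x) aeifrate:::.eif_F(x, fs, sd0$mu_eff)
  Qfun <- stats::approxfun(sd0$V, sd0$Q0)
  JQ <- apply_J(sd0$Q0, sd0, fs)
  quad <- function(f, lo, hi) {
    for (rt in c(1e-9, 1e-7)) {
      v <- tryCatch(stats::integrate(f, lo, hi, rel.tol = rt,
                                     subdivisions = 2000L)$value,
                    error = function(e) NULL)
      if (!is.null(v)) return(v)
    }
    stats::integrate(f, lo, hi, rel.tol = 1e-5, subdivisions = 2000L)$value
  }
  idx <- round(c(0.15, 0.3, 0.45, 0.6, 0.7) * length(sd0$V))
  for (i in idx) {
    Vi <- sd0$V[i]
    f_in <- function(u) exp(-(2 / sig2) * (G(u) - G(Vi))) * Qfun(u)
    # split at the reset kink of Q0 for the adaptive quadrature
    pieces <- sort(unique(c(Vi, if (fs$V_r > Vi) fs$V_r, fs$V_up)))
    bf <- 0
    for (k in seq_len(length(pieces) - 1))
      bf <- bf + quad(f_in, pieces[k], pieces[k + 1])
    bf <- 2 * sd0$tau_m / sig2 * bf
    expect_equal(JQ[i], bf, tolerance = 2e-4)
  }
})

test_that("operator K is the running integral with exact ramps", {
  fs <- cell_fixtures()$FS
  td <- convert_drive(drive_spec(rheobase(fs), 150), fs)
  r <- nu0_selfconsistent(td, fs)
  sd0 <- stationary_density(td, fs, r$nu_Hz)
  n <- length(sd0$V)
  expect_equal(apply_K(rep(0, n), sd0), rep(0, n))
  KQ <- apply_K(sd0$Q0, sd0)
  expect_equal(KQ[n], 1000 / r$nu_Hz, tolerance = 1e-6)
  # running integral of a function with a known antiderivative
  KV <- apply_K(sd0$V - sd0$V[1], sd0)
  expect_equal(KV, (sd0$V - sd0$V[1])^2 / 2, tolerance = 1e-9)
  # indicator over [x1, x2]: a linear ramp (with the trapezoid's
  # half-cell weight at each sampled edge)
  x1 <- sd0$V[100]
  x2 <- sd0$V[300]
  ind <- as.numeric(sd0$V >= x1 & sd0$V <= x2)
  Ki <- apply_K(ind, sd0)
  e1 <- (sd0$V[100] - sd0$V[99]) / 2
  e2 <- (sd0$V[301] - sd0$V[300]) / 2
  expect_equal(Ki[n], (x2 - x1) + e1 + e2, tolerance = 1e-9)
  expect_equal(Ki[200], (sd0$V[200] - x1) + e1, tolerance = 1e-9)
  expect_equal(Ki[50], 0)
})
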