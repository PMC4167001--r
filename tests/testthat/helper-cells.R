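# Canonical cell parameters (grand means for the four cortical cell types),
# built in code so tests do not depend on the packaged CSV they also verify.
cell_fixtures <- function() {
  list(
    L3 = neuron_params(C = 125.3, g_L = 6.0, E_L = -74.6, Delta_T = 3.5,
                       V_T = -57.7, V_r = -96.0, tau_w = 229.8, b = 37.9,
                       cell = "L3"),
    L5 = neuron_params(C = 246.2, g_L = 6.9, E_L = -71.7, Delta_T = 3.0,
                       V_T = -60.1, V_r = -76.4, tau_w = 263.7, b = 25.1,
                       cell = "L5"),
    FS = neuron_params(C = 48.4, g_L = 4.3, E_L = -75.5, Delta_T = 3.1,
                       V_T = -64.1, V_r = -98.5, tau_w = 25.4, b = 66.5,
                       cell = "FS"),
    BT = neuron_params(C = 80.5, g_L = 4.3, E_L = -79.2, Delta_T = 2.7,
                       V_T = -71.9, V_r = -95.6, tau_w = 74.3, b = 30.3,
                       cell = "BT"))
}

# Mean simulated steady-state rate and its standard error over seeds.
sim_rate <- function(p, d, seeds, duration = 50000, dt = 0.05,
                     discard = 5000) {
  r <- vapply(seeds, function(s)
    steady_state_rate(simulate_aeif(p, d, dt = dt, duration = duration,
                                    discard = discard, seed = s)),
    numeric(1))
  list(mean = mean(r), se = stats::sd(r) / sqrt(length(r)))
}

# Shared cache for expensive fixtures reused across test files.
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}
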