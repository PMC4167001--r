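---
title: "Steady-state firing-rate theory for adaptive EIF neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state firing-rate theory for adaptive EIF neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeifrate)
```

## The model

The package works with the exponential integrate-and-fire neuron with
spike-triggered adaptation (aEIF with no subthreshold adaptation):

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V-V_T)/\Delta_T} + I(t) - w,
\qquad \tau_w\,\dot w = -w,$$

with the reset rule $V \to V_r$, $w \to w + b$ whenever $V$ reaches the
detection threshold $V_\mathrm{up}$.  The synaptic input is the diffusion
approximation of massed synaptic bombardment,
$I(t) = \mu_{I} + \sigma_{I}\,\xi(t)$, where $\xi$ is Gaussian white noise
that is delta-correlated with time measured in milliseconds
($\langle\xi(t)\xi(t')\rangle = \delta(t-t')\,\mathrm{ms}^{-1}$), or an
Ornstein–Uhlenbeck current with correlation time $\tau_s$ when synaptic
filtering matters.  Internal units are mV, ms, pA, nS and pF throughout;
rates are carried in ms$^{-1}$ internally and reported in Hz.

Four canonical neocortical parameter sets (layer-3 and layer-5 pyramidal
cells, fast-spiking and bitufted interneurons; grand means of fits to
rodent prefrontal-cortex recordings) ship with the package:

```{r}
canonical_cells("FS")
```

## Noise conventions

Two equivalent noise parameterisations appear in this field and mixing
them up silently rescales every prediction, so the package fixes them
explicitly:

* the *drive scale* $\sigma = (\sigma_I / C)\sqrt{2\tau_m}$ (mV) reported
  by `convert_drive()` is normalised so that a leak-dominated membrane has
  a stationary voltage SD of exactly $\sigma/2$;
* the diffusion coefficient of the voltage equation for the unit-variance
  white-noise source above is $\sigma^2/4$, so every Fokker–Planck
  integral carries the effective squared amplitude
  $\sigma_\mathrm{eff}^2 = \sigma^2/2$.

This pairing is a calibration, not a convention choice: it is the unique
combination under which the analytical rate and the Euler–Maruyama
simulator agree in the time-step limit (the test suite checks agreement to
Monte-Carlo precision at $b = 0$), and under which the hard-threshold
limit of the rate reproduces the classical LIF first-passage formula.

## The three rate approximations

**EIF-⟨w⟩ (`nu0_selfconsistent`).**  The adaptation current is replaced
by its stationary mean $\langle w\rangle = b\nu\tau_w$, which simply
shifts the mean drive of the white-noise EIF rate
$\nu_\mathrm{EIF}(\mu, \sigma)$; the resulting scalar fixed point
$\nu = \Phi(\nu)$ has a unique root because $\Phi$ is non-increasing, and
is solved by bracketed root finding to $10^{-12}$ ms$^{-1}$.  The kernel
$\nu_\mathrm{EIF}$ itself is the inverse of a double integral over an
exponentiated potential; it is evaluated on a voltage grid with a
recurrence that exponentiates only *local* potential differences, so no
intermediate overflows regardless of how steep the exponential
nonlinearity is.  Rates below $10^{-8}$ ms$^{-1}$ are clamped to zero.

**Full Fokker–Planck (`nu_fullfp`).**  Treating
$\varepsilon = \tau_m/\tau_w$ as a small parameter, the joint $(V, w)$
density is expanded around the product state
$Q_0(V)\,R_0(z)$, where $z$ is the scaled fluctuation of $w$ around its
mean and $R_0$ is Gaussian.  Odd orders vanish by symmetry, and the first
correction to the rate is
$\nu = \nu_0 + \varepsilon^2 \nu_2$, with $\nu_2$ assembled from
compositions of two integral operators applied to the stationary density
$Q_0$: $J$ (a backward exponentially weighted integral up to
$V_\mathrm{up}$) and $K$ (a running integral from below), evaluated at the
detection threshold.  The calculation is carried out in nondimensional
form — rates as spikes per membrane time constant, the adaptation
increment as the equivalent voltage $b\tau_w/(g_L\tau_m)$ — so that the
product of the two is the mean adaptation potential in mV.

Two properties of this correction deserve emphasis.  First, the operator
compositions are computed by repeated $O(n)$ grid passes, never by
nested quadrature (nested quadrature appears only as a test oracle).
Second, the correction must be read as an *effective
finite-$\varepsilon$ approximant* rather than an exact Taylor
coefficient.  High-precision simulation (common random numbers, an
$\varepsilon = 0.02$ reference run; difference SE $\sim 0.01$ Hz) shows
that at fixed $\langle w\rangle$ (scaling $b \propto 1/\tau_w$) the
deviation of the simulated rate from $\nu_0$ is in fact *linear* in
$\varepsilon$ over the whole range $\varepsilon \in [0.02, 0.45]$.  This
is no accident: the stationary adaptation variance of the model scales
as $\varepsilon^1$ (the filtered-point-process moments say so, and
simulation confirms it), so the leading fluctuation correction to the
rate is first order in $\varepsilon$ — the expansion's bookkeeping,
which assigns the first correction to order $\varepsilon^2$, absorbs
what is really an $O(\varepsilon)$ effect into an effective quadratic
term.  The implemented form is therefore validated directly at finite
$\varepsilon$: on the fixed-$\langle w\rangle$ protocol its prediction
stays within 5% of simulation up to $\varepsilon \approx 0.45$ (checked
in the test suite).  Beyond $\varepsilon \approx 0.5$, and for
near-threshold low-noise drives, `nu_eif_fw()` should be preferred.

**EIF-F(w) (`nu_eif_fw`).**  Instead of a perturbation series, the EIF
rate is averaged over a model of the stationary adaptation-current
distribution $F(w)$:
$$\nu_\mathrm{aEIF} = \int F(w)\, \nu_\mathrm{EIF}(\mu - w/g_L, \sigma)\,dw.$$
$F(w)$ is a Gamma density parameterised by the first two moments of the
exponentially filtered spike train — mean $b\nu\tau_w$ and a variance
built from the Laplace transform $\beta_1$ of the interspike-interval
density at $1/\tau_w$, with the ISIs modeled as Gamma from their
first-passage mean and variance — truncated to the band
$[w_\mathrm{min}, w_\mathrm{max}]$ that a perfectly periodic train at the
same rate would occupy ($w_\mathrm{max} - w_\mathrm{min} = b$ exactly).
The whole construction is again a fixed point in the rate; it is solved by
damped iteration (damping 0.5, tolerance $10^{-6}$ ms$^{-1}$) with the
integral over $w$ computed by 64-node Gauss–Legendre quadrature on the
truncation band (doubling the order moves rates by under 0.05%).

The ISI variance is obtained by quadrature of the first-passage moment
hierarchy $\tfrac{\sigma^2_\mathrm{eff}}{2} T_k'' + f\,T_k' =
-k\,\tau_m T_{k-1}$ with a reflecting lower and absorbing upper boundary —
two additional cumulative passes over the same grid — rather than from a
literal triple-nested integral; the two are mathematically identical and
the implementation is validated against simulated interval statistics.

Degenerate regimes are handled explicitly: at $b = 0$ every method
reduces exactly to the white-noise EIF rate; near-periodic trains can
drive the filtered-train variance formula non-positive, in which case the
uniform-density variance $b^2/12$ on the truncation band is substituted
(and flagged); numerically mass-less truncation windows renormalise the
log-density on the window.

## Colored (synaptically filtered) noise

An OU input with correlation time $\tau_s$ is handled two ways:

* **Variance reduction** (`nu_colored_reduced`): replace
  $\sigma \to \sigma/\sqrt{1 + \tau_s/\tau_m}$ — exact for the leaky
  integrator's voltage variance — and reuse any white-noise method.
* **Second-order correction** (`nu_colored_secondorder`): the
  $k^2 = \tau_s/\tau_m$ correction $\nu_2^{CN}$, a double grid integral
  over the stationary density and the drift derivative, averaged over the
  adaptation distribution.

The $k^2$ slope of the correction is validated directly against OU
simulations.  Our measurements show the two routes agree within 5% only
for $\tau_s \lesssim 0.05\,\tau_m$ at sub-rheobase drives and diverge at
larger $\tau_s$ (the variance-reduction route under-corrects); the
$k$-expansion in turn overshoots once $k^2 \gtrsim 0.5$.  Both are
therefore exposed, with the expansion restricted to $\tau_s \le \tau_m$
(beyond that the reduction route is used with a warning).

## The simulator as ground truth

`simulate_aeif()` integrates the model by Euler–Maruyama at
`dt = 0.05` ms (default), detecting spikes on upward crossings of
$V_\mathrm{up}$ within a step and recording the reset value; the OU input
is advanced by its exact discrete-time solution so its statistics are
correct for any `dt`$/\tau_s$.  Defaults follow the validation protocol:
50 s runs (100 s for the heavier sweeps), first 5 s discarded, initial
conditions $V(0) = E_L$, $w(0) = 0$.  At `dt = 0.05` ms the simulated
rates carry a small systematic discretisation deficit (about 2–3% at high
noise); tests that probe *theory* rather than the *protocol* therefore
refine `dt` to 0.01 ms, and the small-$\varepsilon$ scaling test
subtracts a reference run at $\varepsilon = 0.02$ so the common offset
cancels.

What the simulator emulates — and what it does not: stationary Gaussian
(white or OU) current drive into a point neuron.  Conductance-based
synapses, parameter heterogeneity across a cell population, and
network feedback are outside its scope, so passing validation here
demonstrates the fidelity of the rate approximations to the model, not
the fidelity of the model to any particular recording.

## Validation harness and measured envelope

`fi_curve()` sweeps drive grids (rheobase-relative by default) across
cells, noise amplitudes and adaptation strengths, averages simulation
replicates, and reports the relative-error metric `err_rel()` (mean of
$|\nu_\mathrm{sim}-\nu_\mathrm{model}|/\nu_\mathrm{sim}$ over conditions
with $\nu_\mathrm{sim} > 0$).  `sigma_v_table()` reproduces the
subthreshold voltage-SD protocol (±10 ms spike excision), and
`epsilon_sweep()` the fixed-$\langle w\rangle$ expansion-accuracy
protocol.

On the canonical four cells with $\mu$ at the rheobase,
$b \in \{15, 50, 80\}$ pA and $\sigma_I \in \{100, 300, 600\}$
pA√ms (100 s simulations), the measured worst-case sigma-averaged
relative errors are about 10% for EIF-F(w) and 17–24% for the full-FP
correction, the latter dominated by near-rheobase, low-noise conditions
with sub-Hz rates where the required correction approaches the size of
$\nu_0$ itself — well outside any truncated expansion.  The EIF-⟨w⟩
approximation is markedly worse at large $b$ and small $\sigma$, and its
error grows monotonically with $b$; all methods improve as the input
variance grows.

## Numerical choices

* Voltage grid: 8192 near-uniform points on
  $[\min(V_r, E_L + \mu_\mathrm{eff}) - 10\sigma,\; V_\mathrm{up}]$,
  always containing $V_r$ and $V_T$ exactly; doubling the grid moves
  rates by $<0.1$% and the operator compositions by $<0.5$%.
* $V_\mathrm{up} = V_T + 10\,\Delta_T$ by default; doubling the offset
  moves rates by $<0.5$%, so the arbitrary detection threshold is
  immaterial.
* All exponentials enter through local-difference recurrences (the
  `ew_cumint` kernel), saturated at $10^{300}$; a saturated integral can
  only produce a rate that is clamped to zero.
* Reset discontinuities are discretised with the same one-sided indicator
  in the rate normalisation and in the stationary density, making the
  normalisation identity $\int Q_0\,dV = 1/\nu_0$ hold to rounding error
  rather than to quadrature error.

## Known limitations

* The full-FP correction is unreliable for $\varepsilon \gtrsim 0.5$ and
  for near-threshold low-noise drives (see the measured envelope above);
  EIF-F(w) is the robust default.
* The truncated-Gamma adaptation model discards density below
  $w_\mathrm{min}$; at very low rates (mean ISI $\gg \tau_w$) this
  truncation removes genuinely occupied states near $w = 0$ and the
  averaged rate under-predicts.
* The Gamma-ISI (renewal) assumption ignores the negative serial ISI
  correlations induced by adaptation; for slow adaptation
  ($\tau_w \gg$ ISI) the renewal filtered-train variance overestimates
  the simulated adaptation variance by tens of percent, though at the
  canonical cells' own time constants the error is a few percent.
* Subthreshold adaptation ($a \neq 0$), conductance synapses,
  time-dependent inputs and network self-consistency are out of scope.
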