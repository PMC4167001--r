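#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cumulative exponentially weighted integrals
//   forward : h_i = int_{x_1}^{x_i}  exp(psi(y) - psi_i) g(y) dy
//   backward: h_i = int_{x_i}^{x_n}  exp(psi(y) - psi_i) g(y) dy
// evaluated by a trapezoid recurrence in which only *local* differences of
// psi are exponentiated, so the result is immune to the enormous global
// range of psi.  Values are saturated at 1e300: a saturated integral only
// ever feeds a reciprocal that is clamped to a zero rate downstream.
// [[Rcpp::export]]
NumericVector ew_cumint(NumericVector psi, NumericVector g,
                        NumericVector x, bool forward) {
  const int n = psi.size();
  const double CAP = 1e300;
  NumericVector h(n);
  if (forward) {
    h[0] = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const double dx2 = 0.5 * (x[i + 1] - x[i]);
      const double r = std::exp(psi[i] - psi[i + 1]);
      double v = r * (h[i] + dx2 * g[i]) + dx2 * g[i + 1];
      if (v > CAP) v = CAP;
      h[i + 1] = v;
    }
  } else {
    h[n - 1] = 0.0;
    for (int i = n - 2; i >= 0; --i) {
      const double dx2 = 0.5 * (x[i + 1] - x[i]);
      const double r = std::exp(psi[i + 1] - psi[i]);
      double v = r * (h[i + 1] + dx2 * g[i + 1]) + dx2 * g[i];
      if (v > CAP) v = CAP;
      h[i] = v;
    }
  }
  return h;
}

// Euler-Maruyama integration of the aEIF equations with white or
// Ornstein-Uhlenbeck current noise.  Time unit ms, voltage mV, current pA.
// White noise (tau_s = 0): V gets sigma/C * sqrt(dt) * N(0,1) per step
// (delta-correlated current noise with time measured in ms).
// Colored noise (tau_s > 0): an OU current x with stationary variance
// sigma^2 / (2 tau_s) is advanced by its exact discrete-time solution and
// injected as a current; its zero-correlation-time limit recovers the
// white-noise convention above.
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List simulate_aeif_cpp(double C, double gL, double EL, double DeltaT,
                       double VT, double Vr, double Vup,
                       double tau_w, double b,
                       double mu, double sigma, double tau_s,
                       double dt, double duration,
                       bool record, double V0, double w0) {
  const long n = (long)std::floor(duration / dt + 0.5);
  std::vector<double> spikes;
  spikes.reserve(4096);
  NumericVector Vtr, wtr, Itr;
  if (record) {
    Vtr = NumericVector(n);
    wtr = NumericVector(n);
    if (tau_s > 0) Itr = NumericVector(n);
  }
  double V = V0, w = w0, x = 0.0;
  const bool colored = tau_s > 0.0;
  double ed = 0.0, sd_in = 0.0, sw = 0.0;
  if (colored) {
    ed = std::exp(-dt / tau_s);
    sd_in = std::sqrt(sigma * sigma / (2.0 * tau_s) * (1.0 - ed * ed));
  } else {
    sw = sigma / C * std::sqrt(dt);
  }
  const double invC = 1.0 / C;
  for (long i = 0; i < n; ++i) {
    double arg = (V - VT) / DeltaT;
    if (arg > 30.0) arg = 30.0;           // one clamped step still overshoots Vup
    const double drift = (-gL * (V - EL) + gL * DeltaT * std::exp(arg)
                          + mu + (colored ? x : 0.0) - w) * invC;
    double Vn;
    if (colored) {
      Vn = V + dt * drift;
      x = x * ed + sd_in * norm_rand();
    } else {
      Vn = V + dt * drift + sw * norm_rand();
    }
    w += -dt * w / tau_w;
    if (Vn >= Vup || !std::isfinite(Vn)) {
      spikes.push_back((i + 1) * dt);
      Vn = Vr;
      w += b;
    }
    V = Vn;
    if (record) {
      Vtr[i] = V;
      wtr[i] = w;
      if (colored) Itr[i] = mu + x;
    }
  }
  List out = List::create(_["spikes"] = wrap(spikes));
  if (record) {
    out["V"] = Vtr;
    out["w"] = wtr;
    if (colored) out["I"] = Itr;
  }
  return out;
}
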