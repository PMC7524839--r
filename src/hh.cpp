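#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment Hodgkin-Huxley membrane driven by an injected-current
// series and/or an excitatory synaptic conductance series, both given per
// 0.1 ms step (10 kHz). Classic squid-axon kinetics; the membrane area is
// chosen by the caller through the current/conductance -> density scaling
// factors. Integration is RK4 with `substeps` sub-intervals per input step,
// holding the inputs piecewise constant within a step.

static inline double am(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bm(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double ah(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double bh(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double an(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bn(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

struct HHState { double v, m, h, n; };

static inline HHState hh_deriv(const HHState& s, double i_dens, double g_dens) {
  const double gna = 120.0, gk = 36.0, gl = 0.3;
  const double ena = 50.0, ek = -77.0, el = -54.387, esyn = 0.0, cm = 1.0;
  HHState d;
  double ina = gna * s.m * s.m * s.m * s.h * (s.v - ena);
  double ik = gk * s.n * s.n * s.n * s.n * (s.v - ek);
  double il = gl * (s.v - el);
  double isyn = g_dens * (s.v - esyn);
  d.v = (i_dens - ina - ik - il - isyn) / cm;
  d.m = am(s.v) * (1.0 - s.m) - bm(s.v) * s.m;
  d.h = ah(s.v) * (1.0 - s.h) - bh(s.v) * s.h;
  d.n = an(s.v) * (1.0 - s.n) - bn(s.v) * s.n;
  return d;
}

// [[Rcpp::export(name = ".hh_sim_cpp")]]
NumericVector hh_sim_cpp(NumericVector i_dens, NumericVector g_dens,
                         double dt_ms = 0.1, int substeps = 10) {
  int n = i_dens.size();
  if (g_dens.size() != n) stop("current and conductance series differ in length");
  NumericVector vm(n);
  // start at rest for zero input
  HHState s;
  s.v = -65.0;
  s.m = am(s.v) / (am(s.v) + bm(s.v));
  s.h = ah(s.v) / (ah(s.v) + bh(s.v));
  s.n = an(s.v) / (an(s.v) + bn(s.v));
  double h = dt_ms / substeps;
  for (int t = 0; t < n; ++t) {
    double id = i_dens[t], gd = g_dens[t];
    for (int k = 0; k < substeps; ++k) {
      HHState k1 = hh_deriv(s, id, gd);
      HHState s2 = {s.v + 0.5 * h * k1.v, s.m + 0.5 * h * k1.m,
                    s.h + 0.5 * h * k1.h, s.n + 0.5 * h * k1.n};
      HHState k2 = hh_deriv(s2, id, gd);
      HHState s3 = {s.v + 0.5 * h * k2.v, s.m + 0.5 * h * k2.m,
                    s.h + 0.5 * h * k2.h, s.n + 0.5 * h * k2.n};
      HHState k3 = hh_deriv(s3, id, gd);
      HHState s4 = {s.v + h * k3.v, s.m + h * k3.m,
                    s.h + h * k3.h, s.n + h * k3.n};
      HHState k4 = hh_deriv(s4, id, gd);
      s.v += h / 6.0 * (k1.v + 2 * k2.v + 2 * k3.v + k4.v);
      s.m += h / 6.0 * (k1.m + 2 * k2.m + 2 * k3.m + k4.m);
      s.h += h / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
      s.n += h / 6.0 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
    }
    vm[t] = s.v;
  }
  return vm;
}
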