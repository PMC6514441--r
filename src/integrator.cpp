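#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column layout of the channel parameter matrix assembled by tspn_compile_channels():
//  0 g_max (nS)   1 e_rev (mV)   2 p (activation exponent)   3 q (inactivation exponent)
//  4 act_kind  (0 = none, 1 = voltage-gated, 2 = calcium-gated)
//  5 inact_kind(0 = none, 1 = voltage-gated)
//  6 is_ca_source (1 if this channel's current drives the calcium pool, i.e. CaL)
//  7..13  activation gate parameters
//  14..20 inactivation gate parameters
// Voltage gate parameters: vhalf, k, tau_min, tau_amp, tau_vhalf, tau_k1, tau_k2 with
//   x_inf(V)  = 1 / (1 + exp((vhalf - V)/k))          (k < 0 gives a falling curve)
//   tau_x(V)  = tau_min + tau_amp / (exp((V - tau_vhalf)/tau_k1) + exp(-(V - tau_vhalf)/tau_k2))
// Calcium gate parameters (first three slots): kd (uM), hill, tau (ms).

static inline double boltz(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp((vhalf - v) / k));
}

static inline double belltau(double v, double tmin, double tamp,
                             double tvh, double k1, double k2) {
  return tmin + tamp / (std::exp((v - tvh) / k1) + std::exp(-(v - tvh) / k2));
}

static inline double ca_gate_inf(double ca, double kd, double hill) {
  double a = std::pow(ca, hill);
  return a / (a + std::pow(kd, hill));
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericMatrix chan, double c_m,
                   double ca_lambda, double ca_alpha, double ca_k,
                   double v0, NumericMatrix gates0, double ca0,
                   NumericVector i_inj, NumericVector g_syn, double e_syn,
                   double dt, bool record_gates, bool record_ca) {
  const int nch = chan.nrow();
  const int n = i_inj.size();
  const bool has_syn = g_syn.size() > 0;

  NumericVector v_out(n);
  NumericVector ca_out(record_ca ? n : 0);
  NumericMatrix gates_out(record_gates ? n : 0, record_gates ? 2 * nch : 0);

  std::vector<double> m(nch), h(nch);
  for (int c = 0; c < nch; ++c) { m[c] = gates0(c, 0); h[c] = gates0(c, 1); }
  double v = v0, ca = ca0;

  int cal_idx = -1;
  for (int c = 0; c < nch; ++c) if (chan(c, 6) != 0.0) cal_idx = c;

  const double ca_decay = std::exp(-dt * ca_lambda * ca_k);

  for (int i = 0; i < n; ++i) {
    // 1. exact exponential update of every gating variable at the current voltage
    for (int c = 0; c < nch; ++c) {
      const int akind = (int)chan(c, 4);
      if (akind == 1) {
        double xinf = boltz(v, chan(c, 7), chan(c, 8));
        double tau  = belltau(v, chan(c, 9), chan(c, 10), chan(c, 11), chan(c, 12), chan(c, 13));
        m[c] = xinf + (m[c] - xinf) * std::exp(-dt / tau);
      } else if (akind == 2) {
        double xinf = ca_gate_inf(ca, chan(c, 7), chan(c, 8));
        double tau  = chan(c, 9);
        m[c] = xinf + (m[c] - xinf) * std::exp(-dt / tau);
      }
      if ((int)chan(c, 5) == 1) {
        double xinf = boltz(v, chan(c, 14), chan(c, 15));
        double tau  = belltau(v, chan(c, 16), chan(c, 17), chan(c, 18), chan(c, 19), chan(c, 20));
        h[c] = xinf + (h[c] - xinf) * std::exp(-dt / tau);
      }
    }

    // 2. exponential-Euler voltage update: decay at the total conductance,
    //    relax toward the conductance-weighted reversal (+ injected current)
    double g_tot = 0.0, g_e = 0.0;
    for (int c = 0; c < nch; ++c) {
      double g = chan(c, 0);
      if (g == 0.0) continue;
      const int p = (int)chan(c, 2), q = (int)chan(c, 3);
      if (p > 0) g *= ipow(m[c], p);
      if (q > 0) g *= ipow(h[c], q);
      g_tot += g;
      g_e += g * chan(c, 1);
    }
    if (has_syn && g_syn[i] > 0.0) {
      g_tot += g_syn[i];
      g_e += g_syn[i] * e_syn;
    }
    if (g_tot > 0.0) {
      double vss = (g_e + i_inj[i]) / g_tot;
      v = vss + (v - vss) * std::exp(-dt * g_tot / c_m);
    } else {
      v += dt * i_inj[i] / c_m;
    }

    // 3. calcium pool driven by the instantaneous CaL current
    if (cal_idx >= 0) {
      double gca = chan(cal_idx, 0);
      const int p = (int)chan(cal_idx, 2), q = (int)chan(cal_idx, 3);
      if (p > 0) gca *= ipow(m[cal_idx], p);
      if (q > 0) gca *= ipow(h[cal_idx], q);
      double i_cal = gca * (v - chan(cal_idx, 1));
      double cass = -ca_alpha * i_cal / ca_k;
      ca = cass + (ca - cass) * ca_decay;
      if (ca < 0.0) ca = 0.0;
    }

    if (!std::isfinite(v) || std::fabs(v) > 200.0)
      stop("integration diverged at step %d (t = %.3f ms, V = %g mV)", i + 1, (i + 1) * dt, v);

    v_out[i] = v;
    if (record_ca) ca_out[i] = ca;
    if (record_gates)
      for (int c = 0; c < nch; ++c) { gates_out(i, c) = m[c]; gates_out(i, nch + c) = h[c]; }
  }

  NumericMatrix gates_final(nch, 2);
  for (int c = 0; c < nch; ++c) { gates_final(c, 0) = m[c]; gates_final(c, 1) = h[c]; }

  return List::create(_["v"] = v_out, _["ca"] = ca, _["ca_trace"] = ca_out,
                      _["gates"] = gates_final, _["gates_trace"] = gates_out,
                      _["v_end"] = v);
}
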