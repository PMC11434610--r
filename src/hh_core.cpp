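// Fixed-step RK4 integrator for the modified Hodgkin-Huxley model with
// multiplicative conductance scaling. The derivative code here must stay in
// lock step with the R reference implementation in R/hh-model.R
// (hh_derivatives); the test suite cross-checks the two.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct HHPar {
  double C, gNa, gK, gL, vNa, vK, vL;
  int kexp;        // K gate exponent: 1 or 4
  bool leak_gated; // leak term gL*n*(v-vL) vs gL*(v-vL)
  int rateset;     // 0 = classic squid, 1 = traub (cortical pyramidal)
  double sK, sNa;  // conductance scale factors
};

// x / (1 - exp(-x/y)) with the removable singularity at x = 0
inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y + x / 2.0;
  return x / (1.0 - std::exp(-x / y));
}

inline void gate_rates(int rs, double v, double* am, double* bm, double* ah,
                       double* bh, double* an, double* bn) {
  if (rs == 0) { // classic squid axon, modern -65 mV resting convention
    *am = 0.1 * vtrap(v + 40.0, 10.0);
    *bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
    *ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
    *bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    *an = 0.01 * vtrap(v + 55.0, 10.0);
    *bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  } else {       // Traub-Miles cortical pyramidal cell
    *am = 0.32 * vtrap(v + 54.0, 4.0);
    *bm = 0.28 * vtrap(-(v + 27.0), 5.0);
    *ah = 0.128 * std::exp(-(v + 50.0) / 18.0);
    *bh = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
    *an = 0.032 * vtrap(v + 52.0, 5.0);
    *bn = 0.5 * std::exp(-(v + 57.0) / 40.0);
  }
}

// h relaxes toward this printed steady state (not toward alpha/(alpha+beta))
inline double h_inf(double v) { return 1.0 / (1.0 + std::exp((v + 60.0) / 6.2)); }

inline void derivs(const HHPar& p, double stim, const double* s, double* d) {
  const double v = s[0], m = s[1], h = s[2], n = s[3];
  double am, bm, ah, bh, an, bn;
  gate_rates(p.rateset, v, &am, &bm, &ah, &bh, &an, &bn);
  const double nk  = (p.kexp == 1) ? n : n * n * n * n;
  const double iNa = p.sNa * p.gNa * m * m * m * h * (v - p.vNa);
  const double iK  = p.sK * p.gK * nk * (v - p.vK);
  const double iL  = p.leak_gated ? p.gL * n * (v - p.vL) : p.gL * (v - p.vL);
  d[0] = (stim - iNa - iK - iL) / p.C;
  d[1] = am * (1.0 - m) - bm * m;
  d[2] = (h_inf(v) - h) * (ah + bh);
  d[3] = an * (1.0 - n) - bn * n;
}

} // namespace

// [[Rcpp::export(name = ".hh_gating_rates_cpp")]]
NumericVector hh_gating_rates_cpp(double v, int rateset) {
  double am, bm, ah, bh, an, bn;
  gate_rates(rateset, v, &am, &bm, &ah, &bh, &an, &bn);
  return NumericVector::create(_["alpha_m"] = am, _["beta_m"] = bm,
                               _["alpha_h"] = ah, _["beta_h"] = bh,
                               _["alpha_n"] = an, _["beta_n"] = bn);
}

// [[Rcpp::export(name = ".hh_simulate_cpp")]]
NumericMatrix hh_simulate_cpp(NumericVector state0, List pars,
                              NumericVector seg_start, NumericVector seg_dur,
                              NumericVector seg_amp, double T, double dt,
                              bool record_gating) {
  HHPar p;
  p.C = pars["C"]; p.gNa = pars["gNa_max"]; p.gK = pars["gK_max"];
  p.gL = pars["gL"]; p.vNa = pars["vNa"]; p.vK = pars["vK"]; p.vL = pars["vL"];
  p.kexp = pars["k_gate_exponent"]; p.leak_gated = pars["leak_gated"];
  p.rateset = pars["rateset"]; p.sK = pars["sK"]; p.sNa = pars["sNa"];

  const int nstep = (int)std::floor(T / dt + 0.5);
  const int ncol = record_gating ? 5 : 2;
  NumericMatrix out(nstep + 1, ncol);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  const int nseg = seg_start.size();

  auto stim_at = [&](double t) {
    double a = 0.0;
    for (int j = 0; j < nseg; ++j)
      if (t >= seg_start[j] && t < seg_start[j] + seg_dur[j]) a += seg_amp[j];
    return a;
  };

  for (int i = 0; i <= nstep; ++i) {
    const double t = i * dt;
    out(i, 0) = t; out(i, 1) = s[0];
    if (record_gating) { out(i, 2) = s[1]; out(i, 3) = s[2]; out(i, 4) = s[3]; }
    if (i == nstep) break;

    const double sa = stim_at(t), sb = stim_at(t + dt / 2), sc = stim_at(t + dt);
    derivs(p, sa, s, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt / 2 * k1[j];
    derivs(p, sb, tmp, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt / 2 * k2[j];
    derivs(p, sb, tmp, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt * k3[j];
    derivs(p, sc, tmp, k4);
    for (int j = 0; j < 4; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    // RK4 can overshoot [0,1] by O(dt^5); clamp to preserve the invariant
    for (int j = 1; j < 4; ++j) {
      if (s[j] < 0.0) s[j] = 0.0;
      if (s[j] > 1.0) s[j] = 1.0;
    }
    if (!std::isfinite(s[0]))
      stop("integration diverged (non-finite membrane potential) at t = %f ms",
           t + dt);
  }
  return out;
}
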