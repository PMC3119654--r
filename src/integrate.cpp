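// Fixed-step RK4 core for the coupled membrane-potential / cytosolic-pH
// model.  Deterministic (no adaptive stepping), with per-pathway
// cumulative H+ budgets integrated alongside the state so that the
// conservation audit closes to integrator accuracy.
//
// State vector: v (mV), p (gate open probability), pH_i,
//               cum_chan, cum_bg, cum_calc, cum_sec (mol H+; positive =
//               acid removed from the cytosol).
#include <Rcpp.h>
using namespace Rcpp;

static const double FARADAY = 96485.33212;

struct ModelPars {
  double slope_mv;     // Nernst slope, mV per pH unit
  double ph_o;
  double delta;        // activation midpoint offset above E_H (mV)
  double k;            // Boltzmann slope (mV)
  double tau_act_s, tau_deact_s;
  double g_gated;      // effective gated conductance, nS (after Zn/Gd)
  int    ghk_gated;    // if 1, g_gated is a permeability in pL/s
  double p_bg;         // background H+ permeability, pL/s (GHK flux)
  double g_cl, e_cl, v_half_cl, k_cl;
  double g_leak, e_leak;
  double c_m;          // pF
  double v_cyt;        // L
  double beta;         // mol L^-1 pH^-1
  double j_calc;       // mol H+ s^-1 (calcification + any pulse load)
  double k_sec, ph_set;
};

// F * u * (c_i - c_o e^{-u}) / (1 - e^{-u}) with c in mol/L; multiply by a
// permeability in pL/s to get a current in pA (outward positive).
static inline double ghk_h_factor(double v, double ph_i, double ph_o,
                                  double rtf_mv) {
  double u = v / rtf_mv;
  double ci = std::pow(10.0, -ph_i), co = std::pow(10.0, -ph_o);
  if (std::fabs(u) < 1e-6) return FARADAY * (ci - co);
  double em = std::exp(-u);
  return FARADAY * u * (ci - co * em) / (1.0 - em);
}

struct Currents { double gated, bg, cl, leak; };

static inline Currents currents(double v, double p, double ph,
                                const ModelPars& mp, double rtf_mv) {
  Currents c;
  double e_h = mp.slope_mv * (ph - mp.ph_o);
  if (mp.ghk_gated) {
    c.gated = mp.g_gated * p * ghk_h_factor(v, ph, mp.ph_o, rtf_mv);
  } else {
    c.gated = mp.g_gated * p * (v - e_h);
  }
  c.bg = mp.p_bg * ghk_h_factor(v, ph, mp.ph_o, rtf_mv);
  double sinf = 1.0 / (1.0 + std::exp((v - mp.v_half_cl) / mp.k_cl));
  c.cl = mp.g_cl * sinf * (v - mp.e_cl);
  c.leak = mp.g_leak * (v - mp.e_leak);
  return c;
}

static inline void deriv(const double* s, double* ds, const ModelPars& mp,
                         double rtf_mv, bool clamp) {
  double v = s[0], p = s[1], ph = s[2];
  Currents cc = currents(v, p, ph, mp, rtf_mv);
  double i_h = cc.gated + cc.bg;
  double e_h = mp.slope_mv * (ph - mp.ph_o);
  double pinf = 1.0 / (1.0 + std::exp(-(v - (e_h + mp.delta)) / mp.k));
  double tau = (pinf > p) ? mp.tau_act_s : mp.tau_deact_s;
  ds[0] = clamp ? 0.0 : -1000.0 * (i_h + cc.cl + cc.leak) / mp.c_m; // mV/s
  ds[1] = (pinf - p) / tau;
  double r_chan = cc.gated * 1e-12 / FARADAY;   // mol/s acid removed
  double r_bg   = cc.bg * 1e-12 / FARADAY;
  double r_calc = -mp.j_calc;
  double r_sec  = mp.k_sec * (mp.ph_set - ph) * mp.beta * mp.v_cyt;
  ds[2] = (r_chan + r_bg + r_calc + r_sec) / (mp.beta * mp.v_cyt);
  ds[3] = r_chan; ds[4] = r_bg; ds[5] = r_calc; ds[6] = r_sec;
}

static ModelPars unpack(const List& pars) {
  ModelPars mp;
  mp.slope_mv  = as<double>(pars["slope_mv"]);
  mp.ph_o      = as<double>(pars["ph_o"]);
  mp.delta     = as<double>(pars["delta_mv"]);
  mp.k         = as<double>(pars["slope_k_mv"]);
  mp.tau_act_s = as<double>(pars["tau_act_s"]);
  mp.tau_deact_s = as<double>(pars["tau_deact_s"]);
  mp.g_gated   = as<double>(pars["g_gated_ns"]);
  mp.ghk_gated = as<int>(pars["ghk_gated"]);
  mp.p_bg      = as<double>(pars["p_bg_pl_s"]);
  mp.g_cl      = as<double>(pars["g_cl_ns"]);
  mp.e_cl      = as<double>(pars["e_cl_mv"]);
  mp.v_half_cl = as<double>(pars["v_half_cl_mv"]);
  mp.k_cl      = as<double>(pars["k_cl_mv"]);
  mp.g_leak    = as<double>(pars["g_leak_ns"]);
  mp.e_leak    = as<double>(pars["e_leak_mv"]);
  mp.c_m       = as<double>(pars["c_m_pf"]);
  mp.v_cyt     = as<double>(pars["v_cyt_l"]);
  mp.beta      = as<double>(pars["beta"]);
  mp.j_calc    = as<double>(pars["j_calc_mol_s"]);
  mp.k_sec     = as<double>(pars["k_sec_per_s"]);
  mp.ph_set    = as<double>(pars["ph_set"]);
  return mp;
}

// [[Rcpp::export(name = ".rk4_segment")]]
NumericMatrix rk4_segment(NumericVector state0, List pars, double rtf_mv,
                          double t0, double dt, int n_steps, int save_every,
                          bool clamp, bool include_first) {
  if (state0.size() != 7) stop("state must have 7 elements");
  ModelPars mp = unpack(pars);
  double s[7], k1[7], k2[7], k3[7], k4[7], tmp[7];
  for (int i = 0; i < 7; ++i) s[i] = state0[i];

  int n_save = n_steps / save_every + (include_first ? 1 : 0);
  NumericMatrix out(n_save, 12);
  int row = 0;
  double t = t0;
  if (include_first) {
    Currents cc = currents(s[0], s[1], s[2], mp, rtf_mv);
    out(row, 0) = t; out(row, 1) = s[0]; out(row, 2) = s[1];
    out(row, 3) = s[2]; out(row, 4) = cc.gated; out(row, 5) = cc.bg;
    out(row, 6) = cc.cl; out(row, 7) = cc.leak;
    for (int i = 0; i < 4; ++i) out(row, 8 + i) = s[3 + i];
    row++;
  }
  for (int step = 1; step <= n_steps; ++step) {
    deriv(s, k1, mp, rtf_mv, clamp);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2, mp, rtf_mv, clamp);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3, mp, rtf_mv, clamp);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + dt * k3[i];
    deriv(tmp, k4, mp, rtf_mv, clamp);
    for (int i = 0; i < 7; ++i) {
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    // clip the gate to [0, 1] against roundoff drift
    if (s[1] < 0.0) s[1] = 0.0;
    if (s[1] > 1.0) s[1] = 1.0;
    t = t0 + step * dt;
    if (!R_finite(s[0]) || !R_finite(s[2])) {
      stop("integration diverged (non-finite state) at t = %f s", t);
    }
    if (step % save_every == 0) {
      Currents cc = currents(s[0], s[1], s[2], mp, rtf_mv);
      out(row, 0) = t; out(row, 1) = s[0]; out(row, 2) = s[1];
      out(row, 3) = s[2]; out(row, 4) = cc.gated; out(row, 5) = cc.bg;
      out(row, 6) = cc.cl; out(row, 7) = cc.leak;
      for (int i = 0; i < 4; ++i) out(row, 8 + i) = s[3 + i];
      row++;
    }
  }
  // final state as an attribute so segments can be chained exactly
  NumericVector fin(7);
  for (int i = 0; i < 7; ++i) fin[i] = s[i];
  out.attr("final_state") = fin;
  out.attr("final_time") = t;
  return out;
}
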