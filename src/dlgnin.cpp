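// Core numerics for the dLGN interneuron model: Hodgkin-Huxley style gating
// kinetics, Goldman-Hodgkin-Katz calcium flux, and a Crank-Nicolson
// integrator for the branched cable equation with a linear-time tree solve
// (Hines ordering: every parent precedes its children).
//
// Units: mV, ms, mM, S/cm^2 (GHK permeabilities cm/s), currents mA/cm^2,
// axial conductances S, injected currents nA, areas cm^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double FARADAY = 96485.309;  // C/mol
static const double RGAS = 8.3134;        // J/(mol K)

// x / (exp(x/y) - 1), stable near x = 0
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// z / (exp(z) - 1), stable near z = 0
static inline double efun(double z) {
  if (std::fabs(z) < 1e-5) return 1.0 - z / 2.0 + z * z / 12.0;
  return z / (std::exp(z) - 1.0);
}

// ---------------------------------------------------------------------------
// Rate functions. v2 = v - v_traub - sh for the Traub-lineage Na/K_dr rates.

struct GateVal { double inf, tau; };

static GateVal na_m(double v, double vtraub, double sh) {
  double v2 = v - vtraub - sh;
  double a = 0.32 * vtrap(13.0 - v2, 4.0);
  double b = 0.28 * vtrap(v2 - 40.0, 5.0);
  GateVal g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}
static GateVal na_h(double v, double vtraub, double sh) {
  double v2 = v - vtraub - sh;
  double a = 0.128 * std::exp((17.0 - v2) / 18.0);
  double b = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
  GateVal g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}
static GateVal kdr_n(double v, double vtraub, double sh) {
  double v2 = v - vtraub - sh;
  double a = 0.032 * vtrap(15.0 - v2, 4.0);
  double b = 0.5 * std::exp((10.0 - v2) / 40.0);
  GateVal g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}

// T-type calcium: m^2 h, low threshold. Activation rigidly shifted by
// `shift_act` (+8 mV in the model); time constants divided by the Q10
// factors (24 -> 36 C corrections) passed in as phi_*.
// Steady-state midpoints/slopes are passed in (interneuron voltage-clamp
// values; the +8 mV activation shift of the model is added to v50m).
static GateVal cat_m(double v, double shift_act, double v50m, double km,
                     double phi_m) {
  double x = v - shift_act;
  GateVal g;
  g.inf = 1.0 / (1.0 + std::exp(-(v - (v50m + shift_act)) / km));
  g.tau = (0.612 + 1.0 / (std::exp(-(x + 132.0) / 16.7) +
                          std::exp((x + 16.8) / 18.2))) / phi_m;
  return g;
}
static GateVal cat_h(double v, double v50h, double kh, double phi_h) {
  GateVal g;
  g.inf = 1.0 / (1.0 + std::exp((v - v50h) / kh));
  double t = (v < -80.0) ? std::exp((v + 467.0) / 66.6)
                         : 28.0 + std::exp(-(v + 22.0) / 10.5);
  g.tau = t / phi_h;
  return g;
}

// L-type calcium: m^2, high threshold, non-inactivating; +7 mV shift.
static GateVal cal_m(double v, double shift_act) {
  double x = v - shift_act;
  double a = 1.6 / (1.0 + std::exp(-0.072 * (x - 5.0)));
  double b = 0.02 * vtrap(x - 1.31, 5.36);
  GateVal g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}

// Ih: first-order gate, Boltzmann activation + bell-shaped tau.
static GateVal ih_m(double v, double shift, double stp,
                    double a1, double a2, double a3, double a4) {
  GateVal g;
  g.inf = 1.0 / (1.0 + std::exp((v - shift) / stp));
  g.tau = std::exp((v + a1) / a2) / (1.0 + std::exp((v + a3) / a4));
  return g;
}

// GHK driving flux for Ca2+ (z = 2): mA/cm^2 per (cm/s) permeability.
static inline double ghk(double v, double ci, double co, double tempK) {
  double z = 1e-3 * 2.0 * FARADAY * v / (RGAS * tempK);
  return 1e-3 * 2.0 * FARADAY * (ci * efun(-z) - co * efun(z));
}

// ---------------------------------------------------------------------------
// R-facing evaluators (share the definitions above with the solver)

// [[Rcpp::export]]
List cpp_gate_curves(std::string channel, std::string gate,
                     NumericVector v, double shift, bool temp_corrected,
                     NumericVector cat_par) {
  int n = v.size();
  NumericVector inf(n), tau(n);
  double phi_m = temp_corrected ? std::pow(3.0, 1.2) : 1.0;
  double phi_h = temp_corrected ? std::pow(1.5, 1.2) : 1.0;
  for (int i = 0; i < n; i++) {
    GateVal g;
    if (channel == "na" && gate == "m") g = na_m(v[i], -63.0, shift);
    else if (channel == "na" && gate == "h") g = na_h(v[i], -63.0, shift);
    else if (channel == "kdr" && gate == "n") g = kdr_n(v[i], -63.0, shift);
    else if (channel == "cat" && gate == "m")
      g = cat_m(v[i], 8.0 + shift, cat_par[0], cat_par[1], phi_m);
    else if (channel == "cat" && gate == "h")
      g = cat_h(v[i], cat_par[2], cat_par[3], phi_h);
    else if (channel == "cal" && gate == "m") g = cal_m(v[i], 7.0 + shift);
    else stop("unknown channel/gate: %s/%s", channel.c_str(), gate.c_str());
    inf[i] = g.inf; tau[i] = g.tau;
  }
  return List::create(_["inf"] = inf, _["tau"] = tau);
}

// [[Rcpp::export]]
NumericVector cpp_ghk(NumericVector v, double ci, double co, double tempK) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = ghk(v[i], ci, co, tempK);
  return out;
}

// ---------------------------------------------------------------------------
// Lookup tables over voltage for the integrator

// Interleaved layout: one contiguous block of TB_STRIDE doubles per voltage
// grid point, so a single lookup touches adjacent memory.
// Block layout: [inf0 fac0 inf1 fac1 ... inf6 fac6 gci gco dgci dgco]
// gate indices: 0 na_m 1 na_h 2 kdr_n 3 cat_m 4 cat_h 5 cal_m 6 ih_m
#define TB_STRIDE 18
#define TB_GCI 14
#define TB_GCO 15
#define TB_DGCI 16
#define TB_DGCO 17
struct Tables {
  double vmin, dv;
  int n;
  std::vector<double> blk;
};

static void build_tables(Tables &tb, double dt, double vtraub,
                         double sh_na, double sh_kdr,
                         double ih_shift, double ih_stp,
                         double a1, double a2, double a3, double a4,
                         double cat_v50m, double cat_km,
                         double cat_v50h, double cat_kh,
                         double cao, double tempK) {
  tb.vmin = -150.0; tb.dv = 0.05;
  tb.n = (int)std::floor((100.0 - tb.vmin) / tb.dv) + 1;
  double phi_m = std::pow(3.0, 1.2), phi_h = std::pow(1.5, 1.2);
  tb.blk.assign((size_t)tb.n * TB_STRIDE, 0.0);
  double K = 1e-3 * 2.0 * FARADAY;
  for (int i = 0; i < tb.n; i++) {
    double v = tb.vmin + i * tb.dv;
    GateVal g[7];
    g[0] = na_m(v, vtraub, sh_na);
    g[1] = na_h(v, vtraub, sh_na);
    g[2] = kdr_n(v, vtraub, sh_kdr);
    g[3] = cat_m(v, 8.0, cat_v50m, cat_km, phi_m);
    g[4] = cat_h(v, cat_v50h, cat_kh, phi_h);
    g[5] = cal_m(v, 7.0);
    g[6] = ih_m(v, ih_shift, ih_stp, a1, a2, a3, a4);
    double *b = &tb.blk[(size_t)i * TB_STRIDE];
    for (int k = 0; k < 7; k++) {
      b[2 * k] = g[k].inf;
      b[2 * k + 1] = 1.0 - std::exp(-dt / g[k].tau);
    }
    double z = 1e-3 * 2.0 * FARADAY * v / (RGAS * tempK);
    b[TB_GCI] = K * efun(-z);
    b[TB_GCO] = cao * K * efun(z);
  }
  for (int i = 0; i < tb.n; i++) {
    int i0 = std::max(0, i - 1), i1 = std::min(tb.n - 1, i + 1);
    double h = (i1 - i0) * tb.dv;
    double *b = &tb.blk[(size_t)i * TB_STRIDE];
    tb.blk[(size_t)i * TB_STRIDE + TB_DGCI] =
      (tb.blk[(size_t)i1 * TB_STRIDE + TB_GCI] -
       tb.blk[(size_t)i0 * TB_STRIDE + TB_GCI]) / h;
    tb.blk[(size_t)i * TB_STRIDE + TB_DGCO] =
      (tb.blk[(size_t)i1 * TB_STRIDE + TB_GCO] -
       tb.blk[(size_t)i0 * TB_STRIDE + TB_GCO]) / h;
    (void)b;
  }
}

// Returns pointers to the two bracketing table blocks and the interpolation
// weight.
static inline void tab_lookup(const Tables &tb, double v, double &w,
                              const double *&b0, const double *&b1) {
  double x = (v - tb.vmin) / tb.dv;
  if (x < 0) x = 0;
  if (x > tb.n - 1.001) x = tb.n - 1.001;
  int i0 = (int)x;
  w = x - i0;
  b0 = &tb.blk[(size_t)i0 * TB_STRIDE];
  b1 = b0 + TB_STRIDE;
}

// ---------------------------------------------------------------------------
// The integrator

// [[Rcpp::export]]
List cpp_integrate(List model, List stim, double dt, double t_stop,
                   List init, IntegerVector record, int stride) {
  IntegerVector parent = model["parent"];
  NumericVector area = model["area"];
  NumericVector ax_g = model["ax_g"];
  NumericVector gna = model["g_na"], gkdr = model["g_kdr"],
    pcat = model["p_cat"], pcal = model["p_cal"], gh = model["g_h"],
    gahp = model["g_ahp"], gcan = model["g_can"], gpas = model["g_pas"];
  double epas = as<double>(model["e_pas"]);
  double cm = as<double>(model["c_m"]);
  double ena = as<double>(model["e_na"]), ek = as<double>(model["e_k"]),
    eh = as<double>(model["e_h"]), ecan = as<double>(model["e_can"]);
  double vtraub = as<double>(model["v_traub"]);
  double sh_na = as<double>(model["sh_na"]), sh_kdr = as<double>(model["sh_kdr"]);
  List ihp = model["ih"];
  double cao = as<double>(model["ca_o"]);
  double tempK = as<double>(model["temp_k"]);
  List cap = model["calcium"];
  double ca_alpha = as<double>(cap["alpha"]);
  double ca_tau = as<double>(cap["tau_Ca"]);
  double ca_rest = as<double>(cap["Ca_rest"]);
  double ahp_half = as<double>(model["ahp_ca_half"]);
  double ahp_tau = as<double>(model["ahp_tau"]);
  double can_half = as<double>(model["can_ca_half"]);
  double can_tau = as<double>(model["can_tau"]);
  bool ahp_sq = as<double>(model["ahp_gate_exp"]) > 1.5;
  bool ahp_hill4 = as<double>(model["ahp_hill"]) > 3.0;
  double ahp_h2 = ahp_half * ahp_half;
  double ahp_h4 = ahp_h2 * ahp_h2;

  int N = area.size();
  double ceff = 1e-3 * cm;  // mA ms / (mV cm^2)

  Tables tb;
  build_tables(tb, dt, vtraub, sh_na, sh_kdr,
               as<double>(ihp["shift"]), as<double>(ihp["stp"]),
               as<double>(ihp["a1"]), as<double>(ihp["a2"]),
               as<double>(ihp["a3"]), as<double>(ihp["a4"]),
               as<double>(model["cat_v50m"]), as<double>(model["cat_km"]),
               as<double>(model["cat_v50h"]), as<double>(model["cat_kh"]),
               cao, tempK);
  double ahp_fac = 1.0 - std::exp(-dt / ahp_tau);
  double can_fac = 1.0 - std::exp(-dt / can_tau);
  double ca_dec = std::exp(-dt / ca_tau);

  // --- state ---
  std::vector<double> v(N), ca(N);
  std::vector<double> gate[9];  // 7 voltage gates + ahp_m + can_m
  for (int k = 0; k < 9; k++) gate[k].resize(N);
  if (init.size() > 0) {
    NumericVector v0 = init["v"], ca0 = init["ca"];
    NumericMatrix g0 = init["gates"];
    for (int i = 0; i < N; i++) { v[i] = v0[i]; ca[i] = ca0[i]; }
    for (int k = 0; k < 9; k++)
      for (int i = 0; i < N; i++) gate[k][i] = g0(i, k);
  } else {
    double vinit = as<double>(model["v_init"]);
    for (int i = 0; i < N; i++) { v[i] = vinit; ca[i] = ca_rest; }
    for (int i = 0; i < N; i++) {
      double w; const double *b0, *b1; tab_lookup(tb, v[i], w, b0, b1);
      for (int k = 0; k < 7; k++)
        gate[k][i] = b0[2 * k] * (1 - w) + b1[2 * k] * w;
      double c2 = ca[i] * ca[i];
      gate[7][i] = (as<double>(model["ahp_hill"]) > 3.0)
        ? (c2 * c2) / (c2 * c2 + std::pow(ahp_half, 4))
        : c2 / (c2 + ahp_half * ahp_half);
      gate[8][i] = c2 / (c2 + can_half * can_half);
    }
  }

  // --- stimuli ---
  NumericVector st_amp, st_on, st_off;
  IntegerVector st_seg;
  if (stim.containsElementNamed("steps")) {
    List steps = stim["steps"];
    st_seg = as<IntegerVector>(steps["seg"]);
    st_amp = as<NumericVector>(steps["amp"]);
    st_on = as<NumericVector>(steps["on"]);
    st_off = as<NumericVector>(steps["off"]);
  }
  bool vclamp = false; int vc_seg = 0;
  NumericVector vc_t, vc_v;
  if (stim.containsElementNamed("vclamp")) {
    List vc = stim["vclamp"];
    vclamp = true;
    vc_seg = as<int>(vc["seg"]);
    vc_t = as<NumericVector>(vc["t"]);   // level start times, ascending, [0] = 0
    vc_v = as<NumericVector>(vc["v"]);
  }
  int nsyn = 0;
  IntegerVector sy_seg;
  double sy_gmax = 0, sy_e = 0, sy_t1 = 1, sy_t2 = 2, sy_norm = 1;
  NumericVector ev_t; IntegerVector ev_syn;
  std::vector<double> synA, synB;
  if (stim.containsElementNamed("syn")) {
    List sy = stim["syn"];
    sy_seg = as<IntegerVector>(sy["seg"]);
    nsyn = sy_seg.size();
    sy_gmax = as<double>(sy["gmax"]);       // uS
    sy_e = as<double>(sy["e_rev"]);
    sy_t1 = as<double>(sy["tau_rise"]);
    sy_t2 = as<double>(sy["tau_decay"]);
    ev_t = as<NumericVector>(sy["ev_t"]);   // ascending
    ev_syn = as<IntegerVector>(sy["ev_syn"]);
    synA.assign(nsyn, 0.0); synB.assign(nsyn, 0.0);
    double tp = std::log(sy_t2 / sy_t1) * sy_t1 * sy_t2 / (sy_t2 - sy_t1);
    sy_norm = 1.0 / (std::exp(-tp / sy_t2) - std::exp(-tp / sy_t1));
  }
  double synfacA = std::exp(-dt / sy_t1);
  double synfacB = std::exp(-dt / sy_t2);

  int nstep = (int)std::llround(t_stop / dt);
  int nout = (nstep >= 1) ? ((nstep - 1) / stride + 2) : 1;
  int nrec = record.size();
  NumericVector t_out(nout);
  NumericMatrix v_out(nout, nrec), ca_out(nout, nrec);
  NumericVector iclamp_out(vclamp ? nout : 0);

  std::vector<double> diag(N), rhs(N), au(N), al(N), inj(N, 0.0),
    ica_seg(N, 0.0);
  // Staggered scheme: gating variables live half a step ahead of the
  // voltage. Advance them dt/2 from the (steady-state or chained) initial
  // values so that each voltage step [t, t+dt] sees gates at t + dt/2.
  for (int i = 0; i < N; i++) {
    double w; const double *b0, *b1; tab_lookup(tb, v[i], w, b0, b1);
    for (int k = 0; k < 7; k++) {
      double inf = b0[2 * k] * (1 - w) + b1[2 * k] * w;
      double fac = b0[2 * k + 1] * (1 - w) + b1[2 * k + 1] * w;
      double fac2 = 1.0 - std::sqrt(1.0 - fac);   // half-step factor
      gate[k][i] += (inf - gate[k][i]) * fac2;
    }
    double c2 = ca[i] * ca[i];
    double ahp_inf = ahp_hill4 ? (c2 * c2) / (c2 * c2 + ahp_h4)
                               : c2 / (c2 + ahp_h2);
    gate[7][i] += (ahp_inf - gate[7][i]) * (1.0 - std::sqrt(1.0 - ahp_fac));
    double can_inf = c2 / (c2 + can_half * can_half);
    gate[8][i] += (can_inf - gate[8][i]) * (1.0 - std::sqrt(1.0 - can_fac));
  }
  std::vector<double> gsyn_seg(N, 0.0);
  int ev_ptr = 0, out_row = 0, vc_ptr = 0;
  const double GCLAMP = 1e6;  // S/cm^2: effectively ideal somatic clamp
  double vc_level = vclamp ? vc_v[0] : 0.0;

  for (int step = 0; step <= nstep; step++) {
    double t = step * dt;

    // --- record state at time t ---
    if (step == nstep || step % stride == 0) {
      t_out[out_row] = t;
      for (int r = 0; r < nrec; r++) {
        v_out(out_row, r) = v[record[r]];
        ca_out(out_row, r) = ca[record[r]];
      }
      if (vclamp) {
        // clamp current = membrane current - axial inflow at the clamped
        // segment, nA, outward positive
        int i = vc_seg;
        double w; const double *b0, *b1; tab_lookup(tb, v[i], w, b0, b1);
        double m = gate[0][i], h = gate[1][i], n = gate[2][i];
        double mt = gate[3][i], ht = gate[4][i], ml = gate[5][i],
          mh = gate[6][i], ma = gate[7][i], mc = gate[8][i];
        double gci = b0[TB_GCI] * (1 - w) + b1[TB_GCI] * w;
        double gco = b0[TB_GCO] * (1 - w) + b1[TB_GCO] * w;
        double iion = gna[i] * m * m * m * h * (v[i] - ena)
          + gkdr[i] * n * n * n * n * (v[i] - ek)
          + gh[i] * mh * (v[i] - eh)
          + gahp[i] * (ahp_sq ? ma * ma : ma) * (v[i] - ek)
          + gcan[i] * mc * (v[i] - ecan)
          + (pcat[i] * mt * mt * ht + pcal[i] * ml * ml) * (ca[i] * gci - gco)
          + gpas[i] * (v[i] - epas);
        double ax = 0;
        if (parent[i] >= 0) ax += ax_g[i] * (v[parent[i]] - v[i]);
        for (int c = 0; c < N; c++)
          if (parent[c] == i) ax += ax_g[c] * (v[c] - v[i]);
        iclamp_out[out_row] = (iion * area[i] - ax) * 1e6;
      }
      out_row++;
    }
    if (step == nstep) break;

    // --- synaptic events with activation time <= t ---
    while (ev_ptr < ev_t.size() && ev_t[ev_ptr] <= t + 1e-9) {
      int s = ev_syn[ev_ptr];
      synA[s] += 1.0; synB[s] += 1.0;
      ev_ptr++;
    }

    // --- stimulus currents at time t ---
    std::fill(inj.begin(), inj.end(), 0.0);
    for (int s = 0; s < st_seg.size(); s++)
      if (t >= st_on[s] - 1e-9 && t < st_off[s] - 1e-9)
        inj[st_seg[s]] += st_amp[s] * 1e-6;  // nA -> mA
    if (nsyn) {
      std::fill(gsyn_seg.begin(), gsyn_seg.end(), 0.0);
      for (int s = 0; s < nsyn; s++) {
        double g = sy_gmax * sy_norm * (synB[s] - synA[s]); // uS
        if (g > 0) gsyn_seg[sy_seg[s]] += g * 1e-6;         // -> S
      }
    }
    if (vclamp) {
      while (vc_ptr + 1 < vc_t.size() && t >= vc_t[vc_ptr + 1] - 1e-9)
        vc_ptr++;
      vc_level = vc_v[vc_ptr];
    }

    // --- 1. membrane currents and the Crank-Nicolson system M dV = F(V^n),
    // using the staggered gates (which live at t + dt/2) ---
    for (int i = 0; i < N; i++) {
      double w; const double *b0, *b1; tab_lookup(tb, v[i], w, b0, b1);
      double w1 = 1 - w;
      double m = gate[0][i], h = gate[1][i], n = gate[2][i];
      double mt = gate[3][i], ht = gate[4][i], ml = gate[5][i],
        mh = gate[6][i], ma = gate[7][i], mc = gate[8][i];
      double gna_i = gna[i] * m * m * m * h;
      double gk_i = gkdr[i] * n * n * n * n;
      double gh_i = gh[i] * mh;
      double ga_i = gahp[i] * (ahp_sq ? ma * ma : ma);
      double gc_i = gcan[i] * mc;
      double gci = b0[TB_GCI] * w1 + b1[TB_GCI] * w;
      double gco = b0[TB_GCO] * w1 + b1[TB_GCO] * w;
      double dgci = b0[TB_DGCI] * w1 + b1[TB_DGCI] * w;
      double dgco = b0[TB_DGCO] * w1 + b1[TB_DGCO] * w;
      double pt_i = pcat[i] * mt * mt * ht;
      double pl_i = pcal[i] * ml * ml;
      double ica = (pt_i + pl_i) * (ca[i] * gci - gco);
      ica_seg[i] = ica;
      double iion = gna_i * (v[i] - ena) + gk_i * (v[i] - ek)
        + gh_i * (v[i] - eh) + ga_i * (v[i] - ek) + gc_i * (v[i] - ecan)
        + ica + gpas[i] * (v[i] - epas);
      double gion = gna_i + gk_i + gh_i + ga_i + gc_i + gpas[i]
        + (pt_i + pl_i) * (ca[i] * dgci - dgco);
      double isyn = 0, gsd = 0;
      if (nsyn && gsyn_seg[i] > 0) {
        gsd = gsyn_seg[i] / area[i];
        isyn = gsd * (v[i] - sy_e);
      }
      diag[i] = ceff / dt + 0.5 * (gion + gsd);
      rhs[i] = -(iion + isyn) + inj[i] / area[i];
      al[i] = au[i] = 0;
      int p = parent[i];
      if (p >= 0) {
        al[i] = -0.5 * ax_g[i] / area[i];   // row i, col parent
        au[i] = -0.5 * ax_g[i] / area[p];   // row parent, col i
      }
    }
    // axial explicit currents + diagonal coupling terms
    for (int i = N - 1; i >= 1; i--) {
      int p = parent[i];
      double dI = ax_g[i] * (v[p] - v[i]);    // mA flowing into i
      rhs[i] += dI / area[i];
      rhs[p] -= dI / area[p];
      diag[i] += 0.5 * ax_g[i] / area[i];
      diag[p] += 0.5 * ax_g[i] / area[p];
    }
    if (vclamp) {
      diag[vc_seg] += GCLAMP;
      rhs[vc_seg] += GCLAMP * (vc_level - v[vc_seg]);
    }

    // --- 2. tree solve (Hines elimination, leaves -> root -> leaves) ---
    for (int i = N - 1; i >= 1; i--) {
      int p = parent[i];
      double f = au[i] / diag[i];
      diag[p] -= f * al[i];
      rhs[p] -= f * rhs[i];
    }
    rhs[0] /= diag[0];
    for (int i = 1; i < N; i++)
      rhs[i] = (rhs[i] - al[i] * rhs[parent[i]]) / diag[i];
    for (int i = 0; i < N; i++) v[i] += rhs[i];

    // --- 3. advance gates to t + 3dt/2 with rates at the new voltage
    // (time-centred for the gate interval), exact exponential update;
    // then the calcium pool, implicit, driven by the fresh calcium
    // current ---
    for (int i = 0; i < N; i++) {
      double w; const double *b0, *b1; tab_lookup(tb, v[i], w, b0, b1);
      double w1 = 1 - w;
      for (int k = 0; k < 7; k++) {
        double inf = b0[2 * k] * w1 + b1[2 * k] * w;
        double fac = b0[2 * k + 1] * w1 + b1[2 * k + 1] * w;
        gate[k][i] += (inf - gate[k][i]) * fac;
      }
      double c2 = ca[i] * ca[i];
      double ahp_inf = ahp_hill4 ? (c2 * c2) / (c2 * c2 + ahp_h4)
                                 : c2 / (c2 + ahp_h2);
      gate[7][i] += (ahp_inf - gate[7][i]) * ahp_fac;
      gate[8][i] += (c2 / (c2 + can_half * can_half) - gate[8][i]) * can_fac;
      double gci = b0[TB_GCI] * w1 + b1[TB_GCI] * w;
      double gco = b0[TB_GCO] * w1 + b1[TB_GCO] * w;
      // calcium current centred on the step: average of the pre-update
      // (part 1) and post-update gate/voltage evaluations
      double mt = gate[3][i], ht = gate[4][i], ml = gate[5][i];
      double ica_new = (pcat[i] * mt * mt * ht + pcal[i] * ml * ml) *
        (ca[i] * gci - gco);
      double ica = 0.5 * (ica_seg[i] + ica_new);
      ica_seg[i] = ica_new;
      // exact exponential update of the leaky integrator for this drive
      double ss = ca_rest - ca_alpha * ca_tau * ica;
      ca[i] = ss + (ca[i] - ss) * ca_dec;
      if (ca[i] < 0) ca[i] = 0;
    }

    // --- 5. synapse state decay ---
    for (int s = 0; s < nsyn; s++) { synA[s] *= synfacA; synB[s] *= synfacB; }

    // --- stability checks ---
    if (!(v[0] == v[0]))
      stop("integration produced NaN at t = %g ms", t);
    if (std::fabs(v[0]) > 200.0 || std::fabs(v[N - 1]) > 200.0)
      stop("integration unstable: |V| > 200 mV at t = %g ms", t);
  }

  NumericVector vf(N), caf(N);
  NumericMatrix gf(N, 9);
  for (int i = 0; i < N; i++) {
    vf[i] = v[i]; caf[i] = ca[i];
    for (int k = 0; k < 9; k++) gf(i, k) = gate[k][i];
  }
  List fin = List::create(_["v"] = vf, _["ca"] = caf, _["gates"] = gf);

  return List::create(_["t"] = t_out, _["v"] = v_out, _["ca"] = ca_out,
                      _["iclamp"] = iclamp_out, _["final"] = fin);
}
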