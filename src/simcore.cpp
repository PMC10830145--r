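// Implicit (backward-Euler) cable-equation solver on a branched tree.
//
// Compartments are ordered parents-before-children so the symmetric
// tree-structured linear system can be solved in O(n) per step (Hines
// elimination).  Gating variables advance by Rush-Larsen exponential
// updates using voltage lookup tables rebuilt for each dt.  Calcium
// channels use GHK flux; ohmic channels are treated implicitly in V,
// GHK and the NMDA magnesium block explicitly at the previous step.
//
// Units: V mV, t ms, capacitance nF, conductance uS, current nA,
// concentration mM, channel densities S/cm2 (ohmic) or cm/s (GHK).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212;   // C/mol
static const double GASCONST = 8.31446;      // J/(mol K)

// voltage table grid
static const double VT_MIN = -130.0, VT_MAX = 70.0, VT_DV = 0.05;
static const int VT_N = (int)((VT_MAX - VT_MIN) / VT_DV) + 1;

struct GateSpec {
  int kind;        // 0 = voltage, 1 = calcium Hill, 2 = BK (V with Ca shift)
  int power;
  // voltage / BK
  double vhalf, slope, tau_base, tau_amp, tau_vhalf, tau_s1, tau_s2;
  // calcium Hill
  int hill;
  double ec50, tau_ca;
  // BK
  double ca_ref, tau_bk;
  // tables (voltage-kind only): inf and 1 - exp(-dt/tau)
  std::vector<double> tinf, trel;
  // BK: E(V) = exp(-(V - vhalf)/slope) table and relaxation factor
  std::vector<double> tE;
  double rel_const; // for constant-tau gates
};

struct ChanSpec {
  int type;        // 0 = ohmic, 1 = GHK calcium
  double erev;
  std::vector<GateSpec> gates;
  int gate0;       // index of first gate in global gate state matrix
};

static inline double table_at(const std::vector<double>& tb, double v) {
  double p = (v - VT_MIN) / VT_DV;
  if (p <= 0) return tb[0];
  if (p >= VT_N - 1) return tb[VT_N - 1];
  int i = (int)p;
  double f = p - i;
  return tb[i] * (1.0 - f) + tb[i + 1] * f;
}

static inline double gate_inf(const GateSpec& g, double v) {
  return 1.0 / (1.0 + std::exp((g.vhalf - v) / g.slope));
}
static inline double gate_tau(const GateSpec& g, double v) {
  if (g.tau_amp == 0.0) return g.tau_base;
  return g.tau_base + g.tau_amp /
    (std::exp((v - g.tau_vhalf) / g.tau_s1) +
     std::exp(-(v - g.tau_vhalf) / g.tau_s2));
}

static void build_tables(GateSpec& g, double dt) {
  if (g.kind == 0) {
    g.tinf.resize(VT_N); g.trel.resize(VT_N);
    for (int i = 0; i < VT_N; ++i) {
      double v = VT_MIN + i * VT_DV;
      g.tinf[i] = gate_inf(g, v);
      g.trel[i] = 1.0 - std::exp(-dt / gate_tau(g, v));
    }
  } else if (g.kind == 1) {
    g.rel_const = 1.0 - std::exp(-dt / g.tau_ca);
  } else {
    g.tE.resize(VT_N);
    for (int i = 0; i < VT_N; ++i) {
      double v = VT_MIN + i * VT_DV;
      g.tE[i] = std::exp(-(v - g.vhalf) / g.slope);
    }
    g.rel_const = 1.0 - std::exp(-dt / g.tau_bk);
  }
}

// GHK voltage factors: I (A/cm2) = P * 1e-6 * (G1(V)*ci - G2(V)*co), conc mM
static void ghk_factors(double v_mV, double temp_K, double& g1, double& g2) {
  double u = 2.0 * (v_mV * 1e-3) * FARADAY / (GASCONST * temp_K);
  double zF = 2.0 * FARADAY;
  if (std::fabs(u) < 1e-6) {
    g1 = zF * (1.0 + u / 2.0);
    g2 = zF * (1.0 - u / 2.0);
  } else {
    double em = std::exp(-u);
    g1 = zF * u / (1.0 - em);
    g2 = zF * u * em / (1.0 - em);
  }
}

// [[Rcpp::export]]
List simulate_cpp(List sys, List events, List config) {
  // --- system arrays ---
  IntegerVector parent = sys["parent"];          // 0-based, -1 root
  NumericVector cap = sys["cap_nF"];
  NumericVector gax = sys["g_axial_uS"];         // coupling to parent
  NumericVector area = sys["area_cm2"];
  NumericVector gpas = sys["g_pas_uS"];
  NumericVector epas = sys["e_pas_mV"];
  NumericVector gtonic = sys["g_tonic_uS"];
  double etonic = as<double>(sys["e_tonic_mV"]);
  NumericMatrix dens = sys["density"];           // n_comp x n_chan
  List chans = sys["channels"];
  double temp_K = as<double>(sys["temp_K"]);
  double ca0 = as<double>(sys["ca_rest_mM"]);
  double tau_ca = as<double>(sys["ca_tau_ms"]);
  double ca_depth_cm = as<double>(sys["ca_depth_um"]) * 1e-4;
  double ca_out = as<double>(sys["ca_out_mM"]);
  // NMDA magnesium block parameters
  double mg_conc = as<double>(sys["mg_mM"]);
  double mg_k = as<double>(sys["mg_k_mM"]);
  double mg_gamma = as<double>(sys["mg_gamma_per_mV"]);

  int n = parent.size();
  int n_chan = chans.size();

  // parse channels
  std::vector<ChanSpec> ch(n_chan);
  int n_gates = 0;
  for (int c = 0; c < n_chan; ++c) {
    List cl = chans[c];
    ch[c].type = as<int>(cl["type"]);
    ch[c].erev = as<double>(cl["erev"]);
    List gl = cl["gates"];
    ch[c].gate0 = n_gates;
    for (int k = 0; k < gl.size(); ++k) {
      List gk = gl[k];
      GateSpec gs;
      gs.kind = as<int>(gk["kind"]);
      gs.power = as<int>(gk["power"]);
      gs.vhalf = gs.slope = 0; gs.tau_base = 1; gs.tau_amp = 0;
      gs.tau_vhalf = 0; gs.tau_s1 = gs.tau_s2 = 10;
      gs.hill = 1; gs.ec50 = 1; gs.tau_ca = 1; gs.ca_ref = 1; gs.tau_bk = 1;
      if (gs.kind == 0) {
        gs.vhalf = as<double>(gk["vhalf"]); gs.slope = as<double>(gk["slope"]);
        gs.tau_base = as<double>(gk["tau_base"]);
        gs.tau_amp = as<double>(gk["tau_amp"]);
        if (gs.tau_amp != 0.0) {
          gs.tau_vhalf = as<double>(gk["tau_vhalf"]);
          gs.tau_s1 = as<double>(gk["tau_s1"]);
          gs.tau_s2 = as<double>(gk["tau_s2"]);
        }
      } else if (gs.kind == 1) {
        gs.hill = as<int>(gk["hill"]); gs.ec50 = as<double>(gk["ec50"]);
        gs.tau_ca = as<double>(gk["tau"]);
      } else {
        gs.vhalf = as<double>(gk["vhalf"]); gs.slope = as<double>(gk["slope"]);
        gs.ca_ref = as<double>(gk["ca_ref"]); gs.tau_bk = as<double>(gk["tau"]);
      }
      ch[c].gates.push_back(gs);
      ++n_gates;
    }
  }

  // --- config ---
  double dt = as<double>(config["dt"]);
  double duration = as<double>(config["duration"]);
  IntegerVector rec = config["record"];          // 0-based compartments
  int rec_every = config.containsElementNamed("record_every") ?
    as<int>(config["record_every"]) : 1;

  // current clamps: matrices with columns comp(0-based), amp_nA, t0, t1
  NumericMatrix iclamp = config.containsElementNamed("iclamp") ?
    as<NumericMatrix>(config["iclamp"]) : NumericMatrix(0, 4);
  // sinusoids: comp, amp_nA, freq_Hz, t0
  NumericMatrix isine = config.containsElementNamed("isine") ?
    as<NumericMatrix>(config["isine"]) : NumericMatrix(0, 4);

  for (int c = 0; c < n_chan; ++c)
    for (size_t k = 0; k < ch[c].gates.size(); ++k)
      build_tables(ch[c].gates[k], dt);

  // GHK voltage tables
  std::vector<double> tg1(VT_N), tg2(VT_N);
  for (int i = 0; i < VT_N; ++i)
    ghk_factors(VT_MIN + i * VT_DV, temp_K, tg1[i], tg2[i]);

  // flattened runtime views of the gate specs (channel-order, contiguous)
  struct GateRT {
    int kind, power, hill;
    const double *tinf, *trel, *tE;
    double rel_const, ec50, ca_ref;
  };
  std::vector<GateRT> grt;
  std::vector<int> chan_type(n_chan), chan_g0(n_chan), chan_ng(n_chan);
  std::vector<double> chan_erev(n_chan);
  for (int c = 0; c < n_chan; ++c) {
    chan_type[c] = ch[c].type; chan_erev[c] = ch[c].erev;
    chan_g0[c] = ch[c].gate0; chan_ng[c] = (int)ch[c].gates.size();
    for (size_t k = 0; k < ch[c].gates.size(); ++k) {
      const GateSpec& g = ch[c].gates[k];
      GateRT r;
      r.kind = g.kind; r.power = g.power; r.hill = g.hill;
      r.tinf = g.kind == 0 ? g.tinf.data() : nullptr;
      r.trel = g.kind == 0 ? g.trel.data() : nullptr;
      r.tE = g.kind == 2 ? g.tE.data() : nullptr;
      r.rel_const = g.rel_const; r.ec50 = g.ec50; r.ca_ref = g.ca_ref;
      grt.push_back(r);
    }
  }

  // per-compartment conductance factors, compartment-major:
  // ohmic channels: density*area*1e6 (uS); GHK: density*area*1e3 (so that
  // gfac*(G1*ci - G2*co) is in nA)
  std::vector<double> gfac((size_t)n * n_chan);
  std::vector<double> inv_area6(n);
  for (int i = 0; i < n; ++i) {
    inv_area6[i] = 1.0 / (area[i] * 1e6);
    for (int c = 0; c < n_chan; ++c)
      gfac[(size_t)i * n_chan + c] = dens(i, c) * area[i] *
        (chan_type[c] == 0 ? 1e6 : 1e3);
  }

  // --- state ---
  std::vector<double> v(n), ca(n, ca0);
  std::vector<double> gates(n * n_gates);
  bool have_init = config.containsElementNamed("init_state") &&
    !Rf_isNull(config["init_state"]);
  if (have_init) {
    List st = config["init_state"];
    NumericVector v0 = st["v"]; NumericVector ca_i = st["ca"];
    NumericVector g0 = st["gates"];
    for (int i = 0; i < n; ++i) { v[i] = v0[i]; ca[i] = ca_i[i]; }
    for (int i = 0; i < n * n_gates; ++i) gates[i] = g0[i];
  } else {
    double v_init = as<double>(config["v_init"]);
    for (int i = 0; i < n; ++i) v[i] = v_init;
    for (int c = 0; c < n_chan; ++c)
      for (size_t k = 0; k < ch[c].gates.size(); ++k) {
        const GateSpec& g = ch[c].gates[k];
        int gi = ch[c].gate0 + (int)k;
        for (int i = 0; i < n; ++i) {
          double x;
          if (g.kind == 0) x = gate_inf(g, v_init);
          else if (g.kind == 1) {
            double cr = 1.0;
            for (int h = 0; h < g.hill; ++h) cr *= ca0 / g.ec50;
            x = cr / (1.0 + cr);
          } else {
            double rr = g.ca_ref / ca0;
            x = 1.0 / (1.0 + table_at(g.tE, v_init) * rr * rr);
          }
          gates[(size_t)i * n_gates + gi] = x;
        }
      }
  }

  // --- synapse events ---
  NumericVector ev_comp = events["comp"];        // 0-based
  NumericVector ev_onset = events["onset"];
  NumericVector ev_tau1 = events["tau1"];
  NumericVector ev_tau2 = events["tau2"];
  NumericVector ev_gmax = events["gmax_uS"];
  NumericVector ev_erev = events["erev"];
  NumericVector ev_nmda = events["nmda"];
  int n_ev = ev_comp.size();
  std::vector<double> sA(n_ev, 0.0), sB(n_ev, 0.0);
  std::vector<double> eA(n_ev), eB(n_ev), sNorm(n_ev);
  std::vector<bool> fired(n_ev, false);
  for (int e = 0; e < n_ev; ++e) {
    eA[e] = std::exp(-dt / ev_tau1[e]);
    eB[e] = std::exp(-dt / ev_tau2[e]);
    double tp = ev_tau1[e] * ev_tau2[e] / (ev_tau2[e] - ev_tau1[e]) *
      std::log(ev_tau2[e] / ev_tau1[e]);
    sNorm[e] = 1.0 / (std::exp(-tp / ev_tau2[e]) - std::exp(-tp / ev_tau1[e]));
  }

  int n_steps = (int)std::round(duration / dt);
  int n_rec = rec.size();
  int n_samp = n_steps / rec_every + 1;
  NumericMatrix vout(n_samp, n_rec);
  NumericVector tout(n_samp);
  int samp = 0;
  for (int r = 0; r < n_rec; ++r) vout(0, r) = v[rec[r]];
  tout[0] = 0.0; samp = 1;

  std::vector<double> diag(n), rhs(n), ica_dens(n);

  for (int step = 0; step < n_steps; ++step) {
    double t_new = (step + 1) * dt;

    // synapse state decay + event onsets occurring within this step
    for (int e = 0; e < n_ev; ++e) {
      sA[e] *= eA[e]; sB[e] *= eB[e];
      if (!fired[e] && ev_onset[e] < t_new - 1e-9) {
        sA[e] += sNorm[e]; sB[e] += sNorm[e];
        fired[e] = true;
      }
    }

    // fused gate update (Rush-Larsen at previous voltage) and assembly
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      // shared voltage-table index for every gate of this compartment
      double p = (vi - VT_MIN) / VT_DV;
      if (p < 0) p = 0;
      if (p > VT_N - 1.000001) p = VT_N - 1.000001;
      int ti = (int)p;
      double tf = p - ti, tf1 = 1.0 - tf;

      double cdt = cap[i] / dt;
      double d = cdt + gpas[i] + gtonic[i];
      double r = cdt * vi + gpas[i] * epas[i] + gtonic[i] * etonic;
      double cai = ca[i];
      double ica_nA = 0.0;
      double G1 = 0, G2 = 0;
      bool ghk_ready = false;
      double* gi = &gates[(size_t)i * n_gates];
      const double* gf = &gfac[(size_t)i * n_chan];

      for (int c = 0; c < n_chan; ++c) {
        double fac = gf[c];
        if (fac == 0.0) continue;
        double open = 1.0;
        int g0 = chan_g0[c], ng = chan_ng[c];
        for (int k = 0; k < ng; ++k) {
          const GateRT& g = grt[g0 + k];
          double inf, rel;
          if (g.kind == 0) {
            inf = g.tinf[ti] * tf1 + g.tinf[ti + 1] * tf;
            rel = g.trel[ti] * tf1 + g.trel[ti + 1] * tf;
          } else if (g.kind == 1) {
            double cr = cai / g.ec50, crh = cr;
            for (int h = 1; h < g.hill; ++h) crh *= cr;
            inf = crh / (1.0 + crh); rel = g.rel_const;
          } else {
            double rr = g.ca_ref / cai;
            double E = g.tE[ti] * tf1 + g.tE[ti + 1] * tf;
            inf = 1.0 / (1.0 + E * rr * rr); rel = g.rel_const;
          }
          double x = gi[g0 + k] + (inf - gi[g0 + k]) * rel;
          gi[g0 + k] = x;
          for (int q = 0; q < g.power; ++q) open *= x;
        }
        if (chan_type[c] == 0) {
          double gg = fac * open;                 // uS
          d += gg; r += gg * chan_erev[c];
        } else {
          if (!ghk_ready) {
            G1 = tg1[ti] * tf1 + tg1[ti + 1] * tf;
            G2 = tg2[ti] * tf1 + tg2[ti + 1] * tf;
            ghk_ready = true;
          }
          double i_nA = fac * open * (G1 * cai - G2 * ca_out);
          ica_nA += i_nA;
          r -= i_nA;                              // explicit GHK current
        }
      }
      ica_dens[i] = ica_nA * inv_area6[i];        // mA/cm2
      diag[i] = d; rhs[i] = r;
    }

    // synaptic conductances (implicit ohmic; NMDA block at previous V)
    for (int e = 0; e < n_ev; ++e) {
      double g = ev_gmax[e] * (sB[e] - sA[e]);
      if (g <= 0) continue;
      int i = (int)ev_comp[e];
      if (ev_nmda[e] != 0.0) {
        double ub = 1.0 / (1.0 + (mg_conc / mg_k) * std::exp(-mg_gamma * v[i]));
        g *= ub;
      }
      diag[i] += g; rhs[i] += g * ev_erev[e];
    }

    // injected currents
    double t_mid = t_new; // evaluate stimulus at end of step
    for (int j = 0; j < iclamp.nrow(); ++j) {
      if (t_mid > iclamp(j, 2) && t_mid <= iclamp(j, 3))
        rhs[(int)iclamp(j, 0)] += iclamp(j, 1);
    }
    for (int j = 0; j < isine.nrow(); ++j) {
      if (t_mid > isine(j, 3))
        rhs[(int)isine(j, 0)] += isine(j, 1) *
          std::sin(2.0 * M_PI * isine(j, 2) * (t_mid - isine(j, 3)) * 1e-3);
    }

    // axial coupling and Hines solve
    for (int i = n - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double g = gax[i];
      diag[i] += g; diag[p] += g;
      // eliminate child i into parent p
      double f = g / diag[i];
      diag[p] -= f * g;
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      v[i] = (rhs[i] + gax[i] * v[p]) / diag[i];
    }

    // calcium pools
    for (int i = 0; i < n; ++i) {
      if (ica_dens[i] != 0.0 || ca[i] != ca0) {
        double dca = -ica_dens[i] / (2.0 * FARADAY * ca_depth_cm) -
          (ca[i] - ca0) / tau_ca;
        ca[i] += dt * dca;
        if (ca[i] < 1e-9) ca[i] = 1e-9;
      }
    }

    if (!std::isfinite(v[0]) || std::fabs(v[0]) > 500.0)
      stop("simulation diverged at t = %f ms", t_new);

    if ((step + 1) % rec_every == 0) {
      for (int r = 0; r < n_rec; ++r) vout(samp, r) = v[rec[r]];
      tout[samp] = t_new;
      ++samp;
    }
  }

  NumericVector v_end(n), ca_end(n), g_end(n * n_gates);
  for (int i = 0; i < n; ++i) { v_end[i] = v[i]; ca_end[i] = ca[i]; }
  for (int i = 0; i < n * n_gates; ++i) g_end[i] = gates[i];

  return List::create(
    _["t"] = tout, _["v"] = vout,
    _["state"] = List::create(_["v"] = v_end, _["ca"] = ca_end,
                              _["gates"] = g_end));
}

// Evaluate gate steady state / time constant for a voltage gate spec —
// used by the R-level gating code and tests so both sides share one
// functional form.
// [[Rcpp::export]]
NumericMatrix gate_curves_cpp(double vhalf, double slope, double tau_base,
                              double tau_amp, double tau_vhalf,
                              double tau_s1, double tau_s2,
                              NumericVector v) {
  GateSpec g;
  g.kind = 0; g.power = 1;
  g.vhalf = vhalf; g.slope = slope; g.tau_base = tau_base;
  g.tau_amp = tau_amp; g.tau_vhalf = tau_vhalf;
  g.tau_s1 = tau_s1; g.tau_s2 = tau_s2;
  NumericMatrix out(v.size(), 2);
  for (int i = 0; i < v.size(); ++i) {
    out(i, 0) = gate_inf(g, v[i]);
    out(i, 1) = gate_tau(g, v[i]);
  }
  return out;
}
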