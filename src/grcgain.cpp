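// Simulation kernels: Markov receptor-scheme stepping, Tsodyks-Markram
// presynaptic dynamics, and the compartmental circuit integrator
// (exponential-Euler gating, implicit-Euler voltage via a Hines tree solve).
//
// Units throughout: time ms, voltage mV, conductance uS, current nA,
// capacitance nF, concentration mM, area cm2, shell depth cm.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double FARADAY = 96485.3329; // C/mol

// ---------------------------------------------------------------------------
// Markov scheme master-equation stepping
// ---------------------------------------------------------------------------

// Build the occupancy derivative d occ/dt for transitions (from, to, rate,
// drive) at transmitter concentration T. drive: 0 const, 1 linear in T,
// 2 saturating AMPA drive S = T^2/(T+KB)^2.
static inline void scheme_deriv(const std::vector<double> &occ,
                                const int *from, const int *to,
                                const double *rate, const int *drive,
                                int ntr, double KB, double T,
                                std::vector<double> &d) {
  const int ns = (int)occ.size();
  for (int i = 0; i < ns; ++i) d[i] = 0.0;
  double S = 0.0;
  if (T > 0.0) {
    const double f = T / (T + KB);
    S = f * f;
  }
  for (int k = 0; k < ntr; ++k) {
    double r = rate[k];
    if (drive[k] == 1) r *= T;
    else if (drive[k] == 2) r *= S;
    if (r <= 0.0) continue;
    const double flux = r * occ[from[k]];
    d[from[k]] -= flux;
    d[to[k]] += flux;
  }
}

// One RK4 substep cycle over dt with nsub substeps.
static void scheme_rk4(std::vector<double> &occ,
                       const int *from, const int *to,
                       const double *rate, const int *drive,
                       int ntr, double KB, double T,
                       double dt, int nsub) {
  const int ns = (int)occ.size();
  const double h = dt / nsub;
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  for (int s = 0; s < nsub; ++s) {
    scheme_deriv(occ, from, to, rate, drive, ntr, KB, T, k1);
    for (int i = 0; i < ns; ++i) tmp[i] = occ[i] + 0.5 * h * k1[i];
    scheme_deriv(tmp, from, to, rate, drive, ntr, KB, T, k2);
    for (int i = 0; i < ns; ++i) tmp[i] = occ[i] + 0.5 * h * k2[i];
    scheme_deriv(tmp, from, to, rate, drive, ntr, KB, T, k3);
    for (int i = 0; i < ns; ++i) tmp[i] = occ[i] + h * k3[i];
    scheme_deriv(tmp, from, to, rate, drive, ntr, KB, T, k4);
    for (int i = 0; i < ns; ++i)
      occ[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
  // guard against tiny negative excursions; renormalise to conserve
  double tot = 0.0;
  for (int i = 0; i < ns; ++i) {
    if (occ[i] < 0.0) occ[i] = 0.0;
    tot += occ[i];
  }
  if (tot > 0.0)
    for (int i = 0; i < ns; ++i) occ[i] /= tot;
}

// [[Rcpp::export]]
NumericVector scheme_step_cpp(NumericVector occ, IntegerVector from,
                              IntegerVector to, NumericVector rate,
                              IntegerVector drive, double KB,
                              double T, double dt) {
  const int ns = occ.size(), ntr = from.size();
  // substep so that (max total rate) * h stays small even for large dt
  double rsum = 0.0;
  for (int k = 0; k < ntr; ++k) {
    double r = rate[k];
    if (drive[k] == 1) r *= T;
    else if (drive[k] == 2) r *= 1.0; // S < 1
    rsum += r;
  }
  int nsub = 1 + (int)std::ceil(dt * std::max(rsum, 1e-12) / 0.25);
  std::vector<double> o(occ.begin(), occ.end());
  scheme_rk4(o, from.begin(), to.begin(), rate.begin(), drive.begin(),
             ntr, KB, T, dt, nsub);
  return NumericVector(o.begin(), o.end());
}

// ---------------------------------------------------------------------------
// Tsodyks-Markram closed-form interval solution
// ---------------------------------------------------------------------------

// Advance (X, Y, Z) by dt under dY/dt = -Y/tauI, dZ/dt = Y/tauI - Z/tauR,
// X = 1 - Y - Z (conservation exact). Degenerate tauI == tauR handled by
// the t*exp(-t/tau) limit.
static inline void tm_interval_cpp(double &X, double &Y, double &Z,
                                   double dt, double tauI, double tauR) {
  const double a = 1.0 / tauI, b = 1.0 / tauR;
  const double Y0 = Y, Z0 = Z;
  Y = Y0 * std::exp(-a * dt);
  if (std::fabs(a - b) < 1e-12 * std::max(a, b)) {
    Z = (Z0 + a * Y0 * dt) * std::exp(-a * dt);
  } else {
    const double C = a * Y0 / (b - a);
    Z = (Z0 - C) * std::exp(-b * dt) + C * std::exp(-a * dt);
  }
  X = 1.0 - Y - Z;
}

// ---------------------------------------------------------------------------
// Gating-rate functions
// ---------------------------------------------------------------------------

// type 0: A * exp((V - V0) / K)
// type 1: A / (1 + exp((V - V0) / K))
// type 2: linoid A * (V - V0) / (1 - exp(-(V - V0) / K))
static inline double hh_rate(int type, double A, double V0, double K,
                             double V) {
  const double x = (V - V0) / K;
  switch (type) {
  case 0: return A * std::exp(x);
  case 1: return A / (1.0 + std::exp(x));
  default: {
    if (std::fabs(x) < 1e-6) return A * K * (1.0 + 0.5 * x);
    return A * K * x / (1.0 - std::exp(-x));
  }
  }
}

// Calcium-dependent K rates (KCa kind):
//   alpha = Aa / (1 + Ka * exp(-V/Va) / ca)
//   beta  = Ab / (1 + ca / (Kb * exp(-V/Vb)))
static inline double kca_alpha(double Aa, double Ka, double Va,
                               double V, double ca) {
  return Aa / (1.0 + Ka * std::exp(-V / Va) / std::max(ca, 1e-9));
}
static inline double kca_beta(double Ab, double Kb, double Vb,
                              double V, double ca) {
  return Ab / (1.0 + std::max(ca, 1e-9) / (Kb * std::exp(-V / Vb)));
}

// ---------------------------------------------------------------------------
// Flattened cell / synapse representations
// ---------------------------------------------------------------------------

struct Cell {
  int ncomp;
  std::vector<int> parent;      // -1 for root; parent[i] < i
  std::vector<double> g_ax;     // uS coupling to parent
  std::vector<double> cm;       // nF
  // channels
  std::vector<int> ch_comp;
  std::vector<double> ch_gbar;  // uS
  std::vector<double> ch_erev;  // mV; NaN => Ca Nernst from shell
  std::vector<int> ch_np;       // particles per channel
  std::vector<int> ch_p0;       // first particle index
  std::vector<int> ch_is_ca;    // current feeds calcium shell
  // particles (global arrays)
  std::vector<double> pt_z;
  std::vector<int> pt_kind;     // 0 HH, 1 KCa
  std::vector<int> pt_atype, pt_btype;
  std::vector<double> pt_aA, pt_aV0, pt_aK;
  std::vector<double> pt_bA, pt_bV0, pt_bK;
  // calcium shells
  std::vector<int> ca_has;
  std::vector<double> ca_depth, ca_beta, ca0, ca_area;
  double cao;
  double eca_factor;            // RT/2F in mV
  // state
  std::vector<double> V, Vprev, x, ca;
  // stimulation / recording
  double bias;                  // nA at comp 0
  int clamp_comp;               // -1 none
  double clamp_v;
  int record_comp;
  double v_init;
  // spike detection at comp 0
  double spike_thr;
  double last_spike;
  // workspaces
  std::vector<double> D, B, gsyn, gesyn;
};

struct Receptor {
  int ns, ntr;
  std::vector<int> from, to, drive, open;
  std::vector<double> rate;
  double KB;
  double gmax;                  // uS (total over sites)
  double erev;
  bool mg;
  double mgC;
  bool diffusion_only;
  std::vector<double> P0;      // ns x ns column-major propagator at T = 0
  std::vector<double> occ, tmp;
};

struct Synapse {
  int post_cell, post_comp;
  int pre_kind;                 // 0 external mf, 1 cell
  int pre_index;                // mf id or cell id
  double delay;
  // TM
  double p, tauR, tauF, tauI;
  int n_sites;
  bool stochastic;
  std::vector<double> sX, sY, sZ; // per-site states
  double P;                     // shared facilitation state
  double t_last;
  // transmitter
  double Ts_max, Td_max, pulse_dur, diff_tau, td_decay;
  double td_level, ts_level;
  std::deque<std::pair<double, double>> ts_pulses; // (end time, amplitude)
  std::deque<double> pending;   // event times
  std::vector<Receptor> rec;
};

static Cell build_cell(const List &cl) {
  Cell c;
  IntegerVector parent = cl["parent"];
  NumericVector g_ax = cl["g_ax"], cm = cl["cm"];
  c.ncomp = parent.size();
  c.parent.assign(parent.begin(), parent.end());
  c.g_ax.assign(g_ax.begin(), g_ax.end());
  c.cm.assign(cm.begin(), cm.end());
  IntegerVector ch_comp = cl["ch_comp"], ch_np = cl["ch_np"],
    ch_is_ca = cl["ch_is_ca"];
  NumericVector ch_gbar = cl["ch_gbar"], ch_erev = cl["ch_erev"];
  c.ch_comp.assign(ch_comp.begin(), ch_comp.end());
  c.ch_gbar.assign(ch_gbar.begin(), ch_gbar.end());
  c.ch_erev.assign(ch_erev.begin(), ch_erev.end());
  c.ch_np.assign(ch_np.begin(), ch_np.end());
  c.ch_is_ca.assign(ch_is_ca.begin(), ch_is_ca.end());
  c.ch_p0.resize(c.ch_np.size());
  int acc = 0;
  for (size_t i = 0; i < c.ch_np.size(); ++i) {
    c.ch_p0[i] = acc;
    acc += c.ch_np[i];
  }
  NumericVector pt_z = cl["pt_z"];
  IntegerVector pt_kind = cl["pt_kind"], pt_atype = cl["pt_atype"],
    pt_btype = cl["pt_btype"];
  NumericVector pt_aA = cl["pt_aA"], pt_aV0 = cl["pt_aV0"],
    pt_aK = cl["pt_aK"], pt_bA = cl["pt_bA"], pt_bV0 = cl["pt_bV0"],
    pt_bK = cl["pt_bK"];
  c.pt_z.assign(pt_z.begin(), pt_z.end());
  c.pt_kind.assign(pt_kind.begin(), pt_kind.end());
  c.pt_atype.assign(pt_atype.begin(), pt_atype.end());
  c.pt_btype.assign(pt_btype.begin(), pt_btype.end());
  c.pt_aA.assign(pt_aA.begin(), pt_aA.end());
  c.pt_aV0.assign(pt_aV0.begin(), pt_aV0.end());
  c.pt_aK.assign(pt_aK.begin(), pt_aK.end());
  c.pt_bA.assign(pt_bA.begin(), pt_bA.end());
  c.pt_bV0.assign(pt_bV0.begin(), pt_bV0.end());
  c.pt_bK.assign(pt_bK.begin(), pt_bK.end());
  IntegerVector ca_has = cl["ca_has"];
  NumericVector ca_depth = cl["ca_depth"], ca_beta = cl["ca_beta"],
    ca0 = cl["ca0"], ca_area = cl["ca_area"];
  c.ca_has.assign(ca_has.begin(), ca_has.end());
  c.ca_depth.assign(ca_depth.begin(), ca_depth.end());
  c.ca_beta.assign(ca_beta.begin(), ca_beta.end());
  c.ca0.assign(ca0.begin(), ca0.end());
  c.ca_area.assign(ca_area.begin(), ca_area.end());
  c.cao = as<double>(cl["cao"]);
  c.eca_factor = as<double>(cl["eca_factor"]);
  c.bias = as<double>(cl["bias"]);
  c.clamp_comp = as<int>(cl["clamp_comp"]);
  c.clamp_v = as<double>(cl["clamp_v"]);
  c.record_comp = as<int>(cl["record_comp"]);
  c.v_init = as<double>(cl["v_init"]);
  c.spike_thr = as<double>(cl["spike_thr"]);
  c.last_spike = -1e9;
  // initial state
  c.V.assign(c.ncomp, c.v_init);
  c.Vprev = c.V;
  c.ca.assign(c.ncomp, 0.0);
  for (int i = 0; i < c.ncomp; ++i)
    c.ca[i] = c.ca_has[i] ? c.ca0[i] : 0.0;
  c.x.assign(acc, 0.0);
  for (size_t ich = 0; ich < c.ch_np.size(); ++ich) {
    const int comp = c.ch_comp[ich];
    const double ca = c.ca_has[comp] ? c.ca[comp] : 1e-4;
    for (int jp = 0; jp < c.ch_np[ich]; ++jp) {
      const int p = c.ch_p0[ich] + jp;
      double a, b;
      if (c.pt_kind[p] == 1) {
        a = kca_alpha(c.pt_aA[p], c.pt_aV0[p], c.pt_aK[p], c.v_init, ca);
        b = kca_beta(c.pt_bA[p], c.pt_bV0[p], c.pt_bK[p], c.v_init, ca);
      } else {
        a = hh_rate(c.pt_atype[p], c.pt_aA[p], c.pt_aV0[p], c.pt_aK[p],
                    c.v_init);
        b = hh_rate(c.pt_btype[p], c.pt_bA[p], c.pt_bV0[p], c.pt_bK[p],
                    c.v_init);
      }
      c.x[p] = (a + b > 0.0) ? a / (a + b) : 0.0;
    }
  }
  c.D.assign(c.ncomp, 0.0);
  c.B.assign(c.ncomp, 0.0);
  c.gsyn.assign(c.ncomp, 0.0);
  c.gesyn.assign(c.ncomp, 0.0);
  if (c.clamp_comp >= 0)
    for (int i = 0; i < c.ncomp; ++i) c.V[i] = c.clamp_v;
  return c;
}

static Synapse build_synapse(const List &sl, double dt) {
  Synapse s;
  s.post_cell = as<int>(sl["post_cell"]);
  s.post_comp = as<int>(sl["post_comp"]);
  s.pre_kind = as<int>(sl["pre_kind"]);
  s.pre_index = as<int>(sl["pre_index"]);
  s.delay = as<double>(sl["delay"]);
  s.p = as<double>(sl["p"]);
  s.tauR = as<double>(sl["tau_rec"]);
  s.tauF = as<double>(sl["tau_facil"]);
  s.tauI = as<double>(sl["tau_inact"]);
  s.n_sites = as<int>(sl["n_sites"]);
  s.stochastic = as<bool>(sl["stochastic"]);
  s.sX.assign(s.n_sites, 1.0);
  s.sY.assign(s.n_sites, 0.0);
  s.sZ.assign(s.n_sites, 0.0);
  s.P = s.p;
  s.t_last = 0.0;
  s.Ts_max = as<double>(sl["Ts_max"]);
  s.Td_max = as<double>(sl["Td_max"]);
  s.pulse_dur = as<double>(sl["pulse_dur"]);
  s.diff_tau = as<double>(sl["diff_tau"]);
  s.td_decay = std::exp(-dt / s.diff_tau);
  s.td_level = 0.0;
  s.ts_level = 0.0;
  List recs = sl["receptors"];
  for (int r = 0; r < recs.size(); ++r) {
    List rl = recs[r];
    Receptor rc;
    IntegerVector from = rl["from"], to = rl["to"], drive = rl["drive"],
      open = rl["open"];
    NumericVector rate = rl["rate"];
    rc.ns = as<int>(rl["ns"]);
    rc.ntr = from.size();
    rc.from.assign(from.begin(), from.end());
    rc.to.assign(to.begin(), to.end());
    rc.drive.assign(drive.begin(), drive.end());
    rc.open.assign(open.begin(), open.end());
    rc.rate.assign(rate.begin(), rate.end());
    rc.KB = as<double>(rl["KB"]);
    rc.gmax = as<double>(rl["gmax"]);
    rc.erev = as<double>(rl["erev"]);
    rc.mg = as<bool>(rl["mg"]);
    rc.mgC = as<double>(rl["mg_conc"]);
    rc.diffusion_only = as<bool>(rl["diffusion_only"]);
    NumericMatrix P0 = rl["P0"];
    rc.P0.assign(P0.begin(), P0.end());
    rc.occ.assign(rc.ns, 0.0);
    rc.occ[0] = 1.0;
    rc.tmp.assign(rc.ns, 0.0);
    s.rec.push_back(rc);
  }
  return s;
}

// Deliver one release event to a synapse at time t; returns pooled release.
static double synapse_release(Synapse &s, double t) {
  const double dt = t - s.t_last;
  if (dt > 0.0) {
    for (int k = 0; k < s.n_sites; ++k)
      tm_interval_cpp(s.sX[k], s.sY[k], s.sZ[k], dt, s.tauI, s.tauR);
    s.P = s.p + (s.P - s.p) * std::exp(-dt / s.tauF);
    s.t_last = t;
  }
  double total = 0.0;
  if (s.stochastic) {
    for (int k = 0; k < s.n_sites; ++k) {
      if (R::unif_rand() < s.P) {
        total += s.sX[k];
        s.sY[k] += s.sX[k];
        s.sX[k] = 0.0;
      }
    }
  } else {
    for (int k = 0; k < s.n_sites; ++k) {
      const double rel = s.P * s.sX[k];
      total += rel;
      s.sY[k] += rel;
      s.sX[k] -= rel;
    }
  }
  s.P = s.P + s.p * (1.0 - s.P);
  return total / s.n_sites;
}

// ---------------------------------------------------------------------------
// Main circuit runner
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_run_cpp(List cells_in, List synapses_in, List mf_times,
                 double dt, double t_stop, int record_every,
                 double spike_refractory, bool release_log) {
  RNGScope rngscope;

  std::vector<Cell> cells;
  for (int i = 0; i < cells_in.size(); ++i)
    cells.push_back(build_cell(cells_in[i]));
  std::vector<Synapse> syns;
  for (int i = 0; i < synapses_in.size(); ++i)
    syns.push_back(build_synapse(synapses_in[i], dt));

  // schedule mossy-fiber events (stimulus time + transmission delay)
  for (size_t j = 0; j < syns.size(); ++j) {
    if (syns[j].pre_kind == 0) {
      if (syns[j].pre_index < mf_times.size()) {
        NumericVector tt = mf_times[syns[j].pre_index];
        for (int k = 0; k < tt.size(); ++k)
          syns[j].pending.push_back(tt[k] + syns[j].delay);
      }
    }
  }

  const int nstep = (int)std::round(t_stop / dt);
  const int nrec = nstep / record_every + 1;
  const int ncell = (int)cells.size();
  NumericMatrix vrec(nrec, ncell);
  NumericMatrix irec(nrec, ncell);
  std::fill(irec.begin(), irec.end(), NA_REAL);
  NumericVector trec(nrec);
  std::vector<std::vector<double>> spikes(ncell);
  std::vector<double> rel_t, rel_a;
  std::vector<int> rel_s;

  // initial record
  int ri = 0;
  trec[0] = 0.0;
  for (int c = 0; c < ncell; ++c) {
    vrec(0, c) = cells[c].V[cells[c].record_comp];
    if (cells[c].clamp_comp >= 0) irec(0, c) = 0.0;
  }
  ri = 1;

  for (int step = 1; step <= nstep; ++step) {
    const double t = step * dt;

    // 1. synaptic release events due in (t - dt, t]
    for (size_t j = 0; j < syns.size(); ++j) {
      Synapse &s = syns[j];
      while (!s.pending.empty() && s.pending.front() <= t + 1e-9) {
        const double te = s.pending.front();
        s.pending.pop_front();
        const double amount = synapse_release(s, te);
        if (amount > 0.0) {
          s.ts_pulses.push_back(
            std::make_pair(te + s.pulse_dur, amount * s.Ts_max));
          s.ts_level += amount * s.Ts_max;
          s.td_level += amount * s.Td_max;
        }
        if (release_log) {
          rel_s.push_back((int)j + 1);
          rel_t.push_back(te);
          rel_a.push_back(amount);
        }
      }
    }

    // 2. transmitter decay, receptor stepping, synaptic conductances
    for (int c = 0; c < ncell; ++c) {
      std::fill(cells[c].gsyn.begin(), cells[c].gsyn.end(), 0.0);
      std::fill(cells[c].gesyn.begin(), cells[c].gesyn.end(), 0.0);
    }
    for (size_t j = 0; j < syns.size(); ++j) {
      Synapse &s = syns[j];
      s.td_level *= s.td_decay;
      while (!s.ts_pulses.empty() && s.ts_pulses.front().first <= t) {
        s.ts_level -= s.ts_pulses.front().second;
        s.ts_pulses.pop_front();
      }
      if (s.ts_pulses.empty()) s.ts_level = 0.0; // kill accumulation drift
      const double T_full = s.ts_level + s.td_level;
      const double T_diff = s.td_level;
      Cell &post = cells[s.post_cell];
      const double vpost = post.V[s.post_comp];
      for (size_t r = 0; r < s.rec.size(); ++r) {
        Receptor &rc = s.rec[r];
        const double T = rc.diffusion_only ? T_diff : T_full;
        if (T < 1e-12) {
          // cached matrix-exponential propagator at T = 0
          for (int i = 0; i < rc.ns; ++i) {
            double acc = 0.0;
            for (int k2 = 0; k2 < rc.ns; ++k2)
              acc += rc.P0[i + rc.ns * k2] * rc.occ[k2];
            rc.tmp[i] = acc;
          }
          rc.occ.swap(rc.tmp);
        } else {
          scheme_rk4(rc.occ, rc.from.data(), rc.to.data(), rc.rate.data(),
                     rc.drive.data(), rc.ntr, rc.KB, T, dt, 2);
        }
        double O = 0.0;
        for (size_t oi = 0; oi < rc.open.size(); ++oi)
          O += rc.occ[rc.open[oi]];
        if (O <= 0.0) continue;
        double B = 1.0;
        if (rc.mg)
          B = 1.0 / (1.0 + std::exp(-0.062 * vpost) * rc.mgC / 3.57);
        const double g = rc.gmax * O * B;
        post.gsyn[s.post_comp] += g;
        post.gesyn[s.post_comp] += g * rc.erev;
      }
    }

    // 3. per-cell gating + voltage + calcium update
    for (int c = 0; c < ncell; ++c) {
      Cell &cc = cells[c];
      cc.Vprev = cc.V;

      // gating (exponential Euler at V(t))
      for (size_t ich = 0; ich < cc.ch_np.size(); ++ich) {
        const int comp = cc.ch_comp[ich];
        const double V = cc.Vprev[comp];
        const double cav = cc.ca_has[comp] ? cc.ca[comp] : 1e-4;
        for (int jp = 0; jp < cc.ch_np[ich]; ++jp) {
          const int p = cc.ch_p0[ich] + jp;
          double a, b;
          if (cc.pt_kind[p] == 1) {
            a = kca_alpha(cc.pt_aA[p], cc.pt_aV0[p], cc.pt_aK[p], V, cav);
            b = kca_beta(cc.pt_bA[p], cc.pt_bV0[p], cc.pt_bK[p], V, cav);
          } else {
            a = hh_rate(cc.pt_atype[p], cc.pt_aA[p], cc.pt_aV0[p],
                        cc.pt_aK[p], V);
            b = hh_rate(cc.pt_btype[p], cc.pt_bA[p], cc.pt_bV0[p],
                        cc.pt_bK[p], V);
          }
          const double ab = a + b;
          if (ab > 0.0) {
            const double xinf = a / ab;
            cc.x[p] = xinf + (cc.x[p] - xinf) * std::exp(-dt * ab);
          }
        }
      }

      // assemble implicit system: (C/dt + g_tot) V_new - axial = C/dt V +
      // sum g*E + I_inj
      for (int i = 0; i < cc.ncomp; ++i) {
        cc.D[i] = cc.cm[i] / dt + cc.gsyn[i];
        cc.B[i] = cc.cm[i] / dt * cc.Vprev[i] + cc.gesyn[i];
      }
      cc.B[0] += cc.bias;
      for (size_t ich = 0; ich < cc.ch_np.size(); ++ich) {
        const int comp = cc.ch_comp[ich];
        double g = cc.ch_gbar[ich];
        for (int jp = 0; jp < cc.ch_np[ich]; ++jp) {
          const int p = cc.ch_p0[ich] + jp;
          g *= std::pow(cc.x[p], cc.pt_z[p]);
        }
        double erev = cc.ch_erev[ich];
        if (ISNAN(erev)) { // calcium Nernst
          const double cai = std::max(cc.ca[comp], 1e-9);
          erev = cc.eca_factor * std::log(cc.cao / cai);
        }
        cc.D[comp] += g;
        cc.B[comp] += g * erev;
      }
      // axial terms
      for (int i = 1; i < cc.ncomp; ++i) {
        const int pa = cc.parent[i];
        cc.D[i] += cc.g_ax[i];
        cc.D[pa] += cc.g_ax[i];
      }
      // voltage clamp by penalty
      if (cc.clamp_comp >= 0) {
        cc.D[cc.clamp_comp] += 1e9;
        cc.B[cc.clamp_comp] += 1e9 * cc.clamp_v;
      }
      // Hines elimination (children before parents; parent[i] < i)
      for (int i = cc.ncomp - 1; i >= 1; --i) {
        const int pa = cc.parent[i];
        const double f = cc.g_ax[i] / cc.D[i];
        cc.D[pa] -= cc.g_ax[i] * f;
        cc.B[pa] += f * cc.B[i];
      }
      cc.V[0] = cc.B[0] / cc.D[0];
      for (int i = 1; i < cc.ncomp; ++i)
        cc.V[i] = (cc.B[i] + cc.g_ax[i] * cc.V[cc.parent[i]]) / cc.D[i];

      if (!R_FINITE(cc.V[0]))
        stop("voltage diverged (cell %d, t = %.3f ms)", c + 1, t);

      // calcium shells (exponential update with channel currents at V_new)
      for (size_t ich = 0; ich < cc.ch_np.size(); ++ich) {
        if (!cc.ch_is_ca[ich]) continue;
        const int comp = cc.ch_comp[ich];
        if (!cc.ca_has[comp]) continue;
        double g = cc.ch_gbar[ich];
        for (int jp = 0; jp < cc.ch_np[ich]; ++jp) {
          const int p = cc.ch_p0[ich] + jp;
          g *= std::pow(cc.x[p], cc.pt_z[p]);
        }
        const double cai = std::max(cc.ca[comp], 1e-9);
        const double eca = cc.eca_factor * std::log(cc.cao / cai);
        const double ica = g * (cc.V[comp] - eca); // nA, negative inward
        const double influx = -ica * 1e-6 /
          (2.0 * FARADAY * cc.ca_area[comp] * cc.ca_depth[comp]); // mM/ms
        const double beta = cc.ca_beta[comp];
        const double steady = cc.ca0[comp] + influx / beta;
        cc.ca[comp] = steady + (cc.ca[comp] - steady) * std::exp(-beta * dt);
        if (cc.ca[comp] < 0.0) cc.ca[comp] = 0.0;
      }

      // spike detection at soma (upward crossing, refractory de-dup)
      if (cc.clamp_comp < 0 && cc.Vprev[0] < cc.spike_thr &&
          cc.V[0] >= cc.spike_thr && (t - cc.last_spike) > spike_refractory) {
        cc.last_spike = t;
        spikes[c].push_back(t);
        for (size_t j = 0; j < syns.size(); ++j)
          if (syns[j].pre_kind == 1 && syns[j].pre_index == c)
            syns[j].pending.push_back(t + syns[j].delay);
      }
    }

    // 4. record
    if (step % record_every == 0) {
      trec[ri] = t;
      for (int c = 0; c < ncell; ++c) {
        Cell &cc = cells[c];
        vrec(ri, c) = cc.V[cc.record_comp];
        if (cc.clamp_comp >= 0) {
          // electrode current balancing membrane + axial currents
          const int cp = cc.clamp_comp;
          double im = cc.gsyn[cp] * cc.clamp_v - cc.gesyn[cp];
          for (size_t ich = 0; ich < cc.ch_np.size(); ++ich) {
            if (cc.ch_comp[ich] != cp) continue;
            double g = cc.ch_gbar[ich];
            for (int jp = 0; jp < cc.ch_np[ich]; ++jp) {
              const int p = cc.ch_p0[ich] + jp;
              g *= std::pow(cc.x[p], cc.pt_z[p]);
            }
            double erev = cc.ch_erev[ich];
            if (ISNAN(erev)) {
              const double cai = std::max(cc.ca[cp], 1e-9);
              erev = cc.eca_factor * std::log(cc.cao / cai);
            }
            im += g * (cc.clamp_v - erev);
          }
          for (int i = 1; i < cc.ncomp; ++i) {
            if (i == cp)
              im += cc.g_ax[i] * (cc.clamp_v - cc.V[cc.parent[i]]);
            else if (cc.parent[i] == cp)
              im += cc.g_ax[i] * (cc.clamp_v - cc.V[i]);
          }
          im -= (cp == 0 ? cc.bias : 0.0);
          irec(ri, c) = im; // nA
        }
      }
      ++ri;
    }
  }

  List spk(ncell);
  for (int c = 0; c < ncell; ++c)
    spk[c] = NumericVector(spikes[c].begin(), spikes[c].end());

  List rl = R_NilValue;
  if (release_log) {
    rl = List::create(
      Named("synapse") = IntegerVector(rel_s.begin(), rel_s.end()),
      Named("time") = NumericVector(rel_t.begin(), rel_t.end()),
      Named("amount") = NumericVector(rel_a.begin(), rel_a.end()));
  }

  return List::create(Named("time") = trec,
                      Named("v") = vrec,
                      Named("i_clamp") = irec,
                      Named("spikes") = spk,
                      Named("releases") = rl);
}
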