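// Multicompartment Hodgkin-Huxley cable integrator.
//
// Internal unit system (matching the magnitudes of the model's parameter
// table): V in mV, t in ms, membrane areas in cm^2, conductance densities in
// mS/cm^2, absolute conductances in mS, currents in uA (point currents enter
// in nA and are converted), axial couplings in mS.
//
// Scheme: Crank-Nicolson for the axial + conductive terms (tridiagonal
// solve), Rush-Larsen exponential update for gating, synaptic conductances
// advanced by the exact two-exponential recursion of the beta function and
// evaluated at the step midpoint. Unconditionally stable at dt = 0.1 ms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// x / (exp(x/a) - 1) with the removable singularity at x = 0 handled by its
// series a - x/2 + x^2/(12 a).
static inline double vtrap(double x, double a) {
  if (std::fabs(x) < 1e-6) return a - 0.5 * x + x * x / (12.0 * a);
  return x / std::expm1(x / a);
}

struct Rates { double am, bm, ah, bh, an, bn; };

static inline Rates hh_rates(double v, double vt) {
  const double u = v - vt;
  Rates r;
  r.am = 0.32 * vtrap(13.0 - u, 4.0);
  r.bm = 0.28 * vtrap(u - 40.0, 5.0);
  r.ah = 0.128 * std::exp((17.0 - u) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  r.an = 0.032 * vtrap(15.0 - u, 5.0);
  r.bn = 0.5 * std::exp((10.0 - u) / 40.0);
  return r;
}

// Voltage-indexed lookup tables for the Rush-Larsen update: x_inf(V) and
// exp(-dt * phi * (alpha + beta)) for each gate, linearly interpolated.
struct GateTables {
  double vmin, vmax, dv;
  int n;
  std::vector<double> tab; // interleaved: 6 values per grid point

  void build(double dt, double phi, double vt) {
    vmin = -150.0; vmax = 150.0; dv = 0.025;
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    tab.resize(6 * (size_t)n);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * dv;
      Rates r = hh_rates(v, vt);
      double *t = &tab[6 * (size_t)i];
      t[0] = r.am / (r.am + r.bm);
      t[1] = std::exp(-dt * phi * (r.am + r.bm));
      t[2] = r.ah / (r.ah + r.bh);
      t[3] = std::exp(-dt * phi * (r.ah + r.bh));
      t[4] = r.an / (r.an + r.bn);
      t[5] = std::exp(-dt * phi * (r.an + r.bn));
    }
  }

  inline void update(double v, double &m, double &h, double &nn) const {
    double x = (v - vmin) / dv;
    if (x < 0.0) x = 0.0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    double f = x - i;
    const double *a = &tab[6 * (size_t)i];
    const double *b = a + 6;
    double mi = a[0] + f * (b[0] - a[0]);
    double md = a[1] + f * (b[1] - a[1]);
    double hi = a[2] + f * (b[2] - a[2]);
    double hd = a[3] + f * (b[3] - a[3]);
    double ni = a[4] + f * (b[4] - a[4]);
    double nd = a[5] + f * (b[5] - a[5]);
    m = mi + (m - mi) * md;
    h = hi + (h - hi) * hd;
    nn = ni + (nn - ni) * nd;
  }
};

// One cable (ball-and-stick neuron) plus scratch space for the tridiagonal
// Crank-Nicolson solve.
struct Cable {
  int n;
  std::vector<double> area;        // cm^2
  std::vector<double> gax;         // mS, coupling between centers i and i+1
  std::vector<double> cdt;         // C/dt per segment, uF/ms
  std::vector<double> gna, gk, gl; // absolute mS per segment
  double ena, ek, el;
  std::vector<double> V, m, h, nn;
  // scratch
  std::vector<double> diag, rhs, cp, dp;
  bool active;

  void init(const NumericVector &area_, const NumericVector &gax_,
            double cm, double gna_d, double gk_d, double gl_d,
            double ena_, double ek_, double el_, double dt, bool active_) {
    n = area_.size();
    area.assign(area_.begin(), area_.end());
    gax.assign(gax_.begin(), gax_.end());
    cdt.resize(n); gna.resize(n); gk.resize(n); gl.resize(n);
    for (int i = 0; i < n; ++i) {
      cdt[i] = cm * area[i] / dt;
      gna[i] = gna_d * area[i];
      gk[i] = gk_d * area[i];
      gl[i] = gl_d * area[i];
    }
    ena = ena_; ek = ek_; el = el_;
    active = active_;
    V.assign(n, 0.0); m.assign(n, 0.0); h.assign(n, 0.0); nn.assign(n, 0.0);
    diag.resize(n); rhs.resize(n); cp.resize(n); dp.resize(n);
  }

  // Advance one step. g_syn_extra: absolute extra conductance (mS) per
  // segment with reversal e_syn; i_inj: constant injected current (uA).
  void step(const GateTables &gt,
            const std::vector<double> &g_syn_extra, double e_syn,
            const std::vector<double> &i_inj) {
    // gating update from present V
    if (active) for (int i = 0; i < n; ++i) gt.update(V[i], m[i], h[i], nn[i]);
    // assemble tridiagonal CN system
    for (int i = 0; i < n; ++i) {
      double gm = gl[i];
      double b = gl[i] * el;
      if (active) {
        double m3h = m[i] * m[i] * m[i] * h[i];
        double n4 = nn[i] * nn[i]; n4 *= n4;
        gm += gna[i] * m3h + gk[i] * n4;
        b += gna[i] * m3h * ena + gk[i] * n4 * ek;
      }
      double gs = g_syn_extra.empty() ? 0.0 : g_syn_extra[i];
      gm += gs;
      b += gs * e_syn;
      double gleft = (i > 0) ? gax[i - 1] : 0.0;
      double gright = (i < n - 1) ? gax[i] : 0.0;
      double gtot = gm + gleft + gright;
      diag[i] = cdt[i] + 0.5 * gtot;
      rhs[i] = (cdt[i] - 0.5 * gtot) * V[i] + b + i_inj[i];
      if (i > 0) rhs[i] += 0.5 * gleft * V[i - 1];
      if (i < n - 1) rhs[i] += 0.5 * gright * V[i + 1];
    }
    // Thomas algorithm; off-diagonals are -0.5 * gax
    if (n == 1) { V[0] = rhs[0] / diag[0]; return; }
    double inv = 1.0 / diag[0];
    cp[0] = -0.5 * gax[0] * inv;
    dp[0] = rhs[0] * inv;
    for (int i = 1; i < n; ++i) {
      double off = -0.5 * gax[i - 1];
      inv = 1.0 / (diag[i] - off * cp[i - 1]);
      cp[i] = (i < n - 1) ? (-0.5 * gax[i] * inv) : 0.0;
      dp[i] = (rhs[i] - off * dp[i - 1]) * inv;
    }
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];
  }

  bool finite() const {
    for (int i = 0; i < n; ++i) if (!std::isfinite(V[i])) return false;
    return true;
  }
  int first_bad() const {
    for (int i = 0; i < n; ++i) if (!std::isfinite(V[i])) return i;
    return -1;
  }

  // transmembrane current (outward, uA) = net axial inflow
  void membrane_current(std::vector<double> &im) const {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      if (i > 0) s += gax[i - 1] * (V[i - 1] - V[i]);
      if (i < n - 1) s += gax[i] * (V[i + 1] - V[i]);
      im[i] = s;
    }
  }
};

static void init_gating_steady(Cable &c, double vt) {
  for (int i = 0; i < c.n; ++i) {
    Rates r = hh_rates(c.V[i], vt);
    c.m[i] = r.am / (r.am + r.bm);
    c.h[i] = r.ah / (r.ah + r.bh);
    c.nn[i] = r.an / (r.an + r.bn);
  }
}

// Upward threshold-crossing spike detector with refractory period and
// sub-dt linear interpolation of the crossing time.
struct SpikeDetector {
  double prev_v, last_t, threshold, refractory;
  std::vector<double> times;
  void reset(double v, double thr, double refr) {
    prev_v = v; last_t = -1e18; threshold = thr; refractory = refr;
    times.clear();
  }
  // v: voltage at time t (end of step); returns true if a spike was recorded
  bool update(double v, double t, double dt) {
    bool fired = false;
    if (prev_v < threshold && v >= threshold) {
      double tc = t - dt + dt * (threshold - prev_v) / (v - prev_v);
      if (tc - last_t > refractory) {
        times.push_back(tc);
        last_t = tc;
        fired = true;
      }
    }
    prev_v = v;
    return fired;
  }
};

// Two-exponential state of a beta-function conductance population at one
// segment: G(t) = norm * (A - B), A += w, B += w per event, A,B decay with
// tau1, tau2. Midpoint evaluation for Crank-Nicolson.
struct BetaSyn {
  double A = 0.0, B = 0.0;
  double dec1, dec2, half1, half2, norm;
  void init(double tau1, double tau2, double dt) {
    dec1 = std::exp(-dt / tau1);
    dec2 = std::exp(-dt / tau2);
    half1 = std::exp(-0.5 * dt / tau1);
    half2 = std::exp(-0.5 * dt / tau2);
    double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
    norm = 1.0 / (std::exp(-tp / tau1) - std::exp(-tp / tau2));
    A = B = 0.0;
  }
  inline void add(double w) { A += w; B += w; }
  inline double g_mid() const { return norm * (A * half1 - B * half2); }
  inline void decay() { A *= dec1; B *= dec2; }
};

// [[Rcpp::export]]
List run_cable_cpp(NumericVector area, NumericVector gax, List mem,
                   double dt, int n_steps, NumericVector i_inj_nA,
                   double v0, bool active,
                   IntegerVector record_segs, int record_every) {
  GateTables gt;
  double vt = as<double>(mem["vt"]);
  gt.build(dt, as<double>(mem["phi"]), vt);
  Cable c;
  c.init(area, gax, as<double>(mem["cm"]), as<double>(mem["gna"]),
         as<double>(mem["gk"]), as<double>(mem["gl"]), as<double>(mem["ena"]),
         as<double>(mem["ek"]), as<double>(mem["el"]), dt, active);
  for (int i = 0; i < c.n; ++i) c.V[i] = v0;
  init_gating_steady(c, vt);

  std::vector<double> i_inj(c.n);
  for (int i = 0; i < c.n; ++i) i_inj[i] = i_inj_nA[i] * 1e-3; // nA -> uA
  std::vector<double> g_syn; // empty: none

  int n_rec = 1 + n_steps / record_every;
  NumericMatrix traces(record_segs.size(), n_rec);
  NumericVector tvec(n_rec);
  int col = 0;
  for (int s = 0; s <= n_steps; ++s) {
    if (s % record_every == 0) {
      for (int j = 0; j < record_segs.size(); ++j)
        traces(j, col) = c.V[record_segs[j]];
      tvec[col] = s * dt;
      ++col;
    }
    if (s == n_steps) break;
    c.step(gt, g_syn, 0.0, i_inj);
    if (!c.finite())
      stop("numerical instability at step %d, segment %d", s, c.first_bad());
  }
  NumericVector vfin(c.n), mv(c.n), hv(c.n), nv(c.n);
  for (int i = 0; i < c.n; ++i) {
    vfin[i] = c.V[i]; mv[i] = c.m[i]; hv[i] = c.h[i]; nv[i] = c.nn[i];
  }
  return List::create(_["t"] = tvec, _["v"] = traces, _["v_final"] = vfin,
                      _["m"] = mv, _["h"] = hv, _["n"] = nv);
}

// [[Rcpp::export]]
List run_pair_cpp(List geom_pre, List geom_post, List mem, double dt,
                  int settle_steps, int n_steps,
                  IntegerVector spont_pre_step, NumericVector spont_pre_w,
                  IntegerVector spont_post_step, NumericVector spont_post_w,
                  double spont_tau1, double spont_tau2, double spont_e,
                  int spont_seg,
                  int trigger_seg, int target_seg,
                  double ampa_tau1, double ampa_tau2, NumericVector ampa_w,
                  double nmda_tau1, double nmda_tau2, NumericVector nmda_w,
                  double syn_e, double threshold, double refractory,
                  IntegerMatrix sites, bool record_sites_v, bool record_phi,
                  NumericMatrix phi_w_pre, NumericMatrix phi_w_post) {
  GateTables gt;
  double vt = as<double>(mem["vt"]);
  gt.build(dt, as<double>(mem["phi"]), vt);

  Cable pre, post;
  double cm = as<double>(mem["cm"]);
  pre.init(geom_pre["area"], geom_pre["gax"], cm, as<double>(mem["gna"]),
           as<double>(mem["gk"]), as<double>(mem["gl"]), as<double>(mem["ena"]),
           as<double>(mem["ek"]), as<double>(mem["el"]), dt, true);
  post.init(geom_post["area"], geom_post["gax"], cm, as<double>(mem["gna"]),
            as<double>(mem["gk"]), as<double>(mem["gl"]), as<double>(mem["ena"]),
            as<double>(mem["ek"]), as<double>(mem["el"]), dt, true);
  double v0 = as<double>(mem["el"]);
  for (int i = 0; i < pre.n; ++i) pre.V[i] = v0;
  for (int i = 0; i < post.n; ++i) post.V[i] = v0;
  init_gating_steady(pre, vt);
  init_gating_steady(post, vt);

  std::vector<double> zero_pre(pre.n, 0.0), zero_post(post.n, 0.0);
  std::vector<double> g_pre(pre.n, 0.0), g_post(post.n, 0.0);

  // silent settling: no inputs
  for (int s = 0; s < settle_steps; ++s) {
    pre.step(gt, zero_pre, 0.0, zero_pre);
    post.step(gt, zero_post, 0.0, zero_post);
  }

  BetaSyn sp_pre, sp_post, ampa, nmda;
  sp_pre.init(spont_tau1, spont_tau2, dt);
  sp_post.init(spont_tau1, spont_tau2, dt);
  ampa.init(ampa_tau1, ampa_tau2, dt);
  nmda.init(nmda_tau1, nmda_tau2, dt);

  int n_sites = sites.nrow();
  std::vector<SpikeDetector> det(n_sites);
  for (int j = 0; j < n_sites; ++j) {
    const Cable &c = sites(j, 0) == 0 ? pre : post;
    det[j].reset(c.V[sites(j, 1)], threshold, refractory);
  }
  SpikeDetector trig;
  trig.reset(pre.V[trigger_seg], threshold, refractory);

  std::vector<double> syn_times;
  R_xlen_t i_sp_pre = 0, i_sp_post = 0;
  R_xlen_t i_ampa = 0, i_nmda = 0;

  NumericMatrix v_sites, phi;
  int n_elec = phi_w_pre.nrow();
  if (record_sites_v) v_sites = NumericMatrix(n_sites, n_steps + 1);
  if (record_phi) phi = NumericMatrix(n_elec, n_steps + 1);
  std::vector<double> im_pre(pre.n), im_post(post.n);

  auto snapshot = [&](int col) {
    if (record_sites_v)
      for (int j = 0; j < n_sites; ++j)
        v_sites(j, col) = (sites(j, 0) == 0 ? pre : post).V[sites(j, 1)];
    if (record_phi) {
      pre.membrane_current(im_pre);
      post.membrane_current(im_post);
      for (int e = 0; e < n_elec; ++e) {
        double s = 0.0;
        for (int i = 0; i < pre.n; ++i) s += phi_w_pre(e, i) * im_pre[i] * 1e3;
        for (int i = 0; i < post.n; ++i) s += phi_w_post(e, i) * im_post[i] * 1e3;
        phi(e, col) = s;
      }
    }
  };
  snapshot(0);

  bool valid = true;
  int bad_step = -1, bad_seg = -1, bad_neuron = -1;

  for (int s = 0; s < n_steps; ++s) {
    // spontaneous events scheduled for this step
    while (i_sp_pre < spont_pre_step.size() && spont_pre_step[i_sp_pre] == s) {
      sp_pre.add(spont_pre_w[i_sp_pre]); ++i_sp_pre;
    }
    while (i_sp_post < spont_post_step.size() && spont_post_step[i_sp_post] == s) {
      sp_post.add(spont_post_w[i_sp_post]); ++i_sp_post;
    }
    // conductances at step midpoint (uS -> mS); spont and pair synapse may
    // target the same postsynaptic segment, so accumulate
    g_pre[spont_seg] = sp_pre.g_mid() * 1e-3;
    g_post[spont_seg] = 0.0;
    g_post[target_seg] = 0.0;
    g_post[spont_seg] += sp_post.g_mid() * 1e-3;
    g_post[target_seg] += (ampa.g_mid() + nmda.g_mid()) * 1e-3;

    pre.step(gt, g_pre, spont_e, zero_pre);
    // spontaneous and pair synapse share reversal 0 mV, so one extra-
    // conductance pass suffices for the postsynaptic cable
    post.step(gt, g_post, syn_e, zero_post);

    sp_pre.decay(); sp_post.decay(); ampa.decay(); nmda.decay();

    double t = (s + 1) * dt;
    if (!pre.finite() || !post.finite()) {
      valid = false; bad_step = s;
      bad_neuron = pre.finite() ? 1 : 0;
      bad_seg = pre.finite() ? post.first_bad() : pre.first_bad();
      break;
    }
    for (int j = 0; j < n_sites; ++j)
      det[j].update((sites(j, 0) == 0 ? pre : post).V[sites(j, 1)], t, dt);
    // synaptic transmission: presynaptic segment nearest z_syn crosses
    // threshold -> both components activate with fresh weights, zero delay
    if (trig.update(pre.V[trigger_seg], t, dt)) {
      if (i_ampa >= ampa_w.size() || i_nmda >= nmda_w.size())
        stop("synaptic weight pool exhausted");
      ampa.add(ampa_w[i_ampa]); ++i_ampa;
      nmda.add(nmda_w[i_nmda]); ++i_nmda;
      syn_times.push_back(trig.last_t);
    }
    snapshot(s + 1);
  }

  List spikes(n_sites);
  for (int j = 0; j < n_sites; ++j) spikes[j] = wrap(det[j].times);
  List out = List::create(
      _["spikes"] = spikes, _["syn_times"] = wrap(syn_times),
      _["valid"] = valid, _["bad_step"] = bad_step, _["bad_seg"] = bad_seg,
      _["bad_neuron"] = bad_neuron,
      _["n_ampa_used"] = (double)i_ampa);
  if (record_sites_v) out["v_sites"] = v_sites;
  if (record_phi) out["phi"] = phi;
  return out;
}

// Plug-in transfer entropy helpers operate on integer state codes built in R;
// kept in R for clarity (vectorized tabulate is fast enough).
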