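// Plug-in transfer-entropy kernels on binary series. State codes combine the
// target's k past bins, one past bin per conditioning series, one source bin
// at lag delta, and the present target bin; TE is the conditional mutual
// information of the empirical joint frequencies, in bits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double cmi_from_codes(const std::vector<int> &xt,
                             const std::vector<int> &ys,
                             const std::vector<int> &past, int n_past) {
  const int n = (int)xt.size();
  std::vector<double> cnt(4 * (size_t)n_past, 0.0);
  for (int i = 0; i < n; ++i)
    cnt[4 * (size_t)past[i] + 2 * ys[i] + xt[i]] += 1.0;
  double te = 0.0;
  for (int z = 0; z < n_past; ++z) {
    const double *c = &cnt[4 * (size_t)z];
    double cx0 = c[0] + c[2], cx1 = c[1] + c[3];
    double cy0 = c[0] + c[1], cy1 = c[2] + c[3];
    double cz = cx0 + cx1;
    if (cz == 0) continue;
    const double cx[2] = {cx0, cx1}, cy[2] = {cy0, cy1};
    for (int y = 0; y < 2; ++y)
      for (int x = 0; x < 2; ++x) {
        double cc = c[2 * y + x];
        if (cc > 0) te += cc * std::log2(cc * cz / (cx[x] * cy[y]));
      }
  }
  te /= n;
  return te > 0 ? te : 0.0;
}

static void build_codes(const IntegerVector &x, const IntegerVector &y,
                        int k, int delta, const IntegerMatrix &cond,
                        std::vector<int> &xt, std::vector<int> &ys,
                        std::vector<int> &past, int &n_past) {
  const int n = x.size();
  const int k0 = std::max(k, delta);
  const int m = n - k0;
  const int nc = cond.ncol();
  xt.resize(m); ys.resize(m); past.resize(m);
  for (int i = 0; i < m; ++i) {
    int t = k0 + i;
    xt[i] = x[t];
    ys[i] = y[t - delta];
    int p = 0;
    for (int j = 1; j <= k; ++j) p = (p << 1) | x[t - j];
    for (int c = 0; c < nc; ++c) p = (p << 1) | cond(t - 1, c);
    past[i] = p;
  }
  n_past = 1 << (k + nc);
}

// [[Rcpp::export]]
double te_core_cpp(IntegerVector x, IntegerVector y, int k, int delta,
                   IntegerMatrix cond) {
  std::vector<int> xt, ys, past;
  int n_past;
  build_codes(x, y, k, delta, cond, xt, ys, past, n_past);
  return cmi_from_codes(xt, ys, past, n_past);
}

// TE for circularly shifted sources; xt/past are shift-invariant.
// [[Rcpp::export]]
NumericVector te_surrogates_cpp(IntegerVector x, IntegerVector y, int k,
                                int delta, IntegerMatrix cond,
                                IntegerVector shifts) {
  const int n = x.size();
  std::vector<int> xt, ys, past;
  int n_past;
  build_codes(x, y, k, delta, cond, xt, ys, past, n_past);
  const int k0 = std::max(k, delta);
  const int m = n - k0;
  NumericVector out(shifts.size());
  std::vector<int> ysh(m);
  for (int s = 0; s < shifts.size(); ++s) {
    int sh = shifts[s];
    for (int i = 0; i < m; ++i) {
      int t = k0 + i - delta + sh;
      if (t >= n) t -= n;
      ysh[i] = y[t];
    }
    out[s] = cmi_from_codes(xt, ysh, past, n_past);
  }
  return out;
}

// Exhaustive (delta, k) scan; ties resolved to smallest delta, then k.
// [[Rcpp::export]]
List te_scan_cpp(IntegerVector x, IntegerVector y, int tau_source, int kmax) {
  IntegerMatrix cond(x.size(), 0);
  double best = -1.0;
  int bd = NA_INTEGER, bk = NA_INTEGER;
  for (int delta = 1; delta <= tau_source; ++delta)
    for (int k = 1; k <= kmax; ++k) {
      double te = te_core_cpp(x, y, k, delta, cond);
      if (te > best + 1e-12) { best = te; bd = delta; bk = k; }
    }
  return List::create(_["delta_star"] = bd, _["k_star"] = bk, _["te"] = best);
}

// Scan over (delta in delta_set) x (k in 1..kmax) with a maximum-statistic
// surrogate test: every circular-shift surrogate undergoes the same scan,
// and its maximal TE forms the null distribution of the observed maximum.
// A common embedding start (max of all k and deltas) keeps the sample set
// identical across candidates, so the maxima are exchangeable.
// [[Rcpp::export]]
List te_scan_max_perm_cpp(IntegerVector x, IntegerVector y,
                          IntegerMatrix cond, IntegerVector delta_set,
                          int kmax, IntegerVector shifts) {
  const int n = x.size();
  const int nc = cond.ncol();
  const int ns = shifts.size();
  int dmax = 1;
  for (int i = 0; i < delta_set.size(); ++i)
    if (delta_set[i] > dmax) dmax = delta_set[i];
  const int k0 = std::max(kmax, dmax);
  const int m = n - k0;
  if (m < 2) stop("series too short for embedding");

  NumericVector surro_max(ns, 0.0);
  double best = -1.0;
  int bd = NA_INTEGER, bk = NA_INTEGER;
  std::vector<int> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  // shift-invariant 4*past + xt codes, one array per history length
  std::vector<std::vector<int> > px(kmax + 1);
  for (int k = 1; k <= kmax; ++k) {
    px[k].resize(m);
    for (int i = 0; i < m; ++i) {
      int t = k0 + i;
      int p = 0;
      for (int j = 1; j <= k; ++j) p = (p << 1) | vx[t - j];
      for (int c = 0; c < nc; ++c) p = (p << 1) | cond(t - 1, c);
      px[k][i] = 4 * p + vx[t];
    }
  }
  // positions of the source's occupied bins: only they perturb the
  // baseline (all-y-zero) counts, so each evaluation costs O(#ones)
  std::vector<int> oy;
  for (int t = 0; t < n; ++t) if (vy[t]) oy.push_back(t);
  std::vector<double> cnt0(4 * ((size_t)1 << (kmax + nc)), 0.0);
  std::vector<double> cnt(4 * ((size_t)1 << (kmax + nc)), 0.0);

  // delta outer, k inner: strict-improvement updates realize the
  // smallest-delta-then-smallest-k tie rule
  for (int di = 0; di < delta_set.size(); ++di) {
    const int delta = delta_set[di];
    for (int k = 1; k <= kmax; ++k) {
      const int n_past = 1 << (k + nc);
      const int *pxk = px[k].data();
      std::fill(cnt0.begin(), cnt0.begin() + 4 * (size_t)n_past, 0.0);
      for (int i = 0; i < m; ++i) cnt0[(size_t)pxk[i]] += 1.0;
      for (int s = -1; s < ns; ++s) {
        std::copy(cnt0.begin(), cnt0.begin() + 4 * (size_t)n_past,
                  cnt.begin());
        const int sh = (s < 0) ? 0 : shifts[s];
        const int base = k0 - delta + sh;
        for (size_t q = 0; q < oy.size(); ++q) {
          int i = oy[q] - base;
          if (i < 0) i += n;
          if (i < m) {
            cnt[(size_t)pxk[i]] -= 1.0;
            cnt[(size_t)pxk[i] + 2] += 1.0;
          }
        }
        // conditional MI from counts (x fastest, then y, then past)
        double te = 0.0;
        for (int z = 0; z < n_past; ++z) {
          const double *c = &cnt[4 * (size_t)z];
          double cx0 = c[0] + c[2], cx1 = c[1] + c[3];
          double cy0 = c[0] + c[1], cy1 = c[2] + c[3];
          double cz = cx0 + cx1;
          if (cz == 0) continue;
          const double cx[2] = {cx0, cx1}, cy[2] = {cy0, cy1};
          for (int yy = 0; yy < 2; ++yy)
            for (int xx = 0; xx < 2; ++xx) {
              double cc = c[2 * yy + xx];
              if (cc > 0) te += cc * std::log2(cc * cz / (cx[xx] * cy[yy]));
            }
        }
        te /= m;
        if (te < 0) te = 0;
        if (s < 0) {
          if (te > best + 1e-12) { best = te; bd = delta; bk = k; }
        } else if (te > surro_max[s]) {
          surro_max[s] = te;
        }
      }
    }
  }
  return List::create(_["delta_star"] = bd, _["k_star"] = bk, _["te"] = best,
                      _["surrogate_max"] = surro_max);
}
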