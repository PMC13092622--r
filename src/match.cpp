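// Order-preserving one-to-one spike matching between an upstream and a
// downstream detection site: maximize the number of forward-in-time pairs
// with latency in (0, max_latency], and among maximal matchings minimize
// the total latency. Dynamic program over the two sorted trains with a
// byte-sized parent table for path reconstruction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix match_spikes_cpp(NumericVector a, NumericVector b,
                               double max_latency) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return IntegerMatrix(0, 2);
  // parent: 0 = skip a_i, 1 = skip b_j, 2 = match (i, j)
  std::vector<unsigned char> par((size_t)n * m);
  std::vector<int> cnt_next(m + 1, 0), cnt_cur(m + 1, 0);
  std::vector<double> lat_next(m + 1, 0.0), lat_cur(m + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    cnt_cur[m] = 0; lat_cur[m] = 0.0;
    for (int j = m - 1; j >= 0; --j) {
      // skip a_i
      int bc = cnt_next[j];
      double bl = lat_next[j];
      unsigned char bp = 0;
      // skip b_j
      if (cnt_cur[j + 1] > bc ||
          (cnt_cur[j + 1] == bc && lat_cur[j + 1] < bl)) {
        bc = cnt_cur[j + 1]; bl = lat_cur[j + 1]; bp = 1;
      }
      double d = b[j] - a[i];
      if (d > 0 && d <= max_latency) {
        int mc = 1 + cnt_next[j + 1];
        double ml = d + lat_next[j + 1];
        if (mc > bc || (mc == bc && ml < bl)) { bc = mc; bl = ml; bp = 2; }
      }
      cnt_cur[j] = bc; lat_cur[j] = bl;
      par[(size_t)i * m + j] = bp;
    }
    std::swap(cnt_cur, cnt_next);
    std::swap(lat_cur, lat_next);
  }
  // reconstruct from (0, 0); values for row 0 ended in *_next after swap
  std::vector<int> ia, jb;
  int i = 0, j = 0;
  while (i < n && j < m) {
    unsigned char p = par[(size_t)i * m + j];
    if (p == 2) { ia.push_back(i + 1); jb.push_back(j + 1); ++i; ++j; }
    else if (p == 0) ++i;
    else ++j;
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t r = 0; r < ia.size(); ++r) { out(r, 0) = ia[r]; out(r, 1) = jb[r]; }
  return out;
}
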