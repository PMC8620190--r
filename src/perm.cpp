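#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// CMI permutation count
//
// Under permutation of f, S(f) and n are constant, so
//   CMI = S(v,f) + S(w,f) - S(v,w,f) - S(f)
// is monotone in -(A + B - C) where A, B, C are the sum(c*log c) statistics
// of the (v,f), (w,f) and (v,w,f) contingency tables. Comparing those sums
// avoids recomputing entropies (and any std::log) inside the loop: a
// precomputed k*log(k) table covers all attainable counts.
// ---------------------------------------------------------------------------

namespace {

struct SparseTable {
  std::vector<int> counts;
  std::vector<int> touched;
  explicit SparseTable(int size) : counts(size, 0) { touched.reserve(256); }
  inline void add(int idx) {
    if (counts[idx]++ == 0) touched.push_back(idx);
  }
  // sum of c*log(c) over occupied cells, then reset
  inline double clogc_and_reset(const std::vector<double>& lg) {
    double s = 0.0;
    for (size_t k = 0; k < touched.size(); ++k) {
      int idx = touched[k];
      s += lg[counts[idx]];
      counts[idx] = 0;
    }
    touched.clear();
    return s;
  }
};

inline double clogc_sums(const std::vector<int>& v, const std::vector<int>& w,
                         const std::vector<int>& f, int nv, int nw,
                         SparseTable& tvf, SparseTable& twf, SparseTable& tvwf,
                         const std::vector<double>& lg) {
  const int n = (int)v.size();
  for (int t = 0; t < n; ++t) {
    tvf.add(v[t] + nv * f[t]);
    twf.add(w[t] + nw * f[t]);
    tvwf.add(v[t] + nv * (w[t] + nw * f[t]));
  }
  double A = tvf.clogc_and_reset(lg);
  double B = twf.clogc_and_reset(lg);
  double C = tvwf.clogc_and_reset(lg);
  return A + B - C;
}

} // namespace

// Count how many of `iterations` uniform random permutations of f give a
// CMI at least as small as (<=) the CMI of the unpermuted labels. Uses R's
// RNG (deterministic under set.seed).
// [[Rcpp::export]]
int cmi_perm_count_cpp(IntegerVector vb, IntegerVector wb, IntegerVector fb,
                       int iterations) {
  const int n = vb.size();
  if (wb.size() != n || fb.size() != n)
    stop("label vectors differ in length");
  std::vector<int> v(vb.begin(), vb.end());
  std::vector<int> w(wb.begin(), wb.end());
  std::vector<int> f(fb.begin(), fb.end());
  int nv = 0, nw = 0, nf = 0;
  for (int t = 0; t < n; ++t) {
    if (v[t] < 0 || w[t] < 0 || f[t] < 0) stop("negative bin label");
    nv = std::max(nv, v[t] + 1);
    nw = std::max(nw, w[t] + 1);
    nf = std::max(nf, f[t] + 1);
  }
  std::vector<double> lg(n + 1);
  lg[0] = 0.0;
  for (int k = 1; k <= n; ++k) lg[k] = k * std::log((double)k);
  SparseTable tvf(nv * nf), twf(nw * nf), tvwf(nv * nw * nf);
  // larger D  <=>  smaller CMI
  double d_obs = clogc_sums(v, w, f, nv, nw, tvf, twf, tvwf, lg);
  RNGScope scope;
  int count = 0;
  std::vector<int> fp(f);
  for (int it = 0; it < iterations; ++it) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(fp[i], fp[j]);
    }
    double d_i = clogc_sums(v, w, fp, nv, nw, tvf, twf, tvwf, lg);
    if (d_i >= d_obs - 1e-9) count++;
  }
  return count;
}

// ---------------------------------------------------------------------------
// Local similarity
// ---------------------------------------------------------------------------

// Largest |window sum| over all contiguous windows of x[t]*y[t] (Kadane on
// the pointwise product, fused into one pass; no sign/window bookkeeping).
static inline double max_abs_window_sum(const double* x, const double* y,
                                        int n) {
  double z = x[0] * y[0];
  double cur_max = z, best_max = z, cur_min = z, best_min = z;
  for (int t = 1; t < n; ++t) {
    z = x[t] * y[t];
    double em = cur_max + z;
    cur_max = em > z ? em : z;
    if (cur_max > best_max) best_max = cur_max;
    double en = cur_min + z;
    cur_min = en < z ? en : z;
    if (cur_min < best_min) best_min = cur_min;
  }
  return best_max > -best_min ? best_max : -best_min;
}

// Zero-delay local-similarity score of two (standardized) series: over all
// contiguous windows [i, j], maximize |sum_t x_t * y_t| / n. Ties are
// broken by earliest start, then longest duration, then positive sign.
// [[Rcpp::export]]
List local_similarity_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("series differ in length");
  if (n < 1) stop("empty series");
  double best = -1.0;
  int best_start = 0, best_dur = 1, best_sign = 1;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = i; j < n; ++j) {
      s += x[j] * y[j];
      double a = std::fabs(s);
      int dur = j - i + 1;
      int sgn = s >= 0 ? 1 : -1;
      bool better = a > best;
      if (!better && a == best) {
        if (i < best_start) better = true;
        else if (i == best_start && dur > best_dur) better = true;
        else if (i == best_start && dur == best_dur && sgn > best_sign)
          better = true;
      }
      if (better) {
        best = a; best_start = i; best_dur = dur; best_sign = sgn;
      }
    }
  }
  return List::create(_["score"] = best / n,
                      _["sign"] = best_sign > 0 ? "+" : "-",
                      _["start"] = best_start,
                      _["duration"] = best_dur);
}

// Count permutations of y whose local-similarity score reaches the observed
// score. The observed score is recomputed here with the same fused Kadane
// recursion used for the permuted series so ties compare identical
// arithmetic. When stop_after >= 0, counting aborts once the count exceeds
// stop_after (the p-value is then only a lower bound, enough to reject
// significance); stop_after < 0 counts exactly.
// [[Rcpp::export]]
int ls_perm_count_cpp(NumericVector x, NumericVector y, int permutations,
                      int stop_after = -1) {
  const int n = x.size();
  if (y.size() != n) stop("series differ in length");
  const double* xp = REAL(x);
  std::vector<double> yp(y.begin(), y.end());
  double obs = max_abs_window_sum(xp, &yp[0], n);
  RNGScope scope;
  int count = 0;
  for (int it = 0; it < permutations; ++it) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    if (max_abs_window_sum(xp, &yp[0], n) >= obs - 1e-12) {
      count++;
      if (stop_after >= 0 && count > stop_after) return count;
    }
  }
  return count;
}
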