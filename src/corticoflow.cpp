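#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Sliding-window percentile with a centered window truncated at the trace
// edges. Uses two multisets partitioned at the target order statistic so each
// step is O(log W). The interpolation formula mirrors stats::quantile type 7
// bit-for-bit: (1 - h) * x[k] + h * x[k + 1] on the sorted window.
// [[Rcpp::export]]
NumericVector running_percentile_cpp(NumericVector x, int halfwidth, double p) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::multiset<double> lo, hi;  // lo holds the (k + 1) smallest elements

  auto ins = [&](double v) {
    if (!lo.empty() && v <= *lo.rbegin()) lo.insert(v); else hi.insert(v);
  };
  auto del = [&](double v) {
    std::multiset<double>::iterator it = lo.find(v);
    if (it != lo.end()) lo.erase(it);
    else hi.erase(hi.find(v));
  };
  auto rebalance = [&](size_t target) {
    while (lo.size() > target) {
      std::multiset<double>::iterator it = std::prev(lo.end());
      hi.insert(*it); lo.erase(it);
    }
    while (lo.size() < target) {
      std::multiset<double>::iterator it = hi.begin();
      lo.insert(*it); hi.erase(it);
    }
  };

  int a = 0, b = std::min(n - 1, halfwidth);
  for (int i = a; i <= b; ++i) ins(x[i]);
  for (int i = 0; i < n; ++i) {
    const int na = std::max(0, i - halfwidth);
    const int nb = std::min(n - 1, i + halfwidth);
    while (b < nb) { ++b; ins(x[b]); }
    while (a < na) { del(x[a]); ++a; }
    const int m = b - a + 1;
    // mirror stats::quantile type 7 arithmetic bit-for-bit
    const double index = 1.0 + p * (m - 1);
    const int lo1 = (int)std::floor(index);
    const double h = index - lo1;
    rebalance((size_t)lo1);
    double val = *lo.rbegin();
    if (index > lo1 && !hi.empty()) {
      const double nxt = *hi.begin();
      if (nxt != val) val = (1.0 - h) * val + h * nxt;
    }
    out[i] = val;
  }
  return out;
}

static inline int draw_index(int n) {
  int i = (int)(unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

// Two-stage hierarchical bootstrap of the pooled mean. Values are pre-grouped
// into level-2 units (sums and counts); units of one mouse are contiguous.
// Each replicate resamples M mice with replacement, then within each selected
// mouse resamples its own number of units with replacement, and returns the
// mean of the pooled resampled values.
// [[Rcpp::export]]
NumericVector hboot_means_cpp(NumericVector unit_sums, IntegerVector unit_counts,
                              IntegerVector mouse_start, IntegerVector mouse_n_units,
                              int n_boot) {
  const int M = mouse_start.size();
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    double acc = 0.0, cnt = 0.0;
    for (int j = 0; j < M; ++j) {
      const int mi = draw_index(M);
      const int s = mouse_start[mi], nu = mouse_n_units[mi];
      for (int u = 0; u < nu; ++u) {
        const int ui = s + draw_index(nu);
        acc += unit_sums[ui];
        cnt += unit_counts[ui];
      }
    }
    out[b] = acc / cnt;
  }
  return out;
}

// Hierarchical bootstrap of per-bin means with resampling indices shared
// across bins within one replicate, so the per-bin bands stay trace-coherent.
// vals: units x bins matrix (one row per level-2 unit, e.g. one onset).
// [[Rcpp::export]]
NumericMatrix hboot_matrix_cpp(NumericMatrix vals, IntegerVector mouse_start,
                               IntegerVector mouse_n_units, int n_boot) {
  const int M = mouse_start.size();
  const int nb = vals.ncol();
  NumericMatrix out(n_boot, nb);
  std::vector<int> sel;
  for (int b = 0; b < n_boot; ++b) {
    sel.clear();
    for (int j = 0; j < M; ++j) {
      const int mi = draw_index(M);
      const int s = mouse_start[mi], nu = mouse_n_units[mi];
      for (int u = 0; u < nu; ++u) sel.push_back(s + draw_index(nu));
    }
    const double inv = 1.0 / (double)sel.size();
    for (int c = 0; c < nb; ++c) {
      double acc = 0.0;
      for (size_t r = 0; r < sel.size(); ++r) acc += vals(sel[r], c);
      out(b, c) = acc * inv;
    }
  }
  return out;
}
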