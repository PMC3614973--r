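#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Delay embedding of one series: row t holds x[t + k*lag], k = 0..m-1.
// Kept in a flat row-major buffer for cache-friendly distance loops.
static void embed_series(const double* x, int n, int m, int lag,
                         std::vector<double>& out, int& n_emb) {
  n_emb = n - (m - 1) * lag;
  out.resize((size_t)n_emb * m);
  for (int t = 0; t < n_emb; ++t)
    for (int k = 0; k < m; ++k)
      out[(size_t)t * m + k] = x[t + k * lag];
}

static inline double sqdist(const double* a, const double* b, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = a[k] - b[k];
    s += d * d;
  }
  return s;
}

// Eligible neighbours of reference i: indices j with w1 < |i-j| <= w2.
static void eligible_idx(int i, int n_emb, int w1, int w2,
                         std::vector<int>& idx) {
  idx.clear();
  int lo1 = std::max(0, i - w2), hi1 = i - w1 - 1;
  for (int j = lo1; j <= hi1; ++j) idx.push_back(j);
  int lo2 = i + w1 + 1, hi2 = std::min(n_emb - 1, i + w2);
  for (int j = lo2; j <= hi2; ++j) idx.push_back(j);
}

// Critical distance per reference time: the k-th smallest squared distance
// among eligible neighbours, k = max(1, round(p_ref * n_eligible)), so the
// achieved recurrence fraction is the nearest achievable to p_ref (ties at
// the cutoff are included by the <= rule downstream).
// [[Rcpp::export]]
NumericVector critical_distance_cpp(NumericMatrix embedded, double p_ref,
                                    int w1, int w2) {
  int n_emb = embedded.nrow(), m = embedded.ncol();
  // copy into row-major
  std::vector<double> E((size_t)n_emb * m);
  for (int t = 0; t < n_emb; ++t)
    for (int k = 0; k < m; ++k)
      E[(size_t)t * m + k] = embedded(t, k);
  NumericVector eps(n_emb);
  std::vector<int> idx;
  std::vector<double> d;
  int min_elig = (int)std::ceil(1.0 / p_ref);
  for (int i = 0; i < n_emb; ++i) {
    eligible_idx(i, n_emb, w1, w2, idx);
    if ((int)idx.size() < min_elig)
      stop("Reference %d has %d eligible neighbours; need at least %d for p_ref = %f",
           i + 1, (int)idx.size(), min_elig, p_ref);
    d.resize(idx.size());
    const double* ei = &E[(size_t)i * m];
    for (size_t q = 0; q < idx.size(); ++q)
      d[q] = sqdist(ei, &E[(size_t)idx[q] * m], m);
    int k = std::max(1, (int)std::lround(p_ref * (double)idx.size()));
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    eps[i] = std::sqrt(d[k - 1]);
  }
  return eps;
}

// Full synchronization-likelihood matrix for one epoch.
// For every channel: embed, calibrate eps_i per reference, record the
// recurrent neighbour set {j : dist(i,j) <= eps_i}. For a channel pair
// (x, y), SL(x|y-direction) = sum_i |Rx_i  ^  Ry_i| / sum_i |Rx_i| and the
// reported value is the mean of the two directions. Channels with zero
// variance saturate (all distances zero); they get SL 0 against everything
// and are flagged.
// [[Rcpp::export]]
List sl_epoch_cpp(NumericMatrix epoch, int m, int lag, int w1, int w2,
                  double p_ref) {
  int n_ch = epoch.nrow(), n = epoch.ncol();
  int n_emb = n - (m - 1) * lag;
  if (n_emb < 1)
    stop("Epoch of %d samples too short for m = %d, lag = %d (needs > %d).",
         n, m, lag, (m - 1) * lag);
  if (n_emb < w2 + 1)
    stop("Number of embedded vectors (%d) must exceed the outer window w2 = %d.",
         n_emb, w2);

  int min_elig = (int)std::ceil(1.0 / p_ref);
  std::vector<std::vector<std::vector<int> > > rec(n_ch);
  std::vector<bool> saturated(n_ch, false);
  std::vector<double> E;
  std::vector<int> idx;
  std::vector<double> d;
  std::vector<std::pair<double, int> > dj;

  for (int c = 0; c < n_ch; ++c) {
    // channel variance check
    double mu = 0.0, v = 0.0;
    for (int t = 0; t < n; ++t) mu += epoch(c, t);
    mu /= n;
    for (int t = 0; t < n; ++t) {
      double dv = epoch(c, t) - mu;
      v += dv * dv;
    }
    if (v == 0.0) {
      saturated[c] = true;
      continue;
    }
    std::vector<double> x(n);
    for (int t = 0; t < n; ++t) x[t] = epoch(c, t);
    int ne;
    embed_series(x.data(), n, m, lag, E, ne);
    rec[c].resize(ne);
    for (int i = 0; i < ne; ++i) {
      eligible_idx(i, ne, w1, w2, idx);
      if ((int)idx.size() < min_elig)
        stop("Reference %d has too few eligible neighbours for p_ref = %f",
             i + 1, p_ref);
      dj.resize(idx.size());
      const double* ei = &E[(size_t)i * m];
      for (size_t q = 0; q < idx.size(); ++q)
        dj[q] = std::make_pair(sqdist(ei, &E[(size_t)idx[q] * m], m), idx[q]);
      int k = std::max(1, (int)std::lround(p_ref * (double)idx.size()));
      std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.end());
      double eps2 = dj[k - 1].first;
      std::vector<int>& ri = rec[c][i];
      for (size_t q = 0; q < idx.size(); ++q)
        if (dj[q].first <= eps2) ri.push_back(dj[q].second);
      std::sort(ri.begin(), ri.end());
    }
  }

  NumericMatrix W(n_ch, n_ch);
  for (int a = 0; a < n_ch; ++a) {
    for (int b = a + 1; b < n_ch; ++b) {
      if (saturated[a] || saturated[b]) {
        W(a, b) = W(b, a) = 0.0;
        continue;
      }
      long long na = 0, nb = 0, nab = 0;
      int ne = (int)rec[a].size();
      for (int i = 0; i < ne; ++i) {
        const std::vector<int>& ra = rec[a][i];
        const std::vector<int>& rb = rec[b][i];
        na += (long long)ra.size();
        nb += (long long)rb.size();
        // sorted-list intersection
        size_t p = 0, q = 0;
        while (p < ra.size() && q < rb.size()) {
          if (ra[p] < rb[q]) ++p;
          else if (ra[p] > rb[q]) ++q;
          else { ++nab; ++p; ++q; }
        }
      }
      double sl_ab = na > 0 ? (double)nab / (double)na : 0.0;
      double sl_ba = nb > 0 ? (double)nab / (double)nb : 0.0;
      double sl = 0.5 * (sl_ab + sl_ba);
      if (sl < 0.0) sl = 0.0;
      if (sl > 1.0) sl = 1.0;
      W(a, b) = W(b, a) = sl;
    }
  }
  LogicalVector sat(n_ch);
  for (int c = 0; c < n_ch; ++c) sat[c] = saturated[c];
  return List::create(_["W"] = W, _["saturated"] = sat);
}
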