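#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in higher-order transfer entropy on 1-ms binned binary spike trains.
//
// TE_{j->i}(d) = sum p(i_{t+1}, i_t^{(k)}, j_{t+1-d}^{(l)})
//                log2 [ p(i_{t+1} | i_t^{(k)}, j_{t+1-d}^{(l)})
//                     / p(i_{t+1} | i_t^{(k)}) ]
// with probabilities taken as empirical word frequencies (no smoothing)
// and the 0 log 0 = 0 convention. Words are the k (l) most recent bins
// of i (j) ending at t (t+1-d).

static double te_from_counts(const std::vector<int> &cnt, int Ki, int Kj,
                             long N) {
  // cnt indexed by y + 2*(a + Ki*b): y = i_{t+1}, a = i-word, b = j-word
  std::vector<long> c_ab((size_t) Ki * Kj, 0);
  std::vector<long> c_ya((size_t) 2 * Ki, 0);
  std::vector<long> c_a(Ki, 0);
  for (int b = 0; b < Kj; ++b)
    for (int a = 0; a < Ki; ++a)
      for (int y = 0; y < 2; ++y) {
        const long c = cnt[y + 2 * (a + (long) Ki * b)];
        c_ab[a + (size_t) Ki * b] += c;
        c_ya[y + 2 * a] += c;
        c_a[a] += c;
      }
  double te = 0.0;
  for (int b = 0; b < Kj; ++b)
    for (int a = 0; a < Ki; ++a)
      for (int y = 0; y < 2; ++y) {
        const long c = cnt[y + 2 * (a + (long) Ki * b)];
        if (c == 0) continue;
        const double num = (double) c * (double) c_a[a];
        const double den = (double) c_ab[a + (size_t) Ki * b] *
                           (double) c_ya[y + 2 * a];
        te += ((double) c / N) * std::log2(num / den);
      }
  return te < 0.0 ? 0.0 : te;  // clip -0.0 / rounding dust
}

static void word_codes(const int *s, int T, int k, std::vector<int> &out) {
  // out[t] (0-based t, valid for t >= k-1) = code of s[t-k+1..t]
  const int mask = (1 << k) - 1;
  int code = 0;
  for (int t = 0; t < T; ++t) {
    code = ((code << 1) | s[t]) & mask;
    out[t] = code;
  }
}

// [[Rcpp::export]]
double transfer_entropy_cpp(IntegerVector si, IntegerVector sj,
                            int k, int l, int d) {
  const int T = si.size();
  const int Ki = 1 << k, Kj = 1 << l;
  std::vector<int> ik(T), jl(T);
  word_codes(&si[0], T, k, ik);
  word_codes(&sj[0], T, l, jl);
  // 1-based t runs max(k, d+l-1) .. T-1; 0-based index tt = t-1
  const int t0 = std::max(k, d + l - 1);
  if (t0 > T - 1) return NA_REAL;
  std::vector<int> cnt((size_t) 2 * Ki * Kj, 0);
  long N = 0;
  for (int t = t0; t <= T - 1; ++t) {
    const int y = si[t];              // i_{t+1} at 0-based index t
    const int a = ik[t - 1];          // i-word ending at t (1-based)
    const int b = jl[t - d];          // j-word ending at t+1-d
    cnt[y + 2 * (a + (long) Ki * b)]++;
    ++N;
  }
  return te_from_counts(cnt, Ki, Kj, N);
}

// [[Rcpp::export]]
List hote_matrix_cpp(IntegerMatrix binned, int k, int l, int d_max) {
  const int n = binned.nrow();
  const int T = binned.ncol();
  const int Ki = 1 << k, Kj = 1 << l;
  // per-neuron word codes for both orders
  std::vector< std::vector<int> > wk(n, std::vector<int>(T));
  std::vector< std::vector<int> > wl(n, std::vector<int>(T));
  std::vector< std::vector<int> > s(n, std::vector<int>(T));
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) s[i][t] = binned(i, t);
    word_codes(s[i].data(), T, k, wk[i]);
    if (l == k) wl[i] = wk[i]; else word_codes(s[i].data(), T, l, wl[i]);
  }
  NumericMatrix val(n, n);
  IntegerMatrix del(n, n);
  std::vector<int> cnt((size_t) 2 * Ki * Kj);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double best = -1.0; int bestd = 0;
      for (int d = 0; d <= d_max; ++d) {
        const int t0 = std::max(k, d + l - 1);
        if (t0 > T - 1) break;
        std::fill(cnt.begin(), cnt.end(), 0);
        long N = 0;
        const int *siv = s[i].data();
        const int *ikv = wk[i].data();
        const int *jlv = wl[j].data();
        for (int t = t0; t <= T - 1; ++t) {
          cnt[siv[t] + 2 * (ikv[t - 1] + (long) Ki * jlv[t - d])]++;
          ++N;
        }
        const double te = te_from_counts(cnt, Ki, Kj, N);
        if (te > best) { best = te; bestd = d; }  // ties -> smallest delay
      }
      val(i, j) = best;
      del(i, j) = bestd;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["values"] = val, _["best_delay"] = del);
}
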