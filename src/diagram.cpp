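#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Tie-broken total order on samples: lexicographic on (value, index).
// Realizes the infinitesimal perturbation f(i) + eps*i without touching data.
static inline bool key_lt(double fi, int i, double fj, int j) {
  return fi < fj || (fi == fj && i < j);
}

// 0-dimensional sublevel persistence of a discrete signal by the explicit
// extrema-ordering and pairing construction.  Sentinels f(0) = +Inf and
// f(n+1) = -Inf frame the signal; local minima/maxima are detected under the
// tie-broken order, sorted ascending by (value, index), and each maximum b_k
// (in ascending order) is paired with the largest-key unused minimum whose
// candidate predecessors do not sit strictly between the pair's positions.
// Indices in the output are 1-based positions into the input signal.
// [[Rcpp::export]]
NumericMatrix cpp_diagram(NumericVector f) {
  const int n = f.size();
  std::vector<int> amin, amax;  // 1-based signal positions
  amin.reserve(n / 2 + 1);
  amax.reserve(n / 2 + 1);
  for (int i = 1; i <= n; ++i) {
    double fi = f[i - 1];
    double fl = (i == 1) ? R_PosInf : f[i - 2];
    double fr = (i == n) ? R_NegInf : f[i];
    bool lt_left = key_lt(fi, i, fl, i - 1);
    bool lt_right = key_lt(fi, i, fr, i + 1);
    if (lt_left && lt_right)
      amin.push_back(i);
    else if (!lt_left && !lt_right)
      amax.push_back(i);
  }
  auto bykey = [&](int a, int b) { return key_lt(f[a - 1], a, f[b - 1], b); };
  std::sort(amin.begin(), amin.end(), bykey);
  std::sort(amax.begin(), amax.end(), bykey);
  const int r = (int)amin.size();
  if ((int)amax.size() != r)
    stop("internal error: unequal numbers of minima and maxima");

  NumericMatrix out(r, 4);
  std::vector<bool> used(r, false);
  for (int k = 0; k < r; ++k) {
    int bk = amax[k];
    double fbk = f[bk - 1];
    int chosen = -1;
    // scan candidates from the largest key downward; the first admissible
    // one is the maximum of the inductive rule
    for (int i = r - 1; i >= 0; --i) {
      if (used[i]) continue;
      if (!key_lt(f[amin[i] - 1], amin[i], fbk, bk)) continue;  // need a_i strictly below b_k
      int lo = std::min(amin[i], bk), hi = std::max(amin[i], bk);
      bool ok = true;
      for (int j = 0; j < i && ok; ++j) {
        if (used[j]) continue;
        if (!key_lt(f[amin[j] - 1], amin[j], fbk, bk)) continue;
        if (amin[j] > lo && amin[j] < hi) ok = false;
      }
      if (ok) { chosen = i; break; }
    }
    if (chosen < 0)
      stop("internal error: empty candidate set in extrema pairing");
    used[chosen] = true;
    out(k, 0) = f[amin[chosen] - 1];
    out(k, 1) = fbk;
    out(k, 2) = amin[chosen];
    out(k, 3) = bk;
  }
  colnames(out) = CharacterVector::create("birth", "death", "min_index", "max_index");
  return out;
}

// One diagram per non-overlapping window of w consecutive samples; a trailing
// partial window is dropped.  Provenance indices are window-local (1..w).
// [[Rcpp::export]]
List cpp_windowed_diagrams(NumericVector f, int w) {
  if (w < 2) stop("window length must be at least 2");
  const int nw = f.size() / w;
  List out(nw);
  for (int k = 0; k < nw; ++k) {
    NumericVector win(f.begin() + (R_xlen_t)k * w, f.begin() + (R_xlen_t)(k + 1) * w);
    out[k] = cpp_diagram(win);
  }
  return out;
}
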