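#include <Rcpp.h>
using namespace Rcpp;

// Banded dynamic-programming alignment over the |i - j| <= band corridor.
// Inputs must already be z-normalised; the pointwise cost is the squared
// difference of matched samples.  Steps are the classic symmetric
// (1,1)/(1,0)/(0,1) moves, unweighted, cost cumulative (not normalised).
// Tie-break among equal-cost predecessors: diagonal, then vertical
// (advance in u), then horizontal, which makes the backtracked path unique.
//
// [[Rcpp::export]]
List dtw_band_cpp(NumericVector u, NumericVector v, int band, bool want_path) {
  const int n = u.size(), m = v.size();
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 start, 1 diag, 2 vertical, 3 horizontal
  std::fill(D.begin(), D.end(), R_PosInf);

  for (int i = 0; i < n; ++i) {
    const int jlo = std::max(0, i - band), jhi = std::min(m - 1, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double d = u[i] - v[j];
      d *= d;
      if (i == 0 && j == 0) {
        D(0, 0) = d;
        from(0, 0) = 0;
        continue;
      }
      double best = R_PosInf;
      int mv = 0;
      if (i > 0 && j > 0 && D(i - 1, j - 1) < best) { best = D(i - 1, j - 1); mv = 1; }
      if (i > 0 && D(i - 1, j) < best)              { best = D(i - 1, j);     mv = 2; }
      if (j > 0 && D(i, j - 1) < best)              { best = D(i, j - 1);     mv = 3; }
      D(i, j) = best + d;
      from(i, j) = mv;
    }
  }

  const double dist = D(n - 1, m - 1);
  if (!want_path)
    return List::create(_["distance"] = dist);

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1);
  pj.push_back(j + 1);
  while (!(i == 0 && j == 0)) {
    const int mv = from(i, j);
    if (mv == 1)      { --i; --j; }
    else if (mv == 2) { --i; }
    else if (mv == 3) { --j; }
    else break; // unreachable cell; guarded by feasibility check in R
    pi.push_back(i + 1);
    pj.push_back(j + 1);
  }
  const int w = pi.size();
  IntegerMatrix path(w, 2);
  for (int k = 0; k < w; ++k) {
    path(k, 0) = pi[w - 1 - k];
    path(k, 1) = pj[w - 1 - k];
  }
  return List::create(_["distance"] = dist, _["path"] = path);
}
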