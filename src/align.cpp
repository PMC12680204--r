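#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded local alignment (Smith-Waterman flavour) with the scoring scheme
// used throughout the package: match +1, mismatch -1, gap opening -1, gap
// extension 0.  'N' never matches anything.  A single query column may be
// masked (mask_q, 0-based): it scores 0 and is tallied as neither match nor
// mismatch, which lets a probe's polymorphic site float free of the score.
//
// The band restricts the diagonal d = j - i (query i, target j, both
// 0-based) to [diag_lo, diag_hi].  Callers derive the band from the seed
// cluster, so cells outside it are unreachable rather than clipped.
//
// Three states: M (i,j aligned), QG (query base against target gap),
// TG (target base against query gap).  Gap extensions are free, so QG/TG
// carry no per-base cost beyond the opening.

static const double NEG_INF = -1e9;

// [[Rcpp::export(name = ".banded_local_align")]]
List banded_local_align(std::string query, std::string target,
                        int mask_q, int diag_lo, int diag_hi) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);

  // score of aligning query i to target j (0-based)
  auto subst = [&](int i, int j) -> double {
    if (i == mask_q) return 0.0;
    char a = query[(size_t) i], b = target[(size_t) j];
    if (a == 'N' || b == 'N') return -1.0;
    return (a == b) ? 1.0 : -1.0;
  };

  // DP matrices (m+1) x (n+1), row 0 / col 0 are boundary
  std::vector<double> M((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<double> QG((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<double> TG((size_t)(m + 1) * (n + 1), NEG_INF);
  // traceback: 0 none/start, 1 from M, 2 from QG, 3 from TG
  std::vector<unsigned char> bM((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> bQ((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> bT((size_t)(m + 1) * (n + 1), 0);
  auto at = [&](int i, int j) { return (size_t) i * (n + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int d = (j - 1) - (i - 1);
      if (d < diag_lo || d > diag_hi) continue;

      // M: consume (i-1, j-1)
      double s = subst(i - 1, j - 1);
      double fromM = M[at(i - 1, j - 1)];
      double fromQ = QG[at(i - 1, j - 1)];
      double fromT = TG[at(i - 1, j - 1)];
      double prev = 0.0;  // local start
      unsigned char tb = 0;
      if (fromM > prev) { prev = fromM; tb = 1; }
      if (fromQ > prev) { prev = fromQ; tb = 2; }
      if (fromT > prev) { prev = fromT; tb = 3; }
      M[at(i, j)] = prev + s;
      bM[at(i, j)] = tb;

      // QG: query base i-1 against gap (move down); open from M costs 1
      double qOpen = M[at(i - 1, j)] - 1.0;
      double qExt  = QG[at(i - 1, j)];
      if (qOpen >= qExt) { QG[at(i, j)] = qOpen; bQ[at(i, j)] = 1; }
      else               { QG[at(i, j)] = qExt;  bQ[at(i, j)] = 2; }

      // TG: target base j-1 against gap (move right)
      double tOpen = M[at(i, j - 1)] - 1.0;
      double tExt  = TG[at(i, j - 1)];
      if (tOpen >= tExt) { TG[at(i, j)] = tOpen; bT[at(i, j)] = 1; }
      else               { TG[at(i, j)] = tExt;  bT[at(i, j)] = 3; }

      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  if (bi < 0)
    return List::create(_["score"] = 0);

  // traceback from best M cell until a local start
  std::vector<int> qs, ts;  // column map, reversed; -1 = gap
  int i = bi, j = bj;
  int state = 1;  // 1 M, 2 QG, 3 TG
  while (i > 0 || j > 0) {
    if (state == 1) {
      unsigned char tb = bM[at(i, j)];
      qs.push_back(i - 1);
      ts.push_back(j - 1);
      --i; --j;
      if (tb == 0) break;
      state = tb;
    } else if (state == 2) {
      unsigned char tb = bQ[at(i, j)];
      qs.push_back(i - 1);
      ts.push_back(-1);
      --i;
      state = tb;
    } else {
      unsigned char tb = bT[at(i, j)];
      qs.push_back(-1);
      ts.push_back(j - 1);
      --j;
      state = tb;
    }
  }

  const int L = (int) qs.size();
  IntegerVector qcol(L), tcol(L);
  for (int k = 0; k < L; ++k) {
    qcol[k] = qs[L - 1 - k] < 0 ? NA_INTEGER : qs[L - 1 - k];
    tcol[k] = ts[L - 1 - k] < 0 ? NA_INTEGER : ts[L - 1 - k];
  }

  return List::create(
    _["score"] = best,
    _["q"] = qcol,
    _["t"] = tcol);
}
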