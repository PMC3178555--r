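#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed position-score
// matrix S (n x m), where S already folds in substitution scores plus any
// HAR / secondary-structure bonuses. Gap run of length L costs
// gap_open + (L - 1) * gap_extend; with free_end_gaps, leading and trailing
// runs cost nothing.
//
// Tie-breaking is fixed so traceback is deterministic: diagonal, then
// vertical (target residue against a gap in the template row), then
// horizontal.

static const double NEG_INF = -1e30;

// state codes
enum { SM = 0, SX = 1, SY = 2 }; // match, gap-in-template-row, gap-in-target-row

// [[Rcpp::export]]
List fia_align_cpp(NumericMatrix S, double gap_open, double gap_extend,
                   bool free_end_gaps) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor state for each cell/state
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  #define IDX(i, j) ((i) * (m + 1) + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = free_end_gaps ? 0.0 : -(gap_open + (i - 1) * gap_extend);
    pX[IDX(i, 0)] = (i == 1) ? SM : SX;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = free_end_gaps ? 0.0 : -(gap_open + (j - 1) * gap_extend);
    pY[IDX(0, j)] = (j == 1) ? SM : SY;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: preference M > X > Y on ties
      {
        double bm = M[IDX(i - 1, j - 1)], bx = X[IDX(i - 1, j - 1)],
               by = Y[IDX(i - 1, j - 1)];
        double best = bm; signed char ps = SM;
        if (bx > best) { best = bx; ps = SX; }
        if (by > best) { best = by; ps = SY; }
        if (best > NEG_INF / 2) {
          M[IDX(i, j)] = best + S(i - 1, j - 1);
          pM[IDX(i, j)] = ps;
        }
      }
      // X: consume target residue i against a gap
      {
        double bm = M[IDX(i - 1, j)] - gap_open;
        double bx = X[IDX(i - 1, j)] - gap_extend;
        double by = Y[IDX(i - 1, j)] - gap_open;
        double best = bm; signed char ps = SM;
        if (bx > best) { best = bx; ps = SX; }
        if (by > best) { best = by; ps = SY; }
        if (best > NEG_INF / 2) { X[IDX(i, j)] = best; pX[IDX(i, j)] = ps; }
      }
      // Y: consume template residue j against a gap
      {
        double bm = M[IDX(i, j - 1)] - gap_open;
        double bx = X[IDX(i, j - 1)] - gap_open;
        double by = Y[IDX(i, j - 1)] - gap_extend;
        double best = bm; signed char ps = SM;
        if (bx > best) { best = bx; ps = SX; }
        if (by > best) { best = by; ps = SY; }
        if (best > NEG_INF / 2) { Y[IDX(i, j)] = best; pY[IDX(i, j)] = ps; }
      }
    }
  }

  // choose end cell and state
  int ei = n, ej = m;
  signed char est = SM;
  double score;
  {
    double bm = M[IDX(n, m)], bx = X[IDX(n, m)], by = Y[IDX(n, m)];
    score = bm; est = SM;
    if (bx > score) { score = bx; est = SX; }
    if (by > score) { score = by; est = SY; }
  }
  if (free_end_gaps) {
    // trailing gaps are free: end anywhere on the last row/column
    for (int i = n - 1; i >= 1; --i) {
      double bm = M[IDX(i, m)], bx = X[IDX(i, m)], by = Y[IDX(i, m)];
      double best = bm; signed char st = SM;
      if (bx > best) { best = bx; st = SX; }
      if (by > best) { best = by; st = SY; }
      if (best > score) { score = best; est = st; ei = i; ej = m; }
    }
    for (int j = m - 1; j >= 1; --j) {
      double bm = M[IDX(n, j)], bx = X[IDX(n, j)], by = Y[IDX(n, j)];
      double best = bm; signed char st = SM;
      if (bx > best) { best = bx; st = SX; }
      if (by > best) { best = by; st = SY; }
      if (best > score) { score = best; est = st; ei = n; ej = j; }
    }
  }

  // traceback
  std::vector<int> ti, pj;
  // trailing free gaps
  for (int i = n; i > ei; --i) { ti.push_back(i); pj.push_back(0); }
  for (int j = m; j > ej; --j) { ti.push_back(0); pj.push_back(j); }
  int i = ei, j = ej;
  signed char st = est;
  while (i > 0 || j > 0) {
    if (st == SM) {
      signed char ps = pM[IDX(i, j)];
      ti.push_back(i); pj.push_back(j);
      --i; --j; st = ps;
    } else if (st == SX) {
      signed char ps = pX[IDX(i, j)];
      ti.push_back(i); pj.push_back(0);
      --i; st = ps;
    } else {
      signed char ps = pY[IDX(i, j)];
      ti.push_back(0); pj.push_back(j);
      --j; st = ps;
    }
  }
  std::reverse(ti.begin(), ti.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["score"] = score,
                      _["t_idx"] = IntegerVector(ti.begin(), ti.end()),
                      _["p_idx"] = IntegerVector(pj.begin(), pj.end()));
}
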