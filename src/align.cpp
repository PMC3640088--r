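#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks over {A,C,G,T}.
static int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
  case 'K': return 4|8; case 'M': return 1|2;
  case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
  case 'N': return 15;
  default: return 0;
  }
}

// [[Rcpp::export]]
LogicalVector iupac_compatible_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *pa = CHAR(STRING_ELT(a, i));
    const char *pb = CHAR(STRING_ELT(b, i));
    out[i] = (iupac_mask(pa[0]) & iupac_mask(pb[0])) != 0;
  }
  return out;
}

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh style. A gap
// of length k costs gap_open + k * gap_ext, terminal gaps included, so the
// alignment cannot silently slide into a high-scoring shifted overlap.
// Difference counting excludes terminal gap runs (ragged amplicon ends):
// bp differences = substitution columns + internal gap columns. Paired
// columns whose IUPAC base sets intersect count as matches. Traceback ties
// broken: paired > gap-in-b > gap-in-a.
// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) stop("sequences must be non-empty");
  const double NEG = -1e18;

  std::vector<int> ma(la), mb(lb);
  for (int i = 0; i < la; ++i) {
    ma[i] = iupac_mask(a[i]);
    if (ma[i] == 0) stop("non-IUPAC character '%s' at position %d", std::string(1, a[i]), i + 1);
  }
  for (int j = 0; j < lb; ++j) {
    mb[j] = iupac_mask(b[j]);
    if (mb[j] == 0) stop("non-IUPAC character '%s' at position %d", std::string(1, b[j]), j + 1);
  }

  // M: column pairs a_i with b_j; X: column is a_i over a gap (gap in b);
  // Y: column is a gap over b_j.
  std::vector<double> M((la + 1) * (lb + 1), NEG),
                      X((la + 1) * (lb + 1), NEG),
                      Y((la + 1) * (lb + 1), NEG);
  auto at = [lb](int i, int j) { return i * (lb + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) X[at(i, 0)] = -gap_open - gap_ext * i;
  for (int j = 1; j <= lb; ++j) Y[at(0, j)] = -gap_open - gap_ext * j;

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = (ma[i - 1] & mb[j - 1]) ? match : mismatch;
      double diag = std::max(M[at(i - 1, j - 1)],
                             std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      if (diag > NEG / 2) M[at(i, j)] = s + diag;
      double xv = std::max(std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) - gap_open - gap_ext,
                           X[at(i - 1, j)] - gap_ext);
      if (xv > NEG / 2) X[at(i, j)] = xv;
      double yv = std::max(std::max(M[at(i, j - 1)], X[at(i, j - 1)]) - gap_open - gap_ext,
                           Y[at(i, j - 1)] - gap_ext);
      if (yv > NEG / 2) Y[at(i, j)] = yv;
    }
  }

  double best = std::max(M[at(la, lb)], std::max(X[at(la, lb)], Y[at(la, lb)]));

  // Traceback, recording column classes: 0 pair-match, 1 substitution,
  // 2 gap in b, 3 gap in a.
  std::vector<int> cols;
  std::string ca, cb;  // aligned strings, built reversed
  int i = la, j = lb;
  int state = (best == M[at(la, lb)]) ? 0 : (best == X[at(la, lb)]) ? 1 : 2;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      bool compat = (ma[i - 1] & mb[j - 1]) != 0;
      cols.push_back(compat ? 0 : 1);
      ca.push_back(a[i - 1]); cb.push_back(b[j - 1]);
      double s = compat ? match : mismatch;
      double target = M[at(i, j)] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - target) < eps) state = 1;
      else if (std::abs(Y[at(i, j)] - target) < eps) state = 2;
      else stop("traceback failed (paired state)");
    } else if (state == 1) {
      cols.push_back(2);
      ca.push_back(a[i - 1]); cb.push_back('-');
      double target = X[at(i, j)];
      --i;
      if (std::abs(X[at(i, j)] - gap_ext - target) < eps) state = 1;
      else if (std::abs(M[at(i, j)] - gap_open - gap_ext - target) < eps) state = 0;
      else if (std::abs(Y[at(i, j)] - gap_open - gap_ext - target) < eps) state = 2;
      else stop("traceback failed (gap-in-b state)");
      if (i == 0 && j == 0) break;
    } else {
      cols.push_back(3);
      ca.push_back('-'); cb.push_back(b[j - 1]);
      double target = Y[at(i, j)];
      --j;
      if (std::abs(Y[at(i, j)] - gap_ext - target) < eps) state = 2;
      else if (std::abs(M[at(i, j)] - gap_open - gap_ext - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - gap_open - gap_ext - target) < eps) state = 1;
      else stop("traceback failed (gap-in-a state)");
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(cols.begin(), cols.end());
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());

  // strip terminal gap runs from the counts
  int lo = 0, hi = (int)cols.size() - 1;
  while (lo <= hi && cols[lo] >= 2) ++lo;
  while (hi >= lo && cols[hi] >= 2) --hi;
  int n_sub = 0, n_gap_cols = 0, n_gap_runs = 0;
  for (int k = lo; k <= hi; ++k) {
    if (cols[k] == 1) ++n_sub;
    else if (cols[k] >= 2) {
      ++n_gap_cols;
      if (k == lo || cols[k - 1] != cols[k]) ++n_gap_runs;
    }
  }

  return List::create(
    _["score"] = best,
    _["n_sub"] = n_sub,
    _["n_gap_cols"] = n_gap_cols,
    _["n_gap_runs"] = n_gap_runs,
    _["aligned_a"] = ca, _["aligned_b"] = cb);
}
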