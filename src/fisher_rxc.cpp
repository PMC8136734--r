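#include <Rcpp.h>
#include <vector>
#include <cmath>

// Freeman-Halton exact test by depth-first enumeration of all r x c tables
// with the observed margins.  Tables are ordered by their multivariate
// hypergeometric probability; the two-sided p is the total probability of
// tables no more probable than the observed one (with the customary
// (1 + 1e-7) relative float tolerance).

namespace {

struct Enumerator {
  int r, c;
  std::vector<int> rowsum, colsum;
  std::vector<double> lfact;        // lgamma(n + 1) table
  double log_const;                 // log of margin constant
  double log_thresh;                // log p_obs + log1p(tol)
  double p_sum;
  std::vector<int> colleft;

  double lf(int n) const { return lfact[n]; }

  // fill rows depth-first; within a row, iterate the first c-1 cells,
  // pruning when the remaining column capacity cannot absorb the row.
  void row(int i, double acc) {
    if (i == r - 1) {
      // last row forced by the column margins
      double s = acc;
      for (int j = 0; j < c; ++j) s -= lf(colleft[j]);
      double logp = log_const + s;
      if (logp <= log_thresh) p_sum += std::exp(logp);
      return;
    }
    std::vector<int> cell(c, 0);
    cellrec(i, 0, rowsum[i], acc);
  }

  void cellrec(int i, int j, int left, double acc) {
    if (j == c - 1) {
      if (left > colleft[j]) return;
      colleft[j] -= left;
      row(i + 1, acc - lf(left));
      colleft[j] += left;
      return;
    }
    // remaining capacity of columns j+1..c-1
    int cap = 0;
    for (int jj = j + 1; jj < c; ++jj) cap += colleft[jj];
    int lo = left - cap; if (lo < 0) lo = 0;
    int hi = left < colleft[j] ? left : colleft[j];
    for (int x = lo; x <= hi; ++x) {
      colleft[j] -= x;
      cellrec(i, j + 1, left - x, acc - lf(x));
      colleft[j] += x;
    }
  }
};

} // namespace

// [[Rcpp::export]]
double fisher_rxc_enumerate(Rcpp::IntegerMatrix tab, double tol_rel) {
  Enumerator e;
  e.r = tab.nrow();
  e.c = tab.ncol();
  e.rowsum.assign(e.r, 0);
  e.colsum.assign(e.c, 0);
  int N = 0;
  for (int i = 0; i < e.r; ++i)
    for (int j = 0; j < e.c; ++j) {
      int v = tab(i, j);
      if (v < 0) Rcpp::stop("negative cell count");
      e.rowsum[i] += v;
      e.colsum[j] += v;
      N += v;
    }
  if (N == 0) Rcpp::stop("empty table");

  e.lfact.resize(N + 1);
  for (int n = 0; n <= N; ++n) e.lfact[n] = std::lgamma(n + 1.0);

  e.log_const = -e.lf(N);
  for (int i = 0; i < e.r; ++i) e.log_const += e.lf(e.rowsum[i]);
  for (int j = 0; j < e.c; ++j) e.log_const += e.lf(e.colsum[j]);

  double s_obs = 0.0;
  for (int i = 0; i < e.r; ++i)
    for (int j = 0; j < e.c; ++j) s_obs -= e.lf(tab(i, j));
  e.log_thresh = e.log_const + s_obs + std::log1p(tol_rel);

  e.p_sum = 0.0;
  e.colleft = e.colsum;
  e.row(0, 0.0);
  return e.p_sum > 1.0 ? 1.0 : e.p_sum;
}

// log multivariate hypergeometric probabilities of a batch of tables with
// common margins (used by the Monte-Carlo branch and its tests).
// [[Rcpp::export]]
Rcpp::NumericVector table_log_prob(Rcpp::List tables) {
  int B = tables.size();
  Rcpp::NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    Rcpp::IntegerMatrix tab = tables[b];
    int r = tab.nrow(), c = tab.ncol(), N = 0;
    std::vector<int> rs(r, 0), cs(c, 0);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < c; ++j) {
        rs[i] += tab(i, j);
        cs[j] += tab(i, j);
        N += tab(i, j);
      }
    double lp = -std::lgamma(N + 1.0);
    for (int i = 0; i < r; ++i) lp += std::lgamma(rs[i] + 1.0);
    for (int j = 0; j < c; ++j) lp += std::lgamma(cs[j] + 1.0);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < c; ++j) lp -= std::lgamma(tab(i, j) + 1.0);
    out[b] = lp;
  }
  return out;
}
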