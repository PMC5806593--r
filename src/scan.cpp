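#include <Rcpp.h>
using namespace Rcpp;

// Scan all cuts of each replicate under both priors.
//
// pos:     reps x D matrix of 1-based one-positions (order irrelevant)
// L:       sequence length
// logK:    (L-1) x (D+1) table, logK(x-1, d1) = log2 K_x for d1 initial ones
// logZ:    length L-1, log2 Z(x)
// log2jef: length L-1, log2 sqrt(1/x^2 + 1/y^2)
//
// Returns reps x 6: X_j, D1_j, dl_alt_j, X_f, D1_f, dl_alt_f where
// dl_alt = -log2(best score); X = 0 and dl_alt = NA when no cut is
// admissible. Admissibility D1/x > D2/y reduces to D1 * L > D * x.
// Ties break toward the smallest x (strict improvement required).
// [[Rcpp::export]]
NumericMatrix scan_cuts_chunk(IntegerMatrix pos, int L,
                              NumericMatrix logK, NumericVector logZ,
                              NumericVector log2jef) {
  const int reps = pos.nrow(), D = pos.ncol();
  if (logK.nrow() != L - 1 || logK.ncol() < D + 1)
    stop("logK table has wrong shape");
  NumericMatrix out(reps, 6);
  std::vector<int> marks(L);
  for (int r = 0; r < reps; ++r) {
    std::fill(marks.begin(), marks.end(), 0);
    for (int k = 0; k < D; ++k) {
      int p = pos(r, k);
      if (p < 1 || p > L) stop("position out of range");
      marks[p - 1] += 1;
    }
    int c = 0, xP = 0, xF = 0, d1P = 0, d1F = 0;
    double bestP = R_NegInf, bestR = R_NegInf;
    for (int x = 1; x <= L - 1; ++x) {
      c += marks[x - 1];
      if ((long long)c * L <= (long long)D * x) continue;  // inadmissible
      const double sp = logK(x - 1, c) - logZ[x - 1];
      if (sp > bestP) { bestP = sp; xP = x; d1P = c; }
      const double sr = sp - log2jef[x - 1];
      if (sr > bestR) { bestR = sr; xF = x; d1F = c; }
    }
    out(r, 0) = xP; out(r, 1) = d1P;
    out(r, 2) = xP ? -bestP : NA_REAL;
    out(r, 3) = xF; out(r, 4) = d1F;
    out(r, 5) = xF ? -bestR : NA_REAL;
  }
  return out;
}
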