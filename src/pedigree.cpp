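#include <Rcpp.h>
using namespace Rcpp;

// Pedigree inbreeding by the Meuwissen & Luo (1992) recursion.
// sire/dam are 1-based ids into the same vector, 0 = unknown; the pedigree
// must be sorted so parents precede offspring.
// [[Rcpp::export]]
NumericVector cpp_pedigree_F(const IntegerVector& sire,
                             const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  // 1-based work arrays; index 0 = unknown-parent slot (F = -1 convention)
  std::vector<double> L(n + 1, 0.0);
  std::vector<int> point(n + 1, 0);
  auto fpar = [&](int x) { return x == 0 ? -1.0 : F[x - 1]; };

  for (int i = 1; i <= n; ++i) {
    const int si = sire[i - 1], di = dam[i - 1];
    if (si < 0 || si > i - 1 || di < 0 || di > i - 1)
      stop("pedigree not sorted: parents must precede offspring");
    if (si == 0 || di == 0) { F[i - 1] = 0.0; continue; }
    double FI = -1.0;
    L[i] = 1.0;
    point[i] = 0;
    int j = i;
    while (j != 0) {
      const double r = 0.5 * L[j];
      const int js = sire[j - 1], jd = dam[j - 1];
      // insert/accumulate each known parent in the descending linked list
      for (int t = 0; t < 2; ++t) {
        const int par = (t == 0) ? js : jd;
        if (par == 0) continue;
        int k = j;
        while (point[k] > par) k = point[k];
        L[par] += r;
        if (point[k] != par) { point[par] = point[k]; point[k] = par; }
      }
      FI += L[j] * L[j] * (0.5 - 0.25 * (fpar(js) + fpar(jd)));
      L[j] = 0.0;
      const int k = j;
      j = point[k];
      point[k] = 0;
    }
    F[i - 1] = FI;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// Same coding as cpp_pedigree_F. Memory is O(n^2); intended for the
// evaluation layer on moderate pedigrees, not full-scale runs.
// [[Rcpp::export]]
NumericMatrix cpp_amatrix(const IntegerVector& sire,
                          const IntegerVector& dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int si = sire[i] - 1, di = dam[i] - 1;  // -1 = unknown
    if (si >= i || di >= i)
      stop("pedigree not sorted: parents must precede offspring");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (si >= 0) v += 0.5 * A(j, si);
      if (di >= 0) v += 0.5 * A(j, di);
      A(i, j) = A(j, i) = v;
    }
    double d = 1.0;
    if (si >= 0 && di >= 0) d += 0.5 * A(si, di);
    A(i, i) = d;
  }
  return A;
}
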