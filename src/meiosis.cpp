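#include <Rcpp.h>
using namespace Rcpp;

// Map-based meiosis for a batch of gametes.
//
// Haplotypes are stored as integer matrices (individuals x loci), loci ordered
// by chromosome then cM position. Crossover counts per chromosome are
// Poisson(length/100) (Haldane, no interference), crossover positions uniform
// on [0, length], and the starting haplotype is chosen with probability 1/2.
// Allele states and founder-origin labels travel together.
//
// parent_row: 1-based row index of the parent for each gamete.
// chr_start/chr_end: 1-based column ranges per chromosome.
// pos: per-locus cM positions (concatenated over chromosomes, same order as
// columns).
// [[Rcpp::export]]
List cpp_make_gametes(const IntegerMatrix& H1, const IntegerMatrix& H2,
                      const IntegerMatrix& L1, const IntegerMatrix& L2,
                      const IntegerVector& parent_row,
                      const IntegerVector& chr_start,
                      const IntegerVector& chr_end,
                      const NumericVector& chr_len,
                      const NumericVector& pos) {
  const int n_gam = parent_row.size();
  const int n_loci = H1.ncol();
  const int n_chr = chr_start.size();
  IntegerMatrix GH(n_gam, n_loci), GL(n_gam, n_loci);

  for (int g = 0; g < n_gam; ++g) {
    const int p = parent_row[g] - 1;
    for (int c = 0; c < n_chr; ++c) {
      const int lo = chr_start[c] - 1, hi = chr_end[c] - 1;
      const double len = chr_len[c];
      int k = (len > 0.0) ? (int)R::rpois(len / 100.0) : 0;
      std::vector<double> xo(k);
      for (int t = 0; t < k; ++t) xo[t] = R::runif(0.0, len);
      std::sort(xo.begin(), xo.end());
      int cur = (unif_rand() < 0.5) ? 0 : 1;  // 0 -> H1, 1 -> H2
      int nxt = 0;
      for (int j = lo; j <= hi; ++j) {
        while (nxt < k && xo[nxt] <= pos[j]) { cur = 1 - cur; ++nxt; }
        if (cur == 0) { GH(g, j) = H1(p, j); GL(g, j) = L1(p, j); }
        else          { GH(g, j) = H2(p, j); GL(g, j) = L2(p, j); }
      }
    }
  }
  return List::create(_["H"] = GH, _["L"] = GL);
}

// Fraction of loci at which the two carried alleles share a founder-origin
// label (realized inbreeding), per individual.
// [[Rcpp::export]]
NumericVector cpp_realized_F(const IntegerMatrix& L1, const IntegerMatrix& L2) {
  const int n = L1.nrow(), m = L1.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int s = 0;
    for (int j = 0; j < m; ++j) if (L1(i, j) == L2(i, j)) ++s;
    out[i] = (double)s / (double)m;
  }
  return out;
}
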