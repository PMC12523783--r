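# Small in-code fixtures shared across test files.

# two-chromosome mini genome
mini_genome <- function(n_snp = c(30L, 20L), n_qtl = c(6L, 4L),
                        len = c(100, 60), seed = 42L) {
  build_genome(tibble::tibble(chrom = seq_along(len), length_cM = len,
                              n_snp = n_snp, n_qtl = n_qtl), seed = seed)
}

mini_founders <- function(map = mini_genome(), n_per_sex = 30L,
                          spec = founder_spec(c(0.3, 0.3), c(0.6, 0.6),
                                              n_founders_per_sex = 30L),
                          seed = 7L) {
  freqs <- sample_allele_frequencies(spec, map, seed = seed)
  make_reference_population(freqs, map, n_per_sex, seed = seed + 1L)
}

# direct two-locus variance partition by weighted hierarchical regression:
# an oracle independent of the orthogonal-contrast projections used by
# kempthorne_decompose()
brute_kempthorne <- function(G_table, p_i, p_j) {
  xi <- rep(0:2, times = 3); xj <- rep(0:2, each = 3)
  f <- function(p, x) c((1 - p)^2, 2 * p * (1 - p), p^2)[x + 1]
  w <- f(p_i, xi) * f(p_j, xj)
  g <- as.numeric(G_table[cbind(xi + 1, xj + 1)])
  wvar <- function(v) sum(w * (v - sum(w * v))^2)
  fit <- function(form, dat) {
    m <- stats::lm(form, data = dat, weights = w)
    stats::fitted(m)
  }
  dat <- data.frame(g = g, xi = xi, xj = xj,
                    fi = factor(xi), fj = factor(xj))
  # hierarchical (sequential) variance accounting
  v_A <- wvar(fit(g ~ xi + xj, dat))
  v_AD <- wvar(fit(g ~ fi + fj, dat))
  v_AA <- wvar(fit(g ~ fi + fj + xi:xj, dat))
  v_AxD <- wvar(fit(g ~ fi + fj + xi:xj + xi:fj, dat))
  v_DxA <- wvar(fit(g ~ fi + fj + xi:xj + xi:fj + fi:xj, dat))
  v_tot <- wvar(g)
  c(A = v_A, D = v_AD - v_A, AxA = v_AA - v_AD, AxD = v_AxD - v_AA,
    DxA = v_DxA - v_AxD, DxD = v_tot - v_DxA, total = v_tot)
}

derive_seed_test <- function(...) panmixsel:::derive_seed(1L, ...)
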