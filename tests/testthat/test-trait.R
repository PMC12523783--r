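test_that("gene effects satisfy the genotypic-bound sums exactly", {
  e1 <- derive_gene_effects(1.1, 2.9, 1, degrees = 0)
  expect_equal(e1$m, 2.0)
  expect_equal(e1$a, 0.9)
  expect_equal(e1$d, 0)

  e <- derive_gene_effects(1.1, 2.9, 1000, seed = 1)
  expect_equal(sum(e$m + e$a), 2.9)
  expect_equal(sum(e$m - e$a), 1.1)
  expect_equal(sum(e$a), 0.9)
  expect_equal(sum(e$m), 2.0)
  expect_true(all(e$degree >= 0 & e$degree <= 1.2))
  expect_equal(mean(e$degree), 0.6, tolerance = 0.05)
  expect_equal(e$d, e$degree * e$a)

  eg <- derive_gene_effects(1.1, 2.9, 50, allocation = "geometric", seed = 2)
  expect_equal(sum(eg$m + eg$a), 2.9)
  expect_equal(sum(eg$m - eg$a), 1.1)
  expect_gt(eg$a[1], eg$a[50])

  expect_error(derive_gene_effects(1.1, 2.9, 0), "n_qtl")
  expect_error(derive_gene_effects(1.1, 2.9, 5, degrees = 2), "degrees")
})

test_that("epistasis partitions reproduce the F2 ratios", {
  f2 <- c(1, 2, 1)  # F2 genotype counts (out of 4) per dosage 0,1,2
  counts <- outer(f2, f2)
  ratio <- function(type) {
    cls <- epistasis_partition(type)
    as.numeric(sort(tapply(counts, cls, sum), decreasing = TRUE))
  }
  expect_equal(ratio("complementary"), c(9, 7))
  expect_equal(ratio("duplicate"), c(15, 1))
  expect_equal(ratio("dominant"), c(12, 3, 1))
  expect_equal(ratio("recessive"), c(9, 4, 3))
  expect_equal(ratio("dominant_and_recessive"), c(13, 3))
  expect_equal(ratio("duplicate_cumulative"), c(9, 6, 1))
  expect_equal(ratio("non_epistatic_interaction"), c(9, 3, 3, 1))
  # partitions cover all nine genotypes exactly once
  for (ty in epistasis_types())
    expect_equal(sum(tapply(counts, epistasis_partition(ty), sum)), 16)
  expect_error(epistasis_partition("nope"), "unknown")
})

test_that("epistatic pair assignment is disjoint, sized and seed-stable", {
  ids <- sprintf("Q%03d", 1:1000)
  pr <- assign_epistatic_pairs(ids, 0.5, seed = 3)
  expect_equal(nrow(pr), 250)
  expect_equal(anyDuplicated(c(pr$qtl_i, pr$qtl_j)), 0)
  expect_true(all(pr$type %in% epistasis_types()))

  expect_equal(nrow(assign_epistatic_pairs(ids, 0)), 0)
  expect_warning(assign_epistatic_pairs(ids[1:10], 0.5, seed = 1), "odd")

  # identical pairing across single-type scenarios under one seed
  p1 <- assign_epistatic_pairs(ids, 0.3, "complementary", seed = 9)
  p2 <- assign_epistatic_pairs(ids, 0.3, "duplicate", seed = 9)
  expect_equal(p1[c("qtl_i", "qtl_j")], p2[c("qtl_i", "qtl_j")])
})

test_that("solver yields class-constant genotypic values with the right count of distinct values", {
  ei <- list(m = 0.4, a = 0.2, d = 0.1)
  ej <- list(m = 0.3, a = 0.15, d = 0.12)
  for (ty in epistasis_types()) {
    sol <- solve_epistatic_effects(ei, ej, ty, I22 = 0.37)
    cls <- sol$classes
    # constant within classes (single-member classes trivially so)
    for (cl in unique(as.numeric(cls)))
      expect_lt(diff(range(sol$G[cls == cl])), 1e-12)
    # exactly as many distinct values as classes (two to four)
    expect_equal(length(unique(round(as.numeric(sol$G), 12))), max(cls))
    # class of (2,2): anchored at m_i + m_j + a_i + a_j + I22
    expect_equal(sol$G[3, 3], 0.4 + 0.3 + 0.2 + 0.15 + 0.37)
    # reference genotype of each other class keeps its non-epistatic value
    expect_equal(sum(abs(sol$I) < 1e-12) >= max(cls) - 1, TRUE)
  }
  # complementary, anchored at I00 = 0: lower class = m_i + m_j - a_i - a_j
  sol <- solve_epistatic_effects(ei, ej, "complementary", I22 = 0.2)
  expect_equal(sol$G[1, 1], 0.4 + 0.3 - 0.2 - 0.15)
  expect_equal(sol$I[1, 1], 0)
  expect_equal(max(abs(sol$G[cbind(c(3, 3, 2, 2), c(3, 2, 3, 2))] -
                         sol$G[3, 3])), 0)
  # duplicate: the eight dominant-carrying genotypes share one value
  sd <- solve_epistatic_effects(ei, ej, "duplicate", I22 = 0.1)
  dom <- sd$classes == 1
  expect_equal(sum(dom), 8)
  expect_equal(var(sd$G[dom]), 0)
})

test_that("I22 sampling has the assembled variance", {
  expect_equal(sample_I22(1.5, 0, 0, 0, n = 10), rep(0, 10))
  set.seed(4)
  vc <- locus_varcomp(0.35, 0.3, 0.12)
  v_target <- 1.5 * (2 * vc$sigma_A2 + 2 * vc$sigma_D2)  # two equal loci
  draws <- sample_I22(1.5, 2 * vc$sigma_A2, 2 * vc$sigma_D2, 0, n = 1e5)
  expect_equal(var(draws), v_target, tolerance = 0.02)
  expect_warning(sample_I22(1, 0.1, 0, sigma_AD = -0.2), "clamped")
  expect_error(sample_I22(-1, 1, 1), "k must")
})

test_that("Kempthorne partition matches the brute-force regression oracle", {
  set.seed(11)
  for (rep in 1:25) {
    p_i <- runif(1, 0.05, 0.95); p_j <- runif(1, 0.05, 0.95)
    G <- matrix(rnorm(9), 3, 3)
    dec <- kempthorne_decompose(G, p_i, p_j)
    oracle <- brute_kempthorne(G, p_i, p_j)
    got <- setNames(dec$components$variance, dec$components$component)
    expect_equal(got[c("A", "D", "AxA", "AxD", "DxA", "DxD")],
                 oracle[c("A", "D", "AxA", "AxD", "DxA", "DxD")],
                 tolerance = 1e-10)
    # components sum to the total genotypic variance
    expect_equal(sum(got), dec$total_variance, tolerance = 1e-10)
    expect_equal(dec$total_variance, unname(oracle["total"]),
                 tolerance = 1e-10)
    # orthogonality: additive-dominance covariance vanishes at HWE
    expect_equal(dec$sigma_AD, 0, tolerance = 1e-12)
  }
})

test_that("Kempthorne edge cases: no epistasis, single-locus collapse, fixed locus", {
  ei <- list(m = 0, a = 0.4, d = 0)
  # additive-only two-locus table: I = 0 -> all interaction variances 0
  B <- outer(c(-0.4, 0, 0.4), c(-0.2, 0, 0.2), `+`)
  dec <- kempthorne_decompose(B, 0.3, 0.6)
  v <- setNames(dec$components$variance, dec$components$component)
  expect_equal(unname(v[c("AxA", "AxD", "DxA", "DxD")]), rep(0, 4),
               tolerance = 1e-14)
  # collapse locus j (no effect): p = 0.5, d = 0 -> sigma_A2 = a^2 / 2
  Bi <- outer(c(-0.4, 0, 0.4), c(0, 0, 0), `+`)
  di <- kempthorne_decompose(Bi, 0.5, 0.5)
  expect_equal(di$components$variance[1], 0.4^2 / 2)
  expect_equal(di$components$variance[2], 0)
  # degenerate frequency: fixed locus contributes nothing
  dfix <- kempthorne_decompose(B, 1, 0.5)
  expect_equal(dfix$components$variance[1], 2 * 0.5 * 0.5 * 0.2^2)
})

test_that("locus_varcomp matches the HWE closed forms", {
  vc <- locus_varcomp(0.5, 0.9, 0)
  expect_equal(vc$sigma_A2, 0.9^2 / 2)
  expect_equal(vc$sigma_D2, 0)
  vc2 <- locus_varcomp(0.3, 0.5, 0.2)
  q <- 0.7
  expect_equal(vc2$sigma_A2, 2 * 0.3 * q * (0.5 + 0.2 * (q - 0.3))^2)
  expect_equal(vc2$sigma_D2, (2 * 0.3 * q * 0.2)^2)
})

test_that("genotypic values follow the two-locus formula and bounds", {
  map <- mini_genome(n_snp = c(5L, 5L), n_qtl = c(1L, 1L))
  arch <- trait_architecture(map, epistasis = list(fraction = 1,
                                                   type = "complementary",
                                                   k = 1.5),
                             fav_freq = c(0.5, 0.5) |>
                               setNames(map$loci$id[map$loci$type == "qtl"]),
                             degrees = 0.5, seed = 5)
  expect_equal(nrow(arch$pairs), 1)
  eff <- arch$effects
  # all-heterozygote individual with the pair present: base + I at (1,1)
  fav <- matrix(1L, 1, 2, dimnames = list("x", eff$qtl))
  g_het <- genotypic_value(fav, arch)
  expect_equal(unname(g_het),
               sum(eff$m + eff$d) + arch$pairs$I[[1]][2, 2])
  # double unfavorable homozygote: m1 + m2 + a1 + a2 + I22
  fav00 <- matrix(0L, 1, 2, dimnames = list("x", eff$qtl))
  expect_equal(unname(genotypic_value(fav00, arch)),
               sum(eff$m + eff$a) + arch$pairs$I22[1])

  # no-epistasis architecture: all-heterozygote = sum(m + d)
  arch0 <- trait_architecture(map, degrees = 0.3, seed = 6)
  expect_equal(unname(genotypic_value(fav, arch0)), sum(arch0$effects$m) +
                 sum(arch0$effects$d))
  # enumerated single-pair values stay inside [g_min - |I|, g_max + |I|]
  grid <- as.matrix(expand.grid(0:2, 0:2))
  colnames(grid) <- eff$qtl
  gv <- genotypic_value(grid, arch)
  bnd <- max(abs(arch$pairs$I[[1]]))
  expect_true(all(gv >= arch$g_min - bnd & gv <= arch$g_max + bnd))
})

test_that("phenotypes hold broad-sense heritability and respect bounds", {
  set.seed(7)
  g <- rnorm(4000, 2, sqrt(0.02))
  y <- phenotype(g, H2 = 0.3, y_min = 1.0, y_max = 3.5)
  expect_equal(var(g) / var(y), 0.3, tolerance = 0.025)
  expect_true(all(y >= 1.0 & y <= 3.5))
  expect_equal(attr(y, "sigma_e"), sqrt(var(g) * 0.7 / 0.3))

  # H2 -> 1 limit: phenotypes equal genotypic values
  y1 <- phenotype(g, H2 = 1 - 1e-12, y_min = -10, y_max = 10)
  expect_equal(as.numeric(y1), g, tolerance = 1e-4)

  # zero-variance cohort falls back to the supplied sigma with a warning
  expect_warning(y0 <- phenotype(rep(2, 10), H2 = 0.3, 1, 3.5,
                                 sigma_e = 0.1), "zero genotypic")
  expect_error(phenotype(rep(2, 10), H2 = 0.3, 1, 3.5), "fallback")
  expect_error(phenotype(g, H2 = 1.2), "H2")
})

test_that("architecture serialization round-trips", {
  map <- mini_genome()
  qtl <- map$loci$id[map$loci$type == "qtl"]
  arch <- trait_architecture(map, epistasis = list(fraction = 0.6, k = 1.5),
                             fav_freq = setNames(runif(10, 0.3, 0.7), qtl),
                             seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(arch, path)
  back <- read_architecture(path)
  expect_equal(back$effects, arch$effects, tolerance = 1e-12)
  expect_equal(back$g_min, arch$g_min)
  expect_equal(back$H2, arch$H2)
  expect_equal(nrow(back$pairs), nrow(arch$pairs))
  expect_equal(back$pairs$I22, arch$pairs$I22, tolerance = 1e-12)
  for (r in seq_len(nrow(arch$pairs)))
    expect_equal(unname(back$pairs$I[[r]]), unname(arch$pairs$I[[r]]),
                 tolerance = 1e-12)
})

test_that("epistatic variance is a small share of the genotypic variance in the default design", {
  map <- mini_genome(n_snp = c(10L, 10L), n_qtl = c(36L, 24L))
  spec <- founder_spec(c(0.1, 0.5), c(0.3, 0.9), n_founders_per_sex = 150)
  freqs <- sample_allele_frequencies(spec, map, seed = 10)
  pop <- make_reference_population(freqs, map, 150, seed = 11)
  fd <- qtl_dosage(pop)
  fav <- setNames(colMeans(fd) / 2, colnames(fd))
  arch <- trait_architecture(map, epistasis = list(fraction = 0.5, k = 1.5),
                             fav_freq = fav, seed = 12)
  # Kempthorne share of summed epistatic variance across pairs, at realized
  # frequencies, relative to realized genotypic variance
  v_epi <- 0
  for (r in seq_len(nrow(arch$pairs))) {
    ii <- match(arch$pairs$qtl_i[r], arch$effects$qtl)
    jj <- match(arch$pairs$qtl_j[r], arch$effects$qtl)
    ei <- arch$effects[ii, ]; ej <- arch$effects[jj, ]
    B <- outer(ei$m + c(-ei$a, ei$d, ei$a), ej$m + c(-ej$a, ej$d, ej$a), `+`)
    dec <- kempthorne_decompose(B + arch$pairs$I[[r]],
                                1 - fav[[arch$pairs$qtl_i[r]]],
                                1 - fav[[arch$pairs$qtl_j[r]]])
    v <- setNames(dec$components$variance, dec$components$component)
    v_epi <- v_epi + sum(v[c("AxA", "AxD", "DxA", "DxD")])
  }
  vg <- var(genotypic_value(pop, arch))
  expect_lt(v_epi / vg, 0.10)
  expect_gt(v_epi, 0)
})
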