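test_that("crossover counts follow the map length and 0 cM chromosomes never recombine", {
  # single chromosome of 25.7 cM: mean crossovers per gamete = 0.257
  map <- build_genome(tibble::tibble(chrom = 1L, length_cM = 25.7,
                                     n_snp = 40L, n_qtl = 0L), seed = 1)
  # loci pinned to span the whole chromosome so every crossover falls
  # between observable loci
  map$loci$pos_cM <- seq(0, 25.7, length.out = nrow(map$loci))
  pop <- mini_founders(map = map, n_per_sex = 2,
                       spec = founder_spec(c(0.5, 0.5), c(0.5, 0.5),
                                           n_founders_per_sex = 2))
  # make parent haplotypes distinguishable everywhere to count switches
  pop$H1[] <- 0L; pop$H2[] <- 1L
  g <- meiosis(pop, parent_id = 1, n = 20000, seed = 2)
  switches <- rowSums(abs(g$H[, -1, drop = FALSE] -
                            g$H[, -ncol(g$H), drop = FALSE]))
  # observed switches undercount crossovers (even numbers between adjacent
  # loci cancel); with 40 loci on 25.7 cM the correction is negligible
  expect_equal(mean(switches), 0.257, tolerance = 0.05)

  map0 <- build_genome(tibble::tibble(chrom = 1L, length_cM = 1e-9,
                                      n_snp = 20L, n_qtl = 0L), seed = 1)
  pop0 <- mini_founders(map = map0, n_per_sex = 2,
                        spec = founder_spec(c(0.5, 0.5), c(0.5, 0.5),
                                            n_founders_per_sex = 2))
  pop0$H1[] <- 0L; pop0$H2[] <- 1L
  g0 <- meiosis(pop0, parent_id = 1, n = 200, seed = 3)
  expect_true(all(g0$H %in% c(0L, 1L)))
  expect_true(all(rowSums(g0$H) %in% c(0L, 20L)))  # unrecombined haplotypes
})

test_that("two-locus recombinant fraction follows the Haldane closed form", {
  for (d in c(5, 20, 60)) {
    map <- build_genome(tibble::tibble(chrom = 1L, length_cM = d + 2,
                                       n_snp = 2L, n_qtl = 0L), seed = 4)
    map$loci$pos_cM <- c(1, 1 + d)
    pop <- mini_founders(map = map, n_per_sex = 2,
                         spec = founder_spec(c(0.5, 0.5), c(0.5, 0.5),
                                             n_founders_per_sex = 2))
    pop$H1[] <- 0L; pop$H2[] <- 1L
    g <- meiosis(pop, parent_id = 1, n = 40000, seed = d)
    rec <- mean(g$H[, 1] != g$H[, 2])
    expect_equal(rec, haldane_theta(d), tolerance = 0.01)
  }
})

test_that("make_generation produces the planned families with labels conserved", {
  pop <- mini_founders()
  plan <- tibble::tibble(sire = c(31L, 32L), dam = c(1L, 2L),
                        n_offspring = c(10L, 20L))
  off <- make_generation(pop, plan, seed = 5)
  expect_equal(n_individuals(off), 30)
  expect_equal(off$info$sire, rep(c(31L, 32L), c(10L, 20L)))
  expect_equal(unique(off$info$generation), 1L)
  expect_true(all(off$info$sex %in% c("F", "M")))
  expect_equal(off$info$id, max(pop$info$id) + 1:30)
  # every offspring label exists in one of its parents
  for (i in c(1, 15)) {
    prow <- match(off$info$sire[i], pop$info$id)
    mrow <- match(off$info$dam[i], pop$info$id)
    expect_true(all(off$L1[i, ] %in% c(pop$L1[prow, ], pop$L2[prow, ])))
    expect_true(all(off$L2[i, ] %in% c(pop$L1[mrow, ], pop$L2[mrow, ])))
  }
  # empty plan -> empty generation
  expect_equal(n_individuals(make_generation(pop, plan[0, ])), 0)
  # unknown parents error
  expect_error(make_generation(pop, tibble::tibble(sire = 999L, dam = 1L,
                                                   n_offspring = 1L)),
               "unknown")
})

test_that("allocate_mates honours the ratio and the avoidance rule", {
  set.seed(1)
  # ten full-sib families of ten; one sire and four dams drawn per family,
  # so a conflict-free allocation exists but naive shuffles hit sibs
  ped <- tibble::tibble(id = 1:120,
                        sire = c(rep(NA_integer_, 20), rep(1:10, each = 10)),
                        dam = c(rep(NA_integer_, 20), rep(11:20, each = 10)))
  sires <- 21L + 10L * (0:9)
  dams <- as.integer(outer(2:5, seq(20, 110, 10), `+`))
  plan <- allocate_mates(sires, dams, dams_per_sire = 4, pedigree = ped,
                         avoid = "sib", seed = 2)
  expect_equal(nrow(plan), 40)
  expect_equal(as.integer(table(plan$sire)), rep(4L, 10))
  expect_setequal(plan$dam, dams)
  m_s <- match(plan$sire, ped$id); m_d <- match(plan$dam, ped$id)
  expect_false(any(ped$sire[m_s] == ped$sire[m_d], na.rm = TRUE))
  expect_false(any(ped$dam[m_s] == ped$dam[m_d], na.rm = TRUE))

  # all candidates unrelated: any allocation valid, no warning
  expect_silent(allocate_mates(1:4, 5:20, 4, pedigree = NULL, seed = 3))

  # degenerate: every dam is a full sib of every sire -> documented fallback
  ped2 <- tibble::tibble(id = 1:12, sire = c(NA, NA, rep(1L, 10)),
                         dam = c(NA, NA, rep(2L, 10)))
  expect_warning(
    plan2 <- allocate_mates(3:4, 5:12, 4, pedigree = ped2, avoid = "full_sib",
                            max_tries = 5, seed = 4),
    "relaxed")
  expect_equal(nrow(plan2), 8)

  expect_error(allocate_mates(1:3, 1:7, 2), "dams_per_sire")
})

test_that("realized inbreeding: selfing gives E[F_r] = 0.5 and doubled haplotypes give 1", {
  pop <- mini_founders(n_per_sex = 10,
                       spec = founder_spec(c(0.5, 0.5), c(0.5, 0.5),
                                           n_founders_per_sex = 10))
  # selfed offspring of non-inbred parents
  plan <- tibble::tibble(sire = 1:10, dam = 1:10, n_offspring = 40L)
  off <- make_generation(pop, plan, seed = 6)
  fr <- realized_inbreeding(off)$F_realized
  expect_equal(mean(fr), 0.5, tolerance = 0.02)

  dh <- pop
  dh$H2 <- dh$H1; dh$L2 <- dh$L1   # doubled haploid
  expect_equal(realized_inbreeding(dh)$F_realized,
               rep(1, n_individuals(dh)))
})

test_that("allele frequencies drift without direction under random mating", {
  pop <- mini_founders(n_per_sex = 50)
  p0 <- colMeans(qtl_dosage(pop)) / 2
  drift <- replicate(8, {
    ids <- pop$info$id
    f <- ids[pop$info$sex == "F"]; m <- sample(ids[pop$info$sex == "M"])
    plan <- tibble::tibble(sire = m, dam = f, n_offspring = 2L)
    off <- make_generation(pop, plan)
    mean(colMeans(qtl_dosage(off)) / 2 - p0)
  })
  expect_equal(mean(drift), 0, tolerance = 0.01)
})

test_that("tped export round-trips alleles and family data", {
  pop <- mini_founders(n_per_sex = 3,
                       spec = founder_spec(c(0.5, 0.5), c(0.5, 0.5),
                                           n_founders_per_sex = 3))
  stem <- withr::local_tempfile()
  write_tped(pop, stem)
  tped <- utils::read.table(paste0(stem, ".tped"))
  tfam <- utils::read.table(paste0(stem, ".tfam"))
  expect_equal(nrow(tped), nrow(pop$map$loci))
  expect_equal(nrow(tfam), 6)
  expect_equal(tped[, 5] - 1L, unname(pop$H1[1, ]))  # allele codes 1/2
  expect_equal(tped[, 6] - 1L, unname(pop$H2[1, ]))
})
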