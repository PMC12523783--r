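#' Create the reference population (generation 0)
#'
#' Two parental populations in linkage equilibrium (independent loci within
#' gametes, per-locus frequencies `p1`/`p2`) are crossed to give an F1 pool;
#' one generation of random crosses among the F1 (with recombination) then
#' yields a reference population in Hardy-Weinberg equilibrium. The gametic
#' pool forming generation 0 carries the engineered LD
#' \eqn{\Delta_{ab} = (1-2\theta)/4\,(p_{a1}-p_{a2})(p_{b1}-p_{b2})}
#' (see [expected_founder_ld()]).
#'
#' Every allele copy in generation 0 receives a unique founder-origin label
#' (2 labels per individual, so identical-by-state copies are distinguished),
#' the reference for realized identity-by-descent accounting downstream.
#'
#' @param freqs tibble from [sample_allele_frequencies()].
#' @param map a `genome_map`.
#' @param n_per_sex founders of each sex (generation 0 has `2 * n_per_sex`
#'   individuals, ids 1..2n, females first).
#' @param seed integer seed.
#' @return A `population` (generation 0, unknown parents, pedigree F = 0).
#' @export
make_reference_population <- function(freqs, map, n_per_sex, seed = 1L) {
  stopifnot(inherits(map, "genome_map"))
  n_per_sex <- as.integer(n_per_sex)
  if (n_per_sex < 1) stop("n_per_sex must be >= 1", call. = FALSE)
  if (nrow(freqs) != nrow(map$loci) || !identical(freqs$id, map$loci$id))
    stop("freqs do not match the genome map", call. = FALSE)
  set.seed(seed)
  L <- nrow(map$loci)
  n0 <- 2L * n_per_sex
  n_f1 <- n0

  # F1 pool: one linkage-equilibrium gamete from each parental population
  draw_pool <- function(p)
    matrix(rbinom(n_f1 * L, 1L, rep(p, each = n_f1)), n_f1, L)
  zero <- matrix(0L, n_f1, L)
  f1 <- new_population(
    tibble::tibble(id = seq_len(n_f1),
                   sex = rep(c("F", "M"), each = n_f1 %/% 2),
                   sire = NA_integer_, dam = NA_integer_,
                   generation = -1L),
    H1 = draw_pool(freqs$p1), H2 = draw_pool(freqs$p2),
    L1 = zero, L2 = zero, map = map)

  # one round of random crosses among the F1 -> HWE generation 0
  f1_f <- which(f1$info$sex == "F"); f1_m <- which(f1$info$sex == "M")
  srow <- sample(f1_m, n0, replace = TRUE)
  drow <- sample(f1_f, n0, replace = TRUE)
  gs <- make_gametes(f1, srow)
  gd <- make_gametes(f1, drow)

  ids <- seq_len(n0)
  lab <- function(k) matrix(rep.int(2L * ids - 2L + k, L), n0, L)
  new_population(
    tibble::tibble(id = ids,
                   sex = rep(c("F", "M"), each = n_per_sex),
                   sire = NA_integer_, dam = NA_integer_,
                   generation = 0L),
    H1 = gs$H, H2 = gd$H, L1 = lab(1L), L2 = lab(2L), map = map)
}
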