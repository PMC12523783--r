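#' Population container
#'
#' A population holds, for `n` individuals over the loci of a genome map:
#' two haplotype allele matrices (`H1` paternal, `H2` maternal; 0/1 dosage of
#' allele 1), two founder-origin label matrices (`L1`, `L2`; every allele copy
#' in the reference generation gets a unique label, so identity by descent can
#' be counted exactly later, with identical-by-state copies distinguished),
#' and an `info` tibble (`id`, `sex`, `sire`, `dam`, `generation`).
#'
#' @param info tibble with columns `id`, `sex` ("F"/"M"), `sire`, `dam`
#'   (integer ids, `NA` for unknown), `generation`.
#' @param H1,H2,L1,L2 integer matrices, individuals x loci.
#' @param map the `genome_map` the columns refer to.
#' @return An object of class `population`.
#' @keywords internal
new_population <- function(info, H1, H2, L1, L2, map) {
  stopifnot(nrow(info) == nrow(H1), ncol(H1) == nrow(map$loci),
            all(dim(H1) == dim(H2)), all(dim(H1) == dim(L1)),
            all(dim(H1) == dim(L2)))
  structure(list(info = tibble::as_tibble(info), H1 = H1, H2 = H2,
                 L1 = L1, L2 = L2, map = map),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", nrow(x$info), " individuals, generation(s) ",
      paste(sort(unique(x$info$generation)), collapse = ","), ", ",
      ncol(x$H1), " loci\n", sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) nrow(pop$info)

# Batched gametes for the given parent rows; returns list(H, L).
make_gametes <- function(pop, parent_rows) {
  cr <- chrom_ranges(pop$map)
  cpp_make_gametes(pop$H1, pop$H2, pop$L1, pop$L2,
                   as.integer(parent_rows),
                   as.integer(cr$start), as.integer(cr$end),
                   pop$map$chromosomes$length_cM, pop$map$loci$pos_cM)
}

#' Simulate gametes from one parent
#'
#' Map-based meiosis: the number of crossovers per chromosome is
#' Poisson(length/100) with uniform crossover positions (Haldane map
#' function, no interference); allele states and founder-origin labels
#' travel together.
#'
#' @param pop a `population`.
#' @param parent_id id of the parent.
#' @param n number of gametes.
#' @param seed optional integer seed.
#' @return A list with matrices `H` (alleles) and `L` (founder labels),
#'   `n` x loci.
#' @export
meiosis <- function(pop, parent_id, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  row <- match(parent_id, pop$info$id)
  if (is.na(row)) stop("unknown parent id", call. = FALSE)
  make_gametes(pop, rep(row, n))
}

#' Create the next generation from a mating plan
#'
#' Each mating produces `n_offspring` full sibs; sex is assigned
#' Bernoulli(1/2); ids are sequential after `id_start`. Selfing
#' (`sire == dam`) is permitted (used for identity-by-descent checks).
#'
#' @param pop population containing all parents.
#' @param plan tibble with columns `sire`, `dam`, `n_offspring`.
#' @param seed optional integer seed.
#' @param id_start first offspring id; defaults to `max(pop$info$id) + 1`.
#' @return A `population` of the offspring (parents recorded in `info`).
#' @export
make_generation <- function(pop, plan, seed = NULL, id_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(plan) == 0)
    return(new_population(pop$info[0, ], pop$H1[0, , drop = FALSE],
                          pop$H2[0, , drop = FALSE], pop$L1[0, , drop = FALSE],
                          pop$L2[0, , drop = FALSE], pop$map))
  sr <- match(plan$sire, pop$info$id)
  dr <- match(plan$dam, pop$info$id)
  if (anyNA(sr) || anyNA(dr)) stop("mating plan refers to unknown parents",
                                   call. = FALSE)
  no <- as.integer(plan$n_offspring)
  stopifnot(all(no >= 0))
  srow <- rep(sr, no); drow <- rep(dr, no)
  gs <- make_gametes(pop, srow)
  gd <- make_gametes(pop, drow)
  n <- length(srow)
  if (is.null(id_start)) id_start <- max(pop$info$id) + 1L
  info <- tibble::tibble(
    id = seq.int(id_start, length.out = n),
    sex = ifelse(rbinom(n, 1, 0.5) == 1, "F", "M"),
    sire = rep(plan$sire, no),
    dam = rep(plan$dam, no),
    generation = max(pop$info$generation[c(sr, dr)]) + 1L
  )
  new_population(info, gs$H, gd$H, gs$L, gd$L, pop$map)
}

# Does each (sire, dam) pair violate the avoidance rule?
mating_conflicts <- function(sire_par, dam_par, avoid) {
  if (avoid == "none") return(rep(FALSE, nrow(sire_par)))
  same_s <- !is.na(sire_par$sire) & !is.na(dam_par$sire) &
    sire_par$sire == dam_par$sire
  same_d <- !is.na(sire_par$dam) & !is.na(dam_par$dam) &
    sire_par$dam == dam_par$dam
  if (avoid == "full_sib") same_s & same_d else same_s | same_d
}

#' Allocate dams to sires
#'
#' Random allocation of `dams_per_sire` dams to each sire, subject to a
#' sib-avoidance rule, by reshuffling/pairwise swaps until feasible. If no
#' conflict-free allocation is found within the attempt cap, the rule is
#' relaxed (sib -> full-sib-only -> none) with a warning.
#'
#' @param sires,dams vectors of parent ids.
#' @param dams_per_sire dams allocated to each sire; must satisfy
#'   `length(dams) == dams_per_sire * length(sires)`.
#' @param pedigree tibble with `id`, `sire`, `dam` used to identify sibs;
#'   `NULL` treats all candidates as unrelated.
#' @param avoid `"sib"` forbids both full- and half-sib matings (default),
#'   `"full_sib"` only full sibs, `"none"` no restriction.
#' @param seed optional integer seed.
#' @param max_tries attempt cap for the repair loop.
#' @return A tibble `sire`, `dam`, one row per mating.
#' @export
allocate_mates <- function(sires, dams, dams_per_sire = 5L, pedigree = NULL,
                           avoid = c("sib", "full_sib", "none"), seed = NULL,
                           max_tries = 200L) {
  avoid <- match.arg(avoid)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dams)
  if (n != dams_per_sire * length(sires))
    stop("need dams_per_sire * length(sires) dams", call. = FALSE)
  par_of <- function(ids) {
    if (is.null(pedigree)) return(list(s = integer(length(ids)),
                                       d = integer(length(ids))))
    m <- match(ids, pedigree$id)
    s <- pedigree$sire[m]; d <- pedigree$dam[m]
    list(s = ifelse(is.na(s), 0L, s), d = ifelse(is.na(d), 0L, d))
  }
  sire_slot <- rep(sires, each = dams_per_sire)
  sp <- par_of(sire_slot)          # parents of the sire in each slot
  dp <- par_of(dams)               # parents of each dam (dam order fixed)
  # conflict of every slot i with the dam currently in it (perm = dam index)
  conf <- function(perm, rule) {
    if (rule == "none") return(rep(FALSE, n))
    same_s <- sp$s != 0L & sp$s == dp$s[perm]
    same_d <- sp$d != 0L & sp$d == dp$d[perm]
    if (rule == "full_sib") same_s & same_d else same_s | same_d
  }
  for (rule in unique(c(avoid, "full_sib", "none"))) {
    perm <- sample.int(n)
    for (try in seq_len(max_tries)) {
      bad <- which(conf(perm, rule))
      if (length(bad) == 0L) {
        if (rule != avoid)
          warning("sib-avoidance relaxed to '", rule, "'", call. = FALSE)
        return(tibble::tibble(sire = sire_slot, dam = dams[perm]))
      }
      # swap repair: move each conflicted dam to a slot where both pairs
      # become conflict-free
      for (i in bad) {
        di <- perm[i]
        # slot i with every dam; every slot with dam di
        ci <- if (rule == "full_sib")
          (sp$s[i] != 0L & sp$s[i] == dp$s) & (sp$d[i] != 0L & sp$d[i] == dp$d)
        else (sp$s[i] != 0L & sp$s[i] == dp$s) |
             (sp$d[i] != 0L & sp$d[i] == dp$d)
        cj <- if (rule == "full_sib")
          (sp$s != 0L & sp$s == dp$s[di]) & (sp$d != 0L & sp$d == dp$d[di])
        else (sp$s != 0L & sp$s == dp$s[di]) |
             (sp$d != 0L & sp$d == dp$d[di])
        ok <- which(!ci[perm] & !cj)
        ok <- ok[ok != i]
        if (length(ok)) {
          j <- if (length(ok) == 1L) ok else sample(ok, 1L)
          perm[c(i, j)] <- perm[c(j, i)]
        }
      }
      if (!any(conf(perm, rule))) {
        if (rule != avoid)
          warning("sib-avoidance relaxed to '", rule, "'", call. = FALSE)
        return(tibble::tibble(sire = sire_slot, dam = dams[perm]))
      }
      perm <- sample.int(n)
    }
  }
  stop("no feasible mating allocation", call. = FALSE)  # unreachable: none
}

#' SNP allele-1 dosage matrix
#'
#' @param pop a `population`.
#' @return Integer matrix (individuals x SNPs) of allele-1 dosages in
#'   \{0, 1, 2\}; rownames are individual ids.
#' @export
snp_dosage <- function(pop) {
  j <- which(pop$map$loci$type == "snp")
  m <- pop$H1[, j, drop = FALSE] + pop$H2[, j, drop = FALSE]
  dimnames(m) <- list(pop$info$id, pop$map$loci$id[j])
  m
}

#' Favorable-allele dosage matrix at QTL
#'
#' Allele 1 at a QTL is the favorable (trait-decreasing) allele.
#'
#' @param pop a `population`.
#' @return Integer matrix (individuals x QTL); rownames are individual ids.
#' @export
qtl_dosage <- function(pop) {
  j <- which(pop$map$loci$type == "qtl")
  m <- pop$H1[, j, drop = FALSE] + pop$H2[, j, drop = FALSE]
  dimnames(m) <- list(pop$info$id, pop$map$loci$id[j])
  m
}

#' Realized inbreeding from founder-origin labels
#'
#' Fraction of loci at which an individual's two allele copies carry the same
#' founder-origin label, i.e. are identical by descent relative to the
#' reference generation.
#'
#' @param pop a `population`.
#' @return A tibble `id`, `F_realized`.
#' @export
realized_inbreeding <- function(pop) {
  tibble::tibble(id = pop$info$id,
                 F_realized = cpp_realized_F(pop$L1, pop$L2))
}

#' Export genotypes in transposed PLINK text dialect
#'
#' Writes `<stem>.tped` (chromosome, id, cM position in the genetic-distance
#' column, 0 bp, then two allele columns per individual coded 1/2) and
#' `<stem>.tfam` (family = generation, id, sire, dam, sex, -9).
#'
#' @param pop a `population`.
#' @param stem output path without extension.
#' @return The two paths, invisibly.
#' @export
write_tped <- function(pop, stem) {
  loci <- pop$map$loci
  al <- function(h) h + 1L  # 0/1 -> 1/2 allele codes
  g <- matrix(0L, nrow(loci), 2L * nrow(pop$info))
  g[, seq(1, ncol(g), 2)] <- t(al(pop$H1))
  g[, seq(2, ncol(g), 2)] <- t(al(pop$H2))
  tped <- cbind(loci$chrom, loci$id, format(loci$pos_cM, trim = TRUE), 0L, g)
  utils::write.table(tped, paste0(stem, ".tped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  info <- pop$info
  tfam <- cbind(info$generation, info$id,
                ifelse(is.na(info$sire), 0L, info$sire),
                ifelse(is.na(info$dam), 0L, info$dam),
                ifelse(info$sex == "M", 1L, 2L), -9L)
  utils::write.table(tfam, paste0(stem, ".tfam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(stem, ".tped"), paste0(stem, ".tfam")))
}
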