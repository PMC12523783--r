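#' Default per-chromosome lengths and locus counts
#'
#' The default genome mirrors a broiler-chicken style map: 10 chromosomes
#' with lengths declining from 199.4 cM (chromosome 1) to 25.7 cM
#' (chromosome 10), carrying 38,500 SNPs (10,000 down to 1,250) and 1,000
#' QTL (260 down to 30). Only the two endpoints and the totals are pinned;
#' intermediate chromosomes are interpolated with a power law
#' \eqn{v_i = v_{10} + (v_1 - v_{10})\,((10-i)/9)^\gamma}, with \eqn{\gamma}
#' solved per quantity so the totals are exact. A linear interpolation of the
#' same endpoints would imply a 1125.5 cM map, inconsistent with the average
#' marker spacing of 0.02 cM (and gene spacing 0.77 cM) that a 770 cM map
#' gives; the power law honours endpoints, totals and densities at once.
#' Counts are rounded and the remainder absorbed by the largest interior
#' chromosome, keeping the printed endpoints exact.
#'
#' @param n_chr number of chromosomes.
#' @param len_ends,len_total first/last chromosome length (cM) and total map
#'   length.
#' @param snp_ends,snp_total first/last chromosome SNP counts and total.
#' @param qtl_ends,qtl_total first/last chromosome QTL counts and total.
#' @return A tibble with columns `chrom`, `length_cM`, `n_snp`, `n_qtl`.
#' @export
chromosome_table <- function(n_chr = 10L,
                             len_ends = c(199.4, 25.7), len_total = 770,
                             snp_ends = c(10000L, 1250L), snp_total = 38500L,
                             qtl_ends = c(260L, 30L), qtl_total = 1000L) {
  stopifnot(n_chr >= 2)
  interp <- function(ends, total) {
    v1 <- ends[1]; vn <- ends[2]
    target <- (total - n_chr * vn) / (v1 - vn)
    if (n_chr == 2) {  # endpoints only: totals must already be consistent
      if (abs(total - v1 - vn) > 1e-8)
        stop("totals inconsistent with per-chromosome endpoints",
             call. = FALSE)
      return(c(v1, vn))
    }
    if (target <= 1 || target >= n_chr - 1)
      stop("totals inconsistent with per-chromosome endpoints", call. = FALSE)
    frac <- (n_chr - seq_len(n_chr)) / (n_chr - 1)
    g <- uniroot(function(g) sum(frac^g) - target, c(1e-3, 50))$root
    vn + (v1 - vn) * frac^g
  }
  len <- interp(len_ends, len_total)
  round_fix <- function(v, total) {
    x <- round(v)
    # absorb rounding drift on the largest interior chromosome so the
    # printed first/last endpoints stay exact
    j <- if (n_chr > 2) 2L else 1L
    x[j] <- x[j] + (total - sum(x))
    if (any(x < 1)) stop("totals inconsistent with per-chromosome counts",
                         call. = FALSE)
    as.integer(x)
  }
  tibble::tibble(
    chrom = seq_len(n_chr),
    length_cM = len,
    n_snp = round_fix(interp(as.double(snp_ends), snp_total), snp_total),
    n_qtl = round_fix(interp(as.double(qtl_ends), qtl_total), qtl_total)
  )
}

#' Build a genome map
#'
#' Places SNPs and QTL at uniformly distributed random positions on each
#' chromosome. SNP and QTL position sets are disjoint (exact ties are
#' resampled; they have probability ~0 under continuous uniforms).
#'
#' @param chromosomes a tibble as returned by [chromosome_table()] with
#'   columns `chrom`, `length_cM`, `n_snp`, `n_qtl`.
#' @param seed integer seed.
#' @return An object of class `genome_map`: a list with `chromosomes` and a
#'   `loci` tibble (`chrom`, `id`, `pos_cM`, `type` in `snp`/`qtl`), loci
#'   sorted by chromosome then position.
#' @examples
#' g <- build_genome(chromosome_table(), seed = 1)
#' sum(g$loci$type == "snp")  # 38500
#' @export
build_genome <- function(chromosomes = chromosome_table(), seed = 1L) {
  need <- c("chrom", "length_cM", "n_snp", "n_qtl")
  if (!all(need %in% names(chromosomes)))
    stop("chromosome table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(chromosomes$n_snp < 0) || any(chromosomes$n_qtl < 0) ||
      any(chromosomes$length_cM <= 0))
    stop("invalid chromosome configuration", call. = FALSE)
  set.seed(seed)
  loci <- purrr::pmap_dfr(chromosomes, function(chrom, length_cM, n_snp, n_qtl) {
    repeat {
      ps <- sort(runif(n_snp, 0, length_cM))
      pq <- sort(runif(n_qtl, 0, length_cM))
      if (!anyDuplicated(c(ps, pq))) break  # enforce SNP/QTL disjointness
    }
    tibble::tibble(
      chrom = chrom,
      id = c(sprintf("C%02dS%05d", chrom, seq_len(n_snp)),
             sprintf("C%02dQ%04d", chrom, seq_len(n_qtl))),
      pos_cM = c(ps, pq),
      type = rep(c("snp", "qtl"), c(n_snp, n_qtl))
    )
  })
  loci <- dplyr::arrange(loci, .data$chrom, .data$pos_cM)
  structure(list(chromosomes = chromosomes, loci = loci),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", nrow(x$chromosomes), " chromosomes, ",
      sum(x$loci$type == "snp"), " SNPs, ", sum(x$loci$type == "qtl"),
      " QTL, ", round(sum(x$chromosomes$length_cM), 1), " cM\n", sep = "")
  invisible(x)
}

# Column index ranges per chromosome in loci order.
chrom_ranges <- function(map) {
  idx <- split(seq_len(nrow(map$loci)), map$loci$chrom)
  list(start = vapply(idx, min, 1L), end = vapply(idx, max, 1L))
}

#' Founder design specification
#'
#' Mean allele frequencies for the two parental populations whose cross
#' creates the reference population. SNP means are minor-allele frequency
#' targets; QTL means are favorable-allele (trait-decreasing) frequency
#' targets. Per-locus frequencies are drawn from Beta(mu*nu, (1-mu)*nu).
#'
#' @param snp_maf length-2 mean SNP allele-1 frequencies (parental
#'   populations 1 and 2).
#' @param qtl_fav length-2 mean favorable-allele frequencies.
#' @param concentration beta concentration nu (> 0); larger is tighter.
#' @param n_founders_per_sex founders of each sex in the reference
#'   population.
#' @return A `founder_spec` list.
#' @export
founder_spec <- function(snp_maf = c(0.1, 0.5), qtl_fav = c(0.3, 0.9),
                         concentration = 10, n_founders_per_sex = 400L) {
  stopifnot(length(snp_maf) == 2, length(qtl_fav) == 2)
  if (any(c(snp_maf, qtl_fav) <= 0) || any(c(snp_maf, qtl_fav) >= 1))
    stop("frequency means must lie in (0, 1)", call. = FALSE)
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  if (n_founders_per_sex < 1)
    stop("n_founders_per_sex must be >= 1", call. = FALSE)
  structure(list(snp_maf = snp_maf, qtl_fav = qtl_fav,
                 concentration = concentration,
                 n_founders_per_sex = as.integer(n_founders_per_sex)),
            class = "founder_spec")
}

#' Sample per-locus allele frequencies for the two parental populations
#'
#' Allele-1 frequency of every locus is drawn from a beta distribution with
#' the spec's mean (SNP MAF mean for SNPs, favorable-allele mean for QTL)
#' and concentration `nu`: Beta(mu*nu, (1-mu)*nu). Allele 1 is the
#' favorable (trait-decreasing) allele at QTL.
#'
#' When the two parental means are equal the two populations are one and the
#' same: each locus gets a single draw shared by both (`p1 == p2`), so the
#' founder cross generates no LD and the reference population is in linkage
#' equilibrium. Divergent means are drawn independently per population,
#' giving the systematic frequency differences that engineer LD.
#'
#' @param spec a [founder_spec()].
#' @param map a [build_genome()] map.
#' @param seed integer seed.
#' @return A tibble with `id`, `type`, `p1`, `p2` in loci order.
#' @export
sample_allele_frequencies <- function(spec, map, seed = 1L) {
  stopifnot(inherits(spec, "founder_spec"), inherits(map, "genome_map"))
  set.seed(seed)
  loci <- map$loci
  is_snp <- loci$type == "snp"
  draw <- function(mu, n) rbeta(n, mu * spec$concentration,
                                (1 - mu) * spec$concentration)
  p1 <- p2 <- numeric(nrow(loci))
  p1[is_snp] <- draw(spec$snp_maf[1], sum(is_snp))
  p2[is_snp] <- if (spec$snp_maf[1] == spec$snp_maf[2]) p1[is_snp] else
    draw(spec$snp_maf[2], sum(is_snp))
  p1[!is_snp] <- draw(spec$qtl_fav[1], sum(!is_snp))
  p2[!is_snp] <- if (spec$qtl_fav[1] == spec$qtl_fav[2]) p1[!is_snp] else
    draw(spec$qtl_fav[2], sum(!is_snp))
  tibble::tibble(id = loci$id, type = loci$type, p1 = p1, p2 = p2)
}

#' Expected founder linkage disequilibrium
#'
#' Closed-form LD in the gametic pool that forms the reference population
#' when two parental populations in linkage equilibrium are crossed:
#' \deqn{\Delta_{ab} = \frac{1-2\theta}{4}(p_{a1}-p_{a2})(p_{b1}-p_{b2})}
#' where \eqn{\theta} is the recombination fraction between the loci and
#' \eqn{p_{\cdot 1}, p_{\cdot 2}} are allele frequencies in the two parental
#' populations.
#'
#' @param theta recombination fraction in \[0, 0.5\].
#' @param p_a1,p_a2,p_b1,p_b2 allele frequencies in \[0, 1\].
#' @return The LD value (vectorized).
#' @examples
#' expected_founder_ld(0, 0.1, 0.5, 0.1, 0.5)  # 0.04
#' @export
expected_founder_ld <- function(theta, p_a1, p_a2, p_b1, p_b2) {
  if (any(theta < 0 | theta > 0.5))
    stop("theta must lie in [0, 0.5]", call. = FALSE)
  if (any(c(p_a1, p_a2, p_b1, p_b2) < 0 | c(p_a1, p_a2, p_b1, p_b2) > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  (1 - 2 * theta) / 4 * (p_a1 - p_a2) * (p_b1 - p_b2)
}

#' Haldane map distance to recombination fraction
#'
#' @param d map distance in cM.
#' @return Recombination fraction (1 - exp(-2d/100)) / 2.
#' @export
haldane_theta <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Write a genome map to a tab-separated file
#'
#' Columns: chromosome, id, cM position, type (`snp`/`qtl`).
#'
#' @param map a `genome_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_map <- function(map, path) {
  stopifnot(inherits(map, "genome_map"))
  utils::write.table(map$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
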