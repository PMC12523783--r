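#' Derive per-QTL genetic effects from genotypic bounds
#'
#' Parameters `m` (homozygote midpoint) and `a` (half-range) are derived from
#' the minimum and maximum genotypic values for homozygotes (ignoring
#' epistasis): summed over QTL, `sum(m + a) = g_max` and `sum(m - a) = g_min`
#' exactly. The dominance deviation is `d = degree * a`, positive toward the
#' superior (trait-increasing, unfavorable for a feed-conversion-ratio style
#' trait) homozygote, i.e. the favorable allele is (partially) recessive.
#'
#' @param g_min,g_max genotypic bounds for homozygotes.
#' @param n_qtl number of QTL.
#' @param degrees per-QTL degree of dominance in \[0, 1.2\]; default sampled
#'   uniformly on `dominance_range` (mean 0.6 under the default range).
#' @param dominance_range range for sampled degrees.
#' @param allocation `"equal"` gives every QTL the same `a`; `"geometric"`
#'   allocates `a` proportional to `0.99^i`, rescaled so the bound sums are
#'   exact.
#' @param seed optional integer seed.
#' @return A tibble `qtl`, `m`, `a`, `d`, `degree`.
#' @examples
#' derive_gene_effects(1.1, 2.9, 1)  # m = 2, a = 0.9
#' @export
derive_gene_effects <- function(g_min, g_max, n_qtl, degrees = NULL,
                                dominance_range = c(0, 1.2),
                                allocation = c("equal", "geometric"),
                                seed = NULL) {
  allocation <- match.arg(allocation)
  if (n_qtl < 1) stop("n_qtl must be >= 1", call. = FALSE)
  if (g_max <= g_min) stop("g_max must exceed g_min", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(degrees))
    degrees <- runif(n_qtl, dominance_range[1], dominance_range[2])
  if (length(degrees) == 1) degrees <- rep(degrees, n_qtl)
  stopifnot(length(degrees) == n_qtl)
  if (any(degrees < 0 | degrees > 1.2))
    stop("degrees of dominance must lie in [0, 1.2]", call. = FALSE)
  a_tot <- (g_max - g_min) / 2
  w <- switch(allocation, equal = rep(1, n_qtl), geometric = 0.99^seq_len(n_qtl))
  a <- a_tot * w / sum(w)
  m <- rep((g_max + g_min) / (2 * n_qtl), n_qtl)
  tibble::tibble(qtl = seq_len(n_qtl), m = m, a = a, d = degrees * a,
                 degree = degrees)
}

#' The seven constrained digenic epistasis types
#'
#' Classical two-locus interaction patterns named by their F2 phenotypic
#' ratios: complementary (9:7), duplicate (15:1), dominant (12:3:1),
#' recessive (9:3:4), dominant-and-recessive (13:3), duplicate genes with
#' cumulative effects (9:6:1), and non-epistatic gene interaction (all four
#' dominance classes distinct).
#'
#' @return Character vector of type names.
#' @export
epistasis_types <- function() {
  c("complementary", "duplicate", "dominant", "recessive",
    "dominant_and_recessive", "duplicate_cumulative",
    "non_epistatic_interaction")
}

#' Phenotypic-class partition of the nine two-locus genotypes
#'
#' Rows index the dosage `x` (0, 1, 2) of the dominant allele at the first
#' locus, columns the dosage `y` at the second. Class 1 always contains the
#' double dominant homozygote (2, 2).
#'
#' @param type one of [epistasis_types()].
#' @return A 3x3 integer matrix of class labels.
#' @export
epistasis_partition <- function(type) {
  x <- matrix(rep(0:2, 3), 3, 3)          # dosage at locus i
  y <- t(x)                               # dosage at locus j
  A <- x >= 1; B <- y >= 1                # dominance classes
  cls <- switch(type,
    complementary = ifelse(A & B, 1L, 2L),
    duplicate = ifelse(A | B, 1L, 2L),
    dominant = ifelse(A, 1L, ifelse(B, 2L, 3L)),
    recessive = ifelse(A & B, 1L, ifelse(A, 2L, 3L)),
    dominant_and_recessive = ifelse(A | (!A & !B), 1L, 2L),
    duplicate_cumulative = ifelse(A & B, 1L, ifelse(A | B, 2L, 3L)),
    non_epistatic_interaction =
      ifelse(A & B, 1L, ifelse(A, 2L, ifelse(B, 3L, 4L))),
    stop("unknown epistasis type: ", type, call. = FALSE))
  dimnames(cls) <- list(x = 0:2, y = 0:2)
  cls
}

#' Assign disjoint epistatic pairs
#'
#' A fraction of the QTL interact in disjoint pairs; each QTL belongs to at
#' most one pair. Under the `"all_random"` policy each pair's type is drawn
#' uniformly from the seven types; a single type name fixes all pairs. With a
#' fixed seed the pairing is identical across type policies, so single-type
#' scenarios share their pairs.
#'
#' @param qtl_ids vector of QTL identifiers.
#' @param fraction fraction of QTL that interact, in \[0, 1\].
#' @param type_policy `"all_random"` or one of [epistasis_types()].
#' @param seed optional integer seed.
#' @return A tibble `qtl_i`, `qtl_j`, `type`.
#' @export
assign_epistatic_pairs <- function(qtl_ids, fraction, type_policy = "all_random",
                                   seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_int <- round(fraction * length(qtl_ids))
  if (n_int %% 2 == 1) {
    warning("odd number of interacting genes; reduced by one", call. = FALSE)
    n_int <- n_int - 1
  }
  if (n_int < 2)
    return(tibble::tibble(qtl_i = qtl_ids[0], qtl_j = qtl_ids[0],
                          type = character(0)))
  chosen <- sample(qtl_ids, n_int)
  i <- chosen[seq(1, n_int, 2)]
  j <- chosen[seq(2, n_int, 2)]
  types <- if (identical(type_policy, "all_random"))
    sample(epistasis_types(), n_int / 2, replace = TRUE)
  else {
    if (!type_policy %in% epistasis_types())
      stop("unknown epistasis type: ", type_policy, call. = FALSE)
    rep(type_policy, n_int / 2)
  }
  tibble::tibble(qtl_i = i, qtl_j = j, type = types)
}

# Single-locus genotypic contributions for dosages x = 0,1,2 of the
# trait-increasing allele: m - a, m + d, m + a.
locus_values <- function(m, a, d) m + c(-a, d, a)

#' Single-locus variance components at Hardy-Weinberg equilibrium
#'
#' For a locus with frequency `p` of the trait-increasing allele and effects
#' `a`, `d`: additive variance `2pq[a + d(q - p)]^2`, dominance variance
#' `(2pqd)^2`. The additive-dominance covariance is zero under HWE (the
#' deviations are orthogonal) and nonzero only under inbreeding; it is
#' returned for interface completeness.
#'
#' @param p frequency of the trait-increasing allele.
#' @param a,d half-range and dominance deviation.
#' @return A list `sigma_A2`, `sigma_D2`, `sigma_AD`.
#' @export
locus_varcomp <- function(p, a, d) {
  q <- 1 - p
  list(sigma_A2 = 2 * p * q * (a + d * (q - p))^2,
       sigma_D2 = (2 * p * q * d)^2,
       sigma_AD = 0)
}

#' Sample the anchor epistatic effect I22
#'
#' The epistatic effect of the double superior homozygote is drawn from
#' Normal(0, k(sigma_A^2 + sigma_D^2 + 2 sigma_AD)), with the variances and
#' covariance summed over the two interacting loci at their current allele
#' frequencies.
#'
#' @param k positive scale factor (study default 1.5).
#' @param sigma_A2,sigma_D2,sigma_AD assembled variance pieces for the pair.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric draws of length `n`.
#' @export
sample_I22 <- function(k, sigma_A2, sigma_D2, sigma_AD = 0, n = 1L,
                       seed = NULL) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- k * (sigma_A2 + sigma_D2 + 2 * sigma_AD)
  if (v < 0) {
    warning("assembled I22 variance negative; clamped to 0", call. = FALSE)
    v <- 0
  }
  rnorm(n, 0, sqrt(v))
}

#' Solve the nine epistatic effects for a constrained type
#'
#' Two-locus genotypic values are `G_xy = m_i + m_j + alpha_x + alpha_y +
#' I_xy` with `alpha` the single-locus contribution (`a`, `d`, `-a` for
#' dosages 2, 1, 0). The type's partition forces `G` to be constant within
#' each phenotypic class: the class containing (2,2) takes the value
#' `m_i + m_j + a_i + a_j + I22`; each remaining class is anchored by setting
#' the epistatic effect of its reference genotype (the member with the lowest
#' `(x, y)` code) to zero, i.e. that class keeps its non-epistatic value.
#'
#' @param effect_i,effect_j lists/rows with `m`, `a`, `d`.
#' @param type one of [epistasis_types()].
#' @param I22 epistatic effect of the (2,2) genotype (see [sample_I22()]).
#' @return A list with the 3x3 matrices `I` (epistatic effects) and `G`
#'   (genotypic values), and `classes` (the partition). Rows/columns index
#'   dosages 0, 1, 2.
#' @export
solve_epistatic_effects <- function(effect_i, effect_j, type, I22) {
  cls <- epistasis_partition(type)
  B <- outer(locus_values(effect_i$m, effect_i$a, effect_i$d),
             locus_values(effect_j$m, effect_j$a, effect_j$d), `+`)
  dimnames(B) <- dimnames(cls)
  V <- numeric(max(cls))
  V[cls[3, 3]] <- B[3, 3] + I22
  for (cl in setdiff(seq_len(max(cls)), cls[3, 3])) {
    members <- which(cls == cl, arr.ind = TRUE)
    ref <- members[order(members[, 1], members[, 2])[1], , drop = FALSE]
    V[cl] <- B[ref]
  }
  G <- matrix(V[cls], 3, 3, dimnames = dimnames(cls))
  list(I = G - B, G = G, classes = cls)
}

#' Kempthorne orthogonal decomposition of a two-locus genotype table
#'
#' Least-squares partition of the nine genotypic values into additive,
#' dominance, additive x additive, additive x dominance, dominance x additive
#' and dominance x dominance components, under Hardy-Weinberg genotype
#' frequencies at each locus and linkage equilibrium between them. The
#' partition uses the orthogonal single-locus contrasts
#' `alpha(x) = x - 2p` and `delta(x) = (-2p^2, 2pq, -2q^2)` and their
#' products; because the basis is orthogonal under the HWE x HWE weights the
#' projections are exact and the component variances sum to the total
#' genotypic variance.
#'
#' @param G_table 3x3 genotypic values, rows = dosage 0,1,2 of the counted
#'   allele at locus i, columns = locus j.
#' @param p_i,p_j frequencies of the counted alleles.
#' @return A list: `components` tibble (component, variance), scalar
#'   `sigma_AD` (zero at HWE), `mean`, `total_variance`, and `values` (a list
#'   of 3x3 per-genotype genetic-value tables per component).
#' @export
kempthorne_decompose <- function(G_table, p_i, p_j) {
  stopifnot(all(dim(G_table) == c(3, 3)))
  basis1 <- function(p) {
    q <- 1 - p
    list(f = c(q^2, 2 * p * q, p^2),
         A = c(0, 1, 2) - 2 * p,
         D = c(-2 * p^2, 2 * p * q, -2 * q^2))
  }
  bi <- basis1(p_i); bj <- basis1(p_j)
  w <- outer(bi$f, bj$f)                       # HWE x LE genotype weights
  one <- matrix(1, 3, 3)
  B <- list(A_i = outer(bi$A, rep(1, 3)), D_i = outer(bi$D, rep(1, 3)),
            A_j = outer(rep(1, 3), bj$A), D_j = outer(rep(1, 3), bj$D))
  B$AxA <- B$A_i * B$A_j; B$AxD <- B$A_i * B$D_j
  B$DxA <- B$D_i * B$A_j; B$DxD <- B$D_i * B$D_j
  mu <- sum(w * G_table)
  proj <- function(b) {
    nb <- sum(w * b^2)
    if (nb < 1e-12) 0 else sum(w * G_table * b) / nb
  }
  beta <- vapply(B, proj, 0)
  values <- lapply(names(B), function(nm) beta[nm] * B[[nm]])
  names(values) <- names(B)
  cvar <- vapply(names(B), function(nm) sum(w * values[[nm]]^2), 0)
  comp <- tibble::tibble(
    component = c("A", "D", "AxA", "AxD", "DxA", "DxD"),
    variance = unname(c(cvar["A_i"] + cvar["A_j"], cvar["D_i"] + cvar["D_j"],
                        cvar["AxA"], cvar["AxD"], cvar["DxA"], cvar["DxD"])))
  add <- values$A_i + values$A_j
  dom <- values$D_i + values$D_j
  list(components = comp,
       sigma_AD = sum(w * add * dom),
       mean = mu,
       total_variance = sum(w * (G_table - mu)^2),
       values = c(list(additive = add, dominance = dom),
                  values[c("AxA", "AxD", "DxA", "DxD")]))
}

#' Construct a trait architecture
#'
#' Bundles per-QTL effects, optional constrained digenic epistasis, trait
#' bounds and heritability. Epistatic effect tables are solved once at the
#' reference generation and fixed thereafter (effects are properties of
#' genotypes, not of frequencies).
#'
#' @param map a `genome_map`.
#' @param g_min,g_max genotypic bounds for homozygotes (study: 1.1, 2.9).
#' @param y_min,y_max phenotypic truncation bounds (study: 1.0, 3.5).
#' @param H2 broad-sense heritability, in (0, 1) (study: 0.30).
#' @param epistasis `NULL` for additive-dominance, or a list with `fraction`
#'   (of interacting QTL), `type` (`"all_random"` or a type name) and `k`
#'   (I22 scale, study default 1.5).
#' @param fav_freq per-QTL favorable-allele frequencies used to assemble the
#'   I22 sampling variance (typically realized generation-0 frequencies);
#'   required when `epistasis` is given.
#' @param degrees,dominance_range,allocation passed to
#'   [derive_gene_effects()].
#' @param seed integer seed.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(map, g_min = 1.1, g_max = 2.9, y_min = 1.0,
                               y_max = 3.5, H2 = 0.3, epistasis = NULL,
                               fav_freq = NULL, degrees = NULL,
                               dominance_range = c(0, 1.2),
                               allocation = "equal", seed = 1L) {
  stopifnot(inherits(map, "genome_map"))
  if (H2 <= 0 || H2 >= 1) stop("H2 must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  qtl_ids <- map$loci$id[map$loci$type == "qtl"]
  eff <- derive_gene_effects(g_min, g_max, length(qtl_ids), degrees = degrees,
                             dominance_range = dominance_range,
                             allocation = allocation)
  eff$qtl <- qtl_ids
  pairs <- tibble::tibble(qtl_i = character(0), qtl_j = character(0),
                          type = character(0), I22 = numeric(0),
                          I = list())
  k <- NA_real_
  if (!is.null(epistasis)) {
    stopifnot(is.list(epistasis))
    k <- if (is.null(epistasis$k)) 1.5 else epistasis$k
    if (is.null(fav_freq))
      stop("fav_freq required to assemble the I22 variance", call. = FALSE)
    pr <- assign_epistatic_pairs(qtl_ids, epistasis$fraction,
                                 type_policy = epistasis$type %||% "all_random")
    if (nrow(pr)) {
      sol <- purrr::pmap(pr, function(qtl_i, qtl_j, type) {
        ei <- eff[match(qtl_i, eff$qtl), ]
        ej <- eff[match(qtl_j, eff$qtl), ]
        # p of the counted (trait-increasing) allele = 1 - favorable freq
        vi <- locus_varcomp(1 - fav_freq[[qtl_i]], ei$a, ei$d)
        vj <- locus_varcomp(1 - fav_freq[[qtl_j]], ej$a, ej$d)
        I22 <- sample_I22(k, vi$sigma_A2 + vj$sigma_A2,
                          vi$sigma_D2 + vj$sigma_D2,
                          vi$sigma_AD + vj$sigma_AD)
        list(I22 = I22,
             I = solve_epistatic_effects(ei, ej, type, I22)$I)
      })
      pr$I22 <- vapply(sol, `[[`, 0, "I22")
      pr$I <- lapply(sol, `[[`, "I")
      pairs <- pr
    }
  }
  structure(list(effects = eff, pairs = pairs, g_min = g_min, g_max = g_max,
                 y_min = y_min, y_max = y_max, H2 = H2, k = k),
            class = "trait_architecture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", nrow(x$effects), " QTL, ", nrow(x$pairs),
      " epistatic pairs, H2 = ", x$H2, ", genotypic bounds [", x$g_min, ", ",
      x$g_max, "]\n", sep = "")
  invisible(x)
}

#' True genotypic values
#'
#' Sum over non-interacting QTL of the single-locus values plus, for each
#' epistatic pair, the two-locus value including the epistatic effect. The
#' double superior homozygote of a pair has value
#' `m_i + m_j + a_i + a_j + I22`.
#'
#' @param pop a `population`, or a favorable-allele dosage matrix
#'   (individuals x QTL, see [qtl_dosage()]).
#' @param arch a `trait_architecture`.
#' @return Named numeric vector of genotypic values.
#' @export
genotypic_value <- function(pop, arch) {
  fav <- if (inherits(pop, "population")) qtl_dosage(pop) else pop
  stopifnot(ncol(fav) == nrow(arch$effects))
  X <- 2L - fav                                 # dosage of increasing allele
  g <- sum(arch$effects$m) +
    (X - 1L) %*% arch$effects$a +
    (X == 1L) %*% arch$effects$d
  g <- drop(g)
  if (nrow(arch$pairs)) {
    ii <- match(arch$pairs$qtl_i, arch$effects$qtl)
    jj <- match(arch$pairs$qtl_j, arch$effects$qtl)
    for (r in seq_len(nrow(arch$pairs))) {
      Imat <- arch$pairs$I[[r]]
      g <- g + Imat[cbind(X[, ii[r]] + 1L, X[, jj[r]] + 1L)]
    }
  }
  names(g) <- rownames(fav)
  g
}

#' Phenotypes at fixed broad-sense heritability
#'
#' Error effects are sampled from a normal distribution with variance
#' `var(g) * (1 - H2) / H2`, calibrated to the realized genotypic variance of
#' the cohort, so broad-sense heritability is held at `H2` in every
#' generation. Phenotypes are truncated into `[y_min, y_max]` to avoid
#' outliers; a warning is raised if truncation affects more than 1% of
#' records.
#'
#' @param g genotypic values.
#' @param H2 broad-sense heritability in (0, 1).
#' @param y_min,y_max phenotypic bounds.
#' @param seed optional integer seed.
#' @param sigma_e optional fixed error SD; used (with a warning) when the
#'   cohort genotypic variance is zero, e.g. the value carried over from the
#'   last generation with nonzero variance.
#' @return Numeric phenotypes with attribute `sigma_e`.
#' @export
phenotype <- function(g, H2 = 0.3, y_min = 1.0, y_max = 3.5, seed = NULL,
                      sigma_e = NULL) {
  if (H2 <= 0 || H2 >= 1) stop("H2 must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vg <- var(g)
  if (is.na(vg) || vg <= 0) {
    if (is.null(sigma_e))
      stop("zero genotypic variance and no fallback sigma_e", call. = FALSE)
    warning("zero genotypic variance; using supplied sigma_e", call. = FALSE)
    se <- sigma_e
  } else se <- sqrt(vg * (1 - H2) / H2)
  y <- g + rnorm(length(g), 0, se)
  n_trunc <- sum(y < y_min | y > y_max)
  if (n_trunc > 0.01 * length(y))
    warning(sprintf("phenotype truncation affected %.1f%% of records",
                    100 * n_trunc / length(y)), call. = FALSE)
  y <- pmin(pmax(y, y_min), y_max)
  attr(y, "sigma_e") <- se
  y
}

#' Serialize / restore a trait architecture as JSON
#'
#' @param arch a `trait_architecture`.
#' @param path file path.
#' @return `path` invisibly; `read_architecture()` returns the restored
#'   object.
#' @export
write_architecture <- function(arch, path) {
  obj <- list(effects = arch$effects,
              pairs = dplyr::mutate(arch$pairs,
                                    I = lapply(.data$I, function(m)
                                      as.list(as.data.frame(m)))),
              g_min = arch$g_min, g_max = arch$g_max, y_min = arch$y_min,
              y_max = arch$y_max, H2 = arch$H2, k = arch$k)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- tibble::as_tibble(obj$pairs)
  if (nrow(pairs)) {
    pairs$I <- lapply(seq_len(nrow(pairs)), function(r) {
      m <- matrix(unlist(obj$pairs$I[r, ]), 3, 3,
                  dimnames = list(x = 0:2, y = 0:2))
      m
    })
  } else pairs <- tibble::tibble(qtl_i = character(0), qtl_j = character(0),
                                 type = character(0), I22 = numeric(0),
                                 I = list())
  structure(list(effects = tibble::as_tibble(obj$effects), pairs = pairs,
                 g_min = obj$g_min, g_max = obj$g_max, y_min = obj$y_min,
                 y_max = obj$y_max, H2 = obj$H2,
                 k = if (is.null(obj$k)) NA_real_ else obj$k),
            class = "trait_architecture")
}
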