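#' Selection scheme configuration
#'
#' Eight named schemes over a common design (selected dams/sires, 5 dams per
#' sire, fixed progeny size, truncation selection minimizing the trait):
#' \describe{
#'   \item{GS}{genomic selection; training set = founders plus a random 20%
#'     of every generation (model updating with historical data).}
#'   \item{GS1}{genomic selection, founders only as training set (no model
#'     updating).}
#'   \item{GS2}{genomic selection with a 10% per-generation training sample.}
#'   \item{GS3}{genomic selection at doubled selection intensity: half the
#'     dams/sires, doubled progeny size (candidate numbers unchanged).}
#'   \item{GV}{truncation on the true genotypic value (upper reference).}
#'   \item{pbB}{pedigree BLUP with all candidates phenotyped.}
#'   \item{pbB1}{pedigree BLUP with the 20% training sample phenotyped;
#'     unphenotyped candidates are predicted through the pedigree
#'     relationship matrix.}
#'   \item{NS}{no selection: random parents, same numbers (drift control).}
#' }
#'
#' @param name scheme name.
#' @param base_dams,base_sires dams/sires selected per cycle in the reference
#'   design (GS3 halves them).
#' @param progeny_size offspring per mating in the reference design (GS3
#'   doubles it).
#' @param n_cycles selection cycles.
#' @param model `"AD"` (additive + dominance kernels, default for genomic
#'   schemes), `"A"`, or `"ADE"` (adds AxA, AxD, DxD Hadamard kernels).
#' @param avoid sib-avoidance rule for mate allocation.
#' @return A `scheme_config` list.
#' @export
scheme_config <- function(name = c("GS", "GS1", "GS2", "GS3", "GV", "pbB",
                                   "pbB1", "NS"),
                          base_dams = 400L, base_sires = 80L,
                          progeny_size = 10L, n_cycles = 7L, model = "AD",
                          avoid = "full_sib") {
  name <- match.arg(name)
  cfg <- list(name = name, n_dams = as.integer(base_dams),
              n_sires = as.integer(base_sires),
              progeny_size = as.integer(progeny_size),
              n_cycles = as.integer(n_cycles),
              training_fraction = 0.2, training_policy = "cumulative",
              criterion = "ebv", kernel = "genomic", model = model,
              avoid = avoid)
  switch(name,
    GS = NULL,
    GS1 = { cfg$training_policy <- "founders_only"; cfg$training_fraction <- 0 },
    GS2 = { cfg$training_fraction <- 0.1 },
    GS3 = { cfg$n_dams <- cfg$n_dams %/% 2L; cfg$n_sires <- cfg$n_sires %/% 2L
            cfg$progeny_size <- 2L * cfg$progeny_size },
    GV = { cfg$criterion <- "true_gv"; cfg$training_fraction <- 0 },
    pbB = { cfg$kernel <- "pedigree"; cfg$model <- "A"
            cfg$training_policy <- "all"; cfg$training_fraction <- 1 },
    pbB1 = { cfg$kernel <- "pedigree"; cfg$model <- "A" },
    NS = { cfg$criterion <- "random"; cfg$training_fraction <- 0 })
  if (cfg$n_dams %% cfg$n_sires != 0)
    stop("n_dams must be a multiple of n_sires", call. = FALSE)
  cfg$dams_per_sire <- cfg$n_dams %/% cfg$n_sires
  structure(cfg, class = "scheme_config")
}

#' Assemble a training set
#'
#' Founders are always included; for the cumulative policy a simple random
#' sample of `fraction` of each generation is added (reproducible per
#' generation given `seed`, so the set grows monotonically over cycles); the
#' `all` policy phenotypes everyone; `founders_only` adds nothing.
#'
#' @param founder_ids ids of the reference-generation individuals.
#' @param generation_ids named list of candidate id vectors per generation
#'   (names are generation numbers).
#' @param policy `"cumulative"`, `"founders_only"` or `"all"`.
#' @param fraction per-generation sampled fraction for the cumulative policy.
#' @param seed integer seed.
#' @return A tibble `id`, `generation`.
#' @export
build_training_set <- function(founder_ids, generation_ids = list(),
                               policy = c("cumulative", "founders_only",
                                          "all"),
                               fraction = 0.2, seed = 1L) {
  policy <- match.arg(policy)
  if (fraction > 1 || fraction < 0)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  out <- tibble::tibble(id = founder_ids, generation = 0L)
  if (policy == "founders_only" || fraction == 0 && policy != "all")
    return(out)
  for (g in names(generation_ids)) {
    ids <- generation_ids[[g]]
    pick <- if (policy == "all") ids else {
      set.seed(derive_seed(seed, 300L, as.integer(g)))
      sample(ids, round(fraction * length(ids)))
    }
    out <- dplyr::bind_rows(out, tibble::tibble(id = sort(pick),
                                                generation = as.integer(g)))
  }
  out
}

#' Truncation selection within sex
#'
#' Selects the `n_females` females and `n_males` males with the best
#' criterion values (lowest, for a trait where lower is better), with a
#' stable tie-break on id.
#'
#' @param candidates tibble with `id` and `sex`.
#' @param criterion numeric values aligned with `candidates` rows.
#' @param n_females,n_males numbers to select.
#' @param direction `"min"` (default; feed-conversion-ratio style) or
#'   `"max"`.
#' @return A list with `dams` and `sires` id vectors.
#' @export
select_parents <- function(candidates, criterion, n_females, n_males,
                           direction = c("min", "max")) {
  direction <- match.arg(direction)
  stopifnot(nrow(candidates) == length(criterion))
  if (anyNA(criterion)) stop("criterion undefined for some candidates",
                             call. = FALSE)
  if (direction == "max") criterion <- -criterion
  pick <- function(sex, n) {
    i <- which(candidates$sex == sex)
    if (length(i) < n)
      stop("insufficient ", if (sex == "F") "female" else "male",
           " candidates: ", length(i), " < ", n, call. = FALSE)
    i[order(criterion[i], candidates$id[i])][seq_len(n)]
  }
  list(dams = candidates$id[pick("F", n_females)],
       sires = candidates$id[pick("M", n_males)])
}

# Incremental cross-product cache for the genomic kernels. VanRaden G and
# Su D over any reference frequency p are exact affine functions of the raw
# dosage and heterozygosity cross-products:
#   WW' = MM' - 2(Mp)1' - 2 1(Mp)' + 4(p.p) J,   W = M - 2 1 p'
#   HH' = BB' -  (Bv)1' -  1(Bv)' +  (v.v) J,    H = B - 1 v', v = 2p(1-p)
# (monomorphic markers contribute exactly zero through the algebra), so only
# the new training rows' products are computed when the set grows.
kernel_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$M <- NULL; env$B <- NULL; env$MM <- NULL; env$BB <- NULL
  add <- function(M_new) {
    B_new <- matrix(as.integer(M_new == 1L), nrow(M_new),
                    dimnames = dimnames(M_new))
    if (is.null(env$M)) {
      env$M <- M_new; env$B <- B_new
      env$MM <- tcrossprod(M_new); env$BB <- tcrossprod(B_new)
    } else {
      xM <- tcrossprod(env$M, M_new); xB <- tcrossprod(env$B, B_new)
      env$MM <- rbind(cbind(env$MM, xM), cbind(t(xM), tcrossprod(M_new)))
      env$BB <- rbind(cbind(env$BB, xB), cbind(t(xB), tcrossprod(B_new)))
      env$M <- rbind(env$M, M_new); env$B <- rbind(env$B, B_new)
    }
  }
  list(env = env, add = add)
}

# assemble tt/xt kernels at reference frequencies p from the cache
genomic_kernels_cached <- function(cache, cand_M, p, model) {
  env <- cache$env
  n_t <- nrow(env$M)
  Mp_t <- as.numeric(env$M %*% p); Mp_c <- as.numeric(cand_M %*% p)
  den_G <- sum(2 * p * (1 - p))
  if (den_G <= 0) stop("all markers monomorphic", call. = FALSE)
  Gtt <- (env$MM - 2 * outer(Mp_t, rep(1, n_t)) -
            2 * outer(rep(1, n_t), Mp_t) + 4 * sum(p^2)) / den_G
  MX <- tcrossprod(cand_M, env$M)
  Gxt <- (MX - 2 * outer(Mp_c, rep(1, n_t)) -
            2 * outer(rep(1, nrow(cand_M)), Mp_t) + 4 * sum(p^2)) / den_G
  rownames(Gtt) <- colnames(Gtt) <- rownames(env$M)
  rownames(Gxt) <- rownames(cand_M); colnames(Gxt) <- rownames(env$M)
  ker <- list(additive = list(tt = Gtt, xt = Gxt))
  if (model %in% c("AD", "ADE")) {
    v <- 2 * p * (1 - p)
    den_D <- sum(v * (1 - v))
    B_c <- matrix(as.integer(cand_M == 1L), nrow(cand_M),
                  dimnames = dimnames(cand_M))
    Bv_t <- as.numeric(env$B %*% v); Bv_c <- as.numeric(B_c %*% v)
    Dtt <- (env$BB - outer(Bv_t, rep(1, n_t)) -
              outer(rep(1, n_t), Bv_t) + sum(v^2)) / den_D
    BX <- tcrossprod(B_c, env$B)
    Dxt <- (BX - outer(Bv_c, rep(1, n_t)) -
              outer(rep(1, nrow(cand_M)), Bv_t) + sum(v^2)) / den_D
    dimnames(Dtt) <- dimnames(Gtt); dimnames(Dxt) <- dimnames(Gxt)
    ker$dominance <- list(tt = Dtt, xt = Dxt)
    if (model == "ADE") {
      sc <- function(tt, xt) {
        m <- mean(diag(tt)); list(tt = tt / m, xt = xt / m)
      }
      ker$AxA <- sc(Gtt * Gtt, Gxt * Gxt)
      ker$AxD <- sc(Gtt * Dtt, Gxt * Dxt)
      ker$DxD <- sc(Dtt * Dtt, Dxt * Dxt)
    }
  }
  ker
}

#' Run one selection scheme over replicated cycles
#'
#' The recurrent loop: generation 1 is created by 1:1 random pairing of the
#' founders; each cycle the training set is updated per the scheme's policy,
#' the evaluation model (GBLUP or pedigree BLUP, AI-REML, additive BLUP as
#' criterion) is refitted, parents are truncation-selected within sex, dams
#' are allocated 5 per sire avoiding sib matings, and the next generation is
#' produced at fixed progeny size. Per-generation records cover genotypic
#' mean and variance, prediction accuracy on the candidates, pedigree,
#' genomic and realized inbreeding, selected full-sib family counts, and
#' favorable-allele frequency summaries.
#'
#' @param founders generation-0 `population` (see
#'   [make_reference_population()]).
#' @param arch a `trait_architecture`.
#' @param config a [scheme_config()].
#' @param seed integer seed for all within-run randomness.
#' @param genotype_metrics compute the per-generation genomic and realized
#'   inbreeding and favorable-allele summaries (default). Turning this off
#'   skips those columns (returned as `NA`) — useful for cheap drift
#'   controls where only means, variances and pedigree inbreeding matter.
#' @return An object of class `gs_run`: list with `records` (tibble, one row
#'   per generation), `pedigree`, `selected` (per-cycle selected ids),
#'   `scheme`, and `variance_components` (per-cycle REML estimates, when a
#'   model is fitted).
#' @export
run_scheme <- function(founders, arch, config, seed = 1L,
                       genotype_metrics = TRUE) {
  stopifnot(inherits(founders, "population"),
            inherits(arch, "trait_architecture"),
            inherits(config, "scheme_config"))
  needs_fit <- config$criterion == "ebv"
  genomic <- config$kernel == "genomic"

  set.seed(derive_seed(seed, 1L))
  pop <- founders
  ped <- pedigree_of(founders)
  gv <- genotypic_value(pop, arch)
  phen <- phenotype(gv, arch$H2, arch$y_min, arch$y_max)
  sigma_e_last <- attr(phen, "sigma_e")

  records <- list()
  vcs <- list()
  selected_log <- list()
  n_fam <- rep(NA_integer_, config$n_cycles + 2L)  # per generation 0..C+1
  acc <- rep(NA_real_, config$n_cycles + 2L)

  snapshot <- function(pop, gv, gen) {
    base <- tibble::tibble(generation = gen, n = n_individuals(pop),
                           mean_gv = mean(gv), var_gv = var(gv))
    if (genotype_metrics) {
      fg <- vanraden_diag(snp_dosage(pop)) - 1
      tibble::tibble(base,
                     F_genomic = mean(fg),
                     F_realized = mean(cpp_realized_F(pop$L1, pop$L2)),
                     allele_frequency_summary(pop))
    } else {
      tibble::tibble(base, F_genomic = NA_real_, F_realized = NA_real_,
                     freq_min = NA_real_, freq_mean = NA_real_,
                     freq_max = NA_real_, n_fixed = NA_integer_,
                     n_lost = NA_integer_)
    }
  }
  records[[1]] <- snapshot(pop, gv, 0L)

  # training storage (ids, phenotypes, and cached kernel cross-products)
  train_ids <- integer(0); train_y <- numeric(0)
  cache <- kernel_cache()
  add_training <- function(ids, y, M) {
    keep <- !ids %in% train_ids
    train_ids <<- c(train_ids, ids[keep])
    train_y <<- c(train_y, y[keep])
    if (genomic && any(keep)) cache$add(M[keep, , drop = FALSE])
  }
  if (needs_fit)
    add_training(pop$info$id, phen, if (genomic) snp_dosage(pop) else NULL)

  # generation 1: 1:1 random pairing of the founders
  set.seed(derive_seed(seed, 2L))
  f0 <- pop$info$id[pop$info$sex == "F"]
  m0 <- sample(pop$info$id[pop$info$sex == "M"])
  plan <- tibble::tibble(sire = m0, dam = f0,
                         n_offspring = config$progeny_size)
  pop <- make_generation(pop, plan)
  ped <- dplyr::bind_rows(ped, pedigree_of(pop))
  prev_sigma <- NULL

  for (cycle in seq_len(config$n_cycles)) {
    gen <- cycle  # candidates are generation `cycle`
    gv <- genotypic_value(pop, arch)
    set.seed(derive_seed(seed, 100L, cycle))
    phen <- phenotype(gv, arch$H2, arch$y_min, arch$y_max,
                      sigma_e = sigma_e_last)
    if (var(gv) > 0) sigma_e_last <- attr(phen, "sigma_e")
    records[[gen + 1L]] <- snapshot(pop, gv, gen)

    # update training set
    if (needs_fit && config$training_fraction > 0) {
      pick <- if (config$training_policy == "all") seq_len(nrow(pop$info))
      else {
        set.seed(derive_seed(seed, 300L, cycle))
        sample(nrow(pop$info),
               round(config$training_fraction * nrow(pop$info)))
      }
      add_training(pop$info$id[pick], phen[pick],
                   if (genomic) snp_dosage(pop)[pick, , drop = FALSE] else NULL)
    }

    # criterion
    if (needs_fit) {
      if (genomic) {
        cand_M <- snp_dosage(pop)
        # reference frequencies from the currently genotyped set
        new_rows <- !pop$info$id %in% train_ids
        n_geno <- length(train_ids) + sum(new_rows)
        p <- (colSums(cache$env$M) +
                colSums(cand_M[new_rows, , drop = FALSE])) / (2 * n_geno)
        kernels <- genomic_kernels_cached(cache, cand_M, p, config$model)
        rm(cand_M)
      } else {
        ids <- c(train_ids, setdiff(pop$info$id, train_ids))
        A <- pedigree_A(ped, ids)
        nt <- length(train_ids)
        cand_rows <- match(as.character(pop$info$id), rownames(A))
        kernels <- list(additive = list(
          tt = A[seq_len(nt), seq_len(nt), drop = FALSE],
          xt = A[cand_rows, seq_len(nt), drop = FALSE]))
      }
      set.seed(derive_seed(seed, 400L, cycle))
      # selection is rank-based: component precision beyond ~1e-4 relative
      # cannot change which candidates are picked, so the scheme loop uses a
      # looser operational tolerance than reml_fit()'s default
      fit <- reml_fit(train_y, kernels, start = prev_sigma, tol = 1e-4,
                      max_iter = 15L)
      prev_sigma <- setNames(fit$sigma$estimate, fit$sigma$term)
      vcs[[cycle]] <- dplyr::mutate(fit$sigma, cycle = cycle,
                                    converged = fit$converged,
                                    iterations = fit$iterations)
      crit <- fit$u[length(train_y) + seq_len(nrow(pop$info)), "additive"]
      acc[gen + 1L] <- prediction_accuracy(crit, gv)
      rm(kernels, fit)
    } else if (config$criterion == "true_gv") {
      crit <- gv
    } else {
      set.seed(derive_seed(seed, 500L, cycle))
      crit <- runif(nrow(pop$info))
    }

    sel <- select_parents(pop$info, crit, config$n_dams, config$n_sires)
    selected_log[[cycle]] <- tibble::tibble(
      cycle = cycle, id = c(sel$dams, sel$sires),
      role = rep(c("dam", "sire"), c(config$n_dams, config$n_sires)))
    n_fam[gen + 1L] <- count_selected_progenies(c(sel$dams, sel$sires), ped)

    set.seed(derive_seed(seed, 600L, cycle))
    plan <- allocate_mates(sel$sires, sel$dams, config$dams_per_sire,
                           pedigree = ped, avoid = config$avoid)
    plan$n_offspring <- config$progeny_size
    set.seed(derive_seed(seed, 700L, cycle))
    pop <- make_generation(pop, plan)
    ped <- dplyr::bind_rows(ped, pedigree_of(pop))
    gc(FALSE)
  }

  gv <- genotypic_value(pop, arch)
  records[[config$n_cycles + 2L]] <- snapshot(pop, gv, config$n_cycles + 1L)

  rec <- dplyr::bind_rows(records)
  rec$accuracy <- acc[rec$generation + 1L]
  rec$n_families_selected <- n_fam[rec$generation + 1L]
  Fp <- pedigree_inbreeding(ped)
  rec$F_pedigree <- vapply(rec$generation, function(g)
    mean(Fp$F_pedigree[ped$generation == g]), 0)
  rec <- dplyr::relocate(rec, "accuracy", "F_pedigree",
                         .after = "var_gv")
  rec$scheme <- config$name
  structure(list(records = dplyr::relocate(rec, "scheme"),
                 pedigree = ped,
                 selected = dplyr::bind_rows(selected_log),
                 variance_components = dplyr::bind_rows(vcs),
                 scheme = config$name),
            class = "gs_run")
}

#' @export
print.gs_run <- function(x, ...) {
  cat("<gs_run> scheme", x$scheme, "-", max(x$records$generation),
      "generations\n")
  print(x$records[, c("generation", "n", "mean_gv", "var_gv", "accuracy",
                      "F_pedigree")])
  invisible(x)
}
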