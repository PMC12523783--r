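#' Experiment presets
#'
#' Bundled study configurations:
#' \describe{
#'   \item{full}{the reference design: 10 chromosomes / 770 cM, 38,500 SNPs,
#'     1,000 QTL; 400 founders per sex; 400 dams / 80 sires selected (20% and
#'     4% of candidates), 5 dams per sire, progeny size 10; 7 cycles, 10
#'     replicates; trait bounds (1.1, 2.9) genotypic and (1.0, 3.5)
#'     phenotypic, H2 = 0.30, k = 1.5.}
#'   \item{desk}{a scaled-down design for desktop replication. The genome
#'     keeps the full 10-chromosome map and all 1,000 QTL (per-QTL effects
#'     and the QTL linkage map set the genetic variance and its LD structure,
#'     which the replication targets measure) and thins the SNP panel to
#'     7,700 (one fifth per chromosome — enough that genomic prediction
#'     still resolves within-family differences; sparser panels visibly
#'     push selection toward whole families and inflate inbreeding); the
#'     population shrinks to 200
#'     founders per sex with 200 dams / 40 sires selected — half the
#'     reference scale, the largest desktop size whose effective population
#'     size (about 133 versus 267) keeps drift and inbreeding accumulation
#'     near the full-scale regime — preserving the 20%/4% selected
#'     fractions, 5:1 mating ratio, progeny size, H2, trait bounds and
#'     founder frequency designs; 5 replicates.}
#'   \item{toy}{a minimal smoke-test design (2 chromosomes, 200 SNPs, 20
#'     QTL, 20 founders per sex, 3 cycles) that runs the full pipeline in
#'     seconds.}
#' }
#'
#' Founder designs: `low` LD crosses two parental populations with equal
#' means (SNP MAF 0.3/0.3, favorable-allele 0.6/0.6); `high` LD crosses
#' divergent populations (SNP MAF 0.1/0.5, favorable 0.3/0.9). Both give the
#' same expected generation-0 frequencies (MAF 0.3, favorable 0.6).
#'
#' @param name `"full"`, `"desk"` or `"toy"`.
#' @return An `experiment_config` list.
#' @export
preset <- function(name = c("full", "desk", "toy")) {
  name <- match.arg(name)
  chrom <- switch(name,
    full = chromosome_table(),
    desk = chromosome_table(snp_ends = c(2000L, 250L), snp_total = 7700L),
    toy = chromosome_table(n_chr = 2L, len_ends = c(120, 80),
                           len_total = 200, snp_ends = c(120L, 80L),
                           snp_total = 200L, qtl_ends = c(12L, 8L),
                           qtl_total = 20L))
  n_found <- c(full = 400L, desk = 200L, toy = 20L)[[name]]
  structure(list(
    name = name,
    chromosomes = chrom,
    founder_designs = list(
      low = founder_spec(c(0.3, 0.3), c(0.6, 0.6),
                         n_founders_per_sex = n_found),
      high = founder_spec(c(0.1, 0.5), c(0.3, 0.9),
                          n_founders_per_sex = n_found)),
    # toy keeps the genotypic design but widens the phenotype window: with
    # only 20 QTL the genotypic spread is wide and the study bounds would
    # truncate several percent of records
    trait = list(g_min = 1.1, g_max = 2.9,
                 y_min = if (name == "toy") 0 else 1.0,
                 y_max = if (name == "toy") 5 else 3.5,
                 H2 = 0.3, k = 1.5),
    base_dams = c(full = 400L, desk = 200L, toy = 20L)[[name]],
    base_sires = c(full = 80L, desk = 40L, toy = 4L)[[name]],
    progeny_size = 10L,
    n_cycles = c(full = 7L, desk = 7L, toy = 3L)[[name]],
    n_replicates = c(full = 10L, desk = 5L, toy = 1L)[[name]],
    schemes = c("GS", "GS1", "GS2", "GS3", "GV", "pbB", "pbB1", "NS")),
    class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config> preset", x$name, "-",
      sum(x$chromosomes$n_snp), "SNPs,", sum(x$chromosomes$n_qtl), "QTL,",
      x$base_dams, "dams /", x$base_sires, "sires,", x$n_cycles, "cycles,",
      x$n_replicates, "replicates\n")
  invisible(x)
}

#' Read / write experiment configurations as YAML
#'
#' @param config an `experiment_config`.
#' @param path file path.
#' @return `path` invisibly; `read_experiment_config()` returns the restored
#'   object.
#' @export
write_experiment_config <- function(config, path) {
  obj <- unclass(config)
  obj$chromosomes <- as.data.frame(obj$chromosomes)
  obj$founder_designs <- lapply(obj$founder_designs, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$chromosomes <- tibble::as_tibble(as.data.frame(obj$chromosomes))
  obj$founder_designs <- lapply(obj$founder_designs, function(fs)
    founder_spec(unlist(fs$snp_maf), unlist(fs$qtl_fav), fs$concentration,
                 fs$n_founders_per_sex))
  structure(obj, class = "experiment_config")
}

# Shared base (genome, frequencies, founders, architecture) for one
# population design x replicate; all schemes start from it.
build_base <- function(config, population = c("low", "high"), replicate = 1L,
                       seed = 1L, epistasis = NULL) {
  population <- match.arg(population)
  pop_i <- match(population, names(config$founder_designs))
  map <- build_genome(config$chromosomes, seed = derive_seed(seed, 11L))
  spec <- config$founder_designs[[population]]
  freqs <- sample_allele_frequencies(spec, map,
                                     seed = derive_seed(seed, 21L, pop_i,
                                                        replicate))
  founders <- make_reference_population(freqs, map, spec$n_founders_per_sex,
                                        seed = derive_seed(seed, 22L, pop_i,
                                                           replicate))
  # dominance degrees are shared across populations and replicates (the
  # per-gene a and d are properties of the trait, not of the population)
  set.seed(derive_seed(seed, 30L))
  degrees <- runif(sum(config$chromosomes$n_qtl), 0, 1.2)
  fav <- NULL
  if (!is.null(epistasis)) {
    fd <- qtl_dosage(founders)
    fav <- setNames(colMeans(fd) / 2, colnames(fd))
  }
  arch <- trait_architecture(
    map, g_min = config$trait$g_min, g_max = config$trait$g_max,
    y_min = config$trait$y_min, y_max = config$trait$y_max,
    H2 = config$trait$H2, epistasis = epistasis, fav_freq = fav,
    degrees = degrees, seed = derive_seed(seed, 31L, pop_i, replicate))
  list(map = map, freqs = freqs, founders = founders, arch = arch,
       population = population, replicate = replicate)
}

#' Run a replicated selection experiment
#'
#' Executes every requested scheme x founder design x replicate combination.
#' Within a replicate all schemes share the same genome, founders and trait
#' architecture (paired comparison); they differ only in selection criterion,
#' training policy and seeded mating randomness. Per-generation records are
#' returned tidy and, when `outdir` is given, written as CSV together with a
#' replicate-aggregated table and a JSON run manifest (config hash, package
#' version, per-run seeds, timings, file inventory).
#'
#' @param config an [preset()]-style `experiment_config`.
#' @param schemes scheme names to run (default `config$schemes`).
#' @param populations founder designs to run (`"low"`, `"high"`).
#' @param replicates number of replicates (default `config$n_replicates`).
#' @param seed master seed; per-run seeds are derived by a counter scheme so
#'   adding replicates never perturbs earlier ones.
#' @param epistasis optional epistasis spec passed to
#'   [trait_architecture()] (e.g. `list(fraction = 0.5, type =
#'   "complementary", k = 1.5)`).
#' @param outdir optional output directory.
#' @return Invisibly, a `gs_experiment` list: `records` (tidy tibble over
#'   scheme, population, replicate, generation), `manifest`, and `paths`.
#' @export
run_experiment <- function(config, schemes = config$schemes,
                           populations = c("low", "high"),
                           replicates = config$n_replicates, seed = 1L,
                           epistasis = NULL, outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  runs <- list()
  seeds <- list()
  for (population in populations) {
    pop_i <- match(population, names(config$founder_designs))
    for (rep_i in seq_len(replicates)) {
      base <- build_base(config, population, rep_i, seed, epistasis)
      for (scheme in schemes) {
        sch_i <- match(scheme, c("GS", "GS1", "GS2", "GS3", "GV", "pbB",
                                 "pbB1", "NS"))
        run_seed <- derive_seed(seed, 40L, pop_i, rep_i, sch_i)
        cfg <- scheme_config(scheme, base_dams = config$base_dams,
                             base_sires = config$base_sires,
                             progeny_size = config$progeny_size,
                             n_cycles = config$n_cycles)
        run <- run_scheme(base$founders, base$arch, cfg, seed = run_seed)
        rec <- dplyr::mutate(run$records, population = population,
                             replicate = rep_i)
        runs[[length(runs) + 1L]] <- rec
        seeds[[length(seeds) + 1L]] <- list(population = population,
                                            replicate = rep_i,
                                            scheme = scheme, seed = run_seed)
      }
    }
  }
  records <- dplyr::bind_rows(runs) |>
    dplyr::relocate("population", "replicate", .after = "scheme")
  manifest <- list(
    package = "panmixsel",
    version = as.character(utils::packageVersion("panmixsel")),
    preset = config$name,
    config_hash = config_hash(config),
    master_seed = seed,
    run_seeds = seeds,
    wallclock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = character(0))
  paths <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p_rec <- file.path(outdir, "generation_records.csv")
    utils::write.csv(records, p_rec, row.names = FALSE)
    p_agg <- file.path(outdir, "aggregated_records.csv")
    utils::write.csv(aggregate_replicates(
      dplyr::mutate(records,
                    scheme = paste(.data$scheme, .data$population, sep = "_"))),
      p_agg, row.names = FALSE)
    manifest$files <- basename(c(p_rec, p_agg))
    p_man <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
    paths <- c(p_rec, p_agg, p_man)
  }
  invisible(structure(list(records = records, manifest = manifest,
                           paths = paths), class = "gs_experiment"))
}

# stable content hash of a configuration (order-independent enough for
# manifests; not cryptographic)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE,
                        force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Pedigree-only simulation of the no-selection design
#'
#' Simulates only the pedigree of the reference mating design (no genotypes):
#' founders of both sexes, generation 1 by 1:1 founder pairing, then each
#' cycle a random draw of dams and sires from the current generation,
#' allocated 5 dams per sire avoiding sib matings, at fixed progeny size.
#' Used to measure drift-driven pedigree inbreeding at full scale cheaply.
#'
#' @param n_dams,n_sires parents drawn per cycle.
#' @param dams_per_sire mating ratio.
#' @param progeny_size offspring per mating.
#' @param n_cycles selection cycles (generations 2..n_cycles + 1).
#' @param n_founders_per_sex founders of each sex.
#' @param avoid sib-avoidance rule (see [allocate_mates()]).
#' @param seed integer seed.
#' @return A list: `pedigree` (tibble with `F_pedigree`) and `by_generation`
#'   (tibble of mean pedigree F per generation).
#' @export
simulate_ns_pedigree <- function(n_dams = 400L, n_sires = 80L,
                                 dams_per_sire = 5L, progeny_size = 10L,
                                 n_cycles = 7L, n_founders_per_sex = 400L,
                                 avoid = "full_sib", seed = 1L) {
  stopifnot(n_dams == dams_per_sire * n_sires)
  new_gen <- function(plan, gen, id_start) {
    no <- rep(progeny_size, nrow(plan))
    n <- sum(no)
    tibble::tibble(id = seq.int(id_start, length.out = n),
                   sire = rep(plan$sire, no), dam = rep(plan$dam, no),
                   generation = gen,
                   sex = ifelse(rbinom(n, 1, 0.5) == 1, "F", "M"))
  }
  set.seed(derive_seed(seed, 1L))
  ped <- tibble::tibble(id = seq_len(2L * n_founders_per_sex),
                        sire = NA_integer_, dam = NA_integer_,
                        generation = 0L,
                        sex = rep(c("F", "M"), each = n_founders_per_sex))
  plan <- tibble::tibble(sire = sample(ped$id[ped$sex == "M"]),
                         dam = ped$id[ped$sex == "F"])
  cur <- new_gen(plan, 1L, max(ped$id) + 1L)
  ped <- dplyr::bind_rows(ped, cur)
  for (cycle in seq_len(n_cycles)) {
    set.seed(derive_seed(seed, 100L, cycle))
    dams <- sample(cur$id[cur$sex == "F"], n_dams)
    sires <- sample(cur$id[cur$sex == "M"], n_sires)
    plan <- allocate_mates(sires, dams, dams_per_sire, pedigree = ped,
                           avoid = avoid)
    cur <- new_gen(plan, cycle + 1L, max(ped$id) + 1L)
    ped <- dplyr::bind_rows(ped, cur)
  }
  ped$F_pedigree <- pedigree_inbreeding(ped)$F_pedigree
  by_gen <- ped |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(mean_F = mean(.data$F_pedigree), n = dplyr::n(),
                     .groups = "drop")
  list(pedigree = ped, by_generation = by_gen)
}

#' Scaled-down replication of the selection study
#'
#' Runs the desk preset's GS (genomic selection, founders + 20% training) and
#' NS (no selection) schemes in both founder LD designs over replicates, and
#' summarises the quantities the study reports: total genotypic-mean change
#' from generation 1 to the final generation under GS, final-generation
#' pedigree inbreeding under GS and NS, and the percentage decrease in
#' genotypic variance from generation 0 to the final generation under NS.
#'
#' @param seed master seed.
#' @param replicates GS replicates per population design.
#' @param ns_replicates NS replicates per population design. The
#'   no-selection variance change is a small signal under substantial
#'   cohort-sampling noise (each generation's genotypic variance is
#'   estimated from a few hundred to a few thousand individuals), so the
#'   cheap NS runs are replicated more heavily by default.
#' @param populations founder designs to run.
#' @param config experiment configuration (default [preset("desk")][preset]).
#' @return A tibble with one row per population x replicate:
#'   `gs_total_gain`, `gs_F_last`, `ns_F_last`, `ns_var_loss_pct` (`NA`
#'   where a scheme was not run for that replicate); the full generation
#'   records are attached as attribute `records`.
#' @export
replicate_desk_study <- function(seed = 1L, replicates = 3L,
                                 ns_replicates = 8L,
                                 populations = c("high", "low"),
                                 config = preset("desk")) {
  out <- list(); recs <- list()
  for (population in populations) {
    pop_i <- match(population, names(config$founder_designs))
    for (r in seq_len(max(replicates, ns_replicates))) {
      base <- build_base(config, population, r, seed)
      row <- tibble::tibble(population = population, replicate = r,
                            gs_total_gain = NA_real_, gs_F_last = NA_real_,
                            ns_F_last = NA_real_,
                            ns_var_loss_pct = NA_real_)
      if (r <= replicates) {
        gs <- run_scheme(base$founders, base$arch,
                         scheme_config("GS", config$base_dams,
                                       config$base_sires,
                                       config$progeny_size, config$n_cycles),
                         seed = derive_seed(seed, 40L, pop_i, r, 1L))
        gr <- gs$records
        row$gs_total_gain <- gr$mean_gv[nrow(gr)] - gr$mean_gv[2]
        row$gs_F_last <- gr$F_pedigree[nrow(gr)]
        recs[[length(recs) + 1L]] <-
          dplyr::mutate(gr, population = population, replicate = r)
        rm(gs, gr)
      }
      if (r <= ns_replicates) {
        ns <- run_scheme(base$founders, base$arch,
                         scheme_config("NS", config$base_dams,
                                       config$base_sires,
                                       config$progeny_size, config$n_cycles),
                         seed = derive_seed(seed, 40L, pop_i, r, 8L),
                         genotype_metrics = FALSE)
        nr <- ns$records
        row$ns_F_last <- nr$F_pedigree[nrow(nr)]
        row$ns_var_loss_pct <- 100 * (1 - nr$var_gv[nrow(nr)] / nr$var_gv[1])
        recs[[length(recs) + 1L]] <-
          dplyr::mutate(nr, population = population, replicate = r)
        rm(ns, nr)
      }
      out[[length(out) + 1L]] <- row
      rm(base); gc(FALSE)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "records") <- dplyr::bind_rows(recs)
  res
}
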