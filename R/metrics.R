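#' Genetic gains from generation means
#'
#' First differences of the genotypic means of successive generations; the
#' total gain is the last mean minus the first (telescoping).
#'
#' @param x either a numeric vector of generation means (in generation
#'   order), or a tibble with `generation` and a mean column.
#' @param mean_col column holding the means when `x` is a data frame.
#' @return A tibble `generation`, `gain` (one row per transition) with the
#'   total as attribute `total`; retrieve it with `attr(, "total")`.
#' @examples
#' genetic_gain(c(2.0, 1.8, 1.7))  # gains -0.2, -0.1; total -0.3
#' @export
genetic_gain <- function(x, mean_col = "mean_gv") {
  if (is.data.frame(x)) {
    x <- dplyr::arrange(x, .data$generation)
    means <- x[[mean_col]]
    gens <- x$generation
  } else {
    means <- as.numeric(x)
    gens <- seq_along(means) - 1
  }
  if (length(means) < 2) stop("need at least two generations", call. = FALSE)
  out <- tibble::tibble(generation = gens[-1], gain = diff(means))
  attr(out, "total") <- means[length(means)] - means[1]
  out
}

#' Additive-value prediction accuracy
#'
#' Pearson correlation between predicted additive values and true genotypic
#' values. Returns `NA` (with a warning) when either input has zero
#' variance.
#'
#' @param predicted,true numeric vectors of equal length (>= 3).
#' @return A single correlation.
#' @export
prediction_accuracy <- function(predicted, true) {
  stopifnot(length(predicted) == length(true))
  if (length(predicted) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(predicted) == 0 || var(true) == 0) {
    warning("zero variance; accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(predicted, true)
}

#' Number of full-sib families among selected individuals
#'
#' Distinct (sire, dam) pairs represented by at least one selected
#' individual; a proxy for how concentrated selection is within families.
#'
#' @param selected_ids ids of the selected parents.
#' @param ped pedigree tibble (`id`, `sire`, `dam`).
#' @return Integer count.
#' @export
count_selected_progenies <- function(selected_ids, ped) {
  m <- match(selected_ids, ped$id)
  if (anyNA(m)) stop("selected ids missing from pedigree", call. = FALSE)
  dplyr::n_distinct(paste(ped$sire[m], ped$dam[m]))
}

#' Favorable-allele frequency summary over QTL
#'
#' @param fav favorable-allele dosage matrix (individuals x QTL, see
#'   [qtl_dosage()]) or a `population`.
#' @return A one-row tibble: `freq_min`, `freq_mean`, `freq_max`, `n_fixed`
#'   (frequency 1), `n_lost` (frequency 0).
#' @export
allele_frequency_summary <- function(fav) {
  if (inherits(fav, "population")) fav <- qtl_dosage(fav)
  f <- colMeans(fav) / 2
  tibble::tibble(freq_min = min(f), freq_mean = mean(f), freq_max = max(f),
                 n_fixed = sum(f == 1), n_lost = sum(f == 0))
}

#' Aggregate per-generation records over replicates
#'
#' @param records a tidy tibble of generation records with at least
#'   `scheme`, `replicate`, `generation` and numeric metric columns.
#' @return A long tibble `scheme`, `generation`, `metric`, `mean`, `sd`,
#'   `n_replicates` (sd is `NA` for a single replicate).
#' @export
aggregate_replicates <- function(records) {
  stopifnot(all(c("scheme", "replicate", "generation") %in% names(records)))
  num <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                 c("replicate", "generation"))
  records |>
    tidyr::pivot_longer(dplyr::all_of(num), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$scheme, .data$generation, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (dplyr::n() > 1) sd(.data$value, na.rm = TRUE) else NA_real_,
      n_replicates = dplyr::n(), .groups = "drop")
}
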