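#' Pedigree utilities
#'
#' Pedigrees are tibbles with columns `id`, `sire`, `dam` (integer ids, `NA`
#' unknown) and optionally `generation`, `sex`, sorted so parents precede
#' offspring.
#'
#' @param pop a `population` or a list of populations.
#' @return The pedigree tibble.
#' @export
pedigree_of <- function(pop) {
  if (inherits(pop, "population")) pop <- list(pop)
  dplyr::bind_rows(lapply(pop, function(p)
    p$info[, c("id", "sire", "dam", "generation", "sex")]))
}

# validate + recode a pedigree into 0-based-unknown integer parent vectors
recode_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree", call. = FALSE)
  s <- match(ped$sire, ped$id); d <- match(ped$dam, ped$id)
  s[is.na(ped$sire)] <- 0L; d[is.na(ped$dam)] <- 0L
  if (anyNA(s) || anyNA(d))
    stop("pedigree refers to unknown parent ids", call. = FALSE)
  if (any(s >= seq_along(s) & s > 0) || any(d >= seq_along(d) & d > 0))
    stop("pedigree must be sorted with parents before offspring",
         call. = FALSE)
  list(sire = as.integer(s), dam = as.integer(d))
}

#' Pedigree inbreeding coefficients
#'
#' Inbreeding from the numerator-relationship recursion (Meuwissen-Luo
#' algorithm; identical to the tabular-method diagonal minus one).
#'
#' @param ped pedigree tibble (`id`, `sire`, `dam`, parents before
#'   offspring; `NA` = unknown founder).
#' @return A tibble `id`, `F_pedigree`.
#' @examples
#' ped <- tibble::tibble(id = 1:5, sire = c(NA, NA, 1L, 1L, 3L),
#'                       dam = c(NA, NA, 2L, 2L, 4L))
#' pedigree_inbreeding(ped)  # full-sib offspring: F = 0.25
#' @export
pedigree_inbreeding <- function(ped) {
  r <- recode_pedigree(ped)
  tibble::tibble(id = ped$id, F_pedigree = cpp_pedigree_F(r$sire, r$dam))
}

#' Pedigree numerator relationship matrix
#'
#' Standard tabular recursion; the diagonal equals 1 + F with F from
#' [pedigree_inbreeding()]. Unknown parents are treated as unrelated
#' founders. Memory is O(n^2) over the whole pedigree; `subset_ids` selects
#' the returned rows/columns after computation.
#'
#' @param ped pedigree tibble (`id`, `sire`, `dam`).
#' @param subset_ids ids of the block to return (default all).
#' @return A symmetric matrix with dimnames = ids.
#' @export
pedigree_A <- function(ped, subset_ids = NULL) {
  r <- recode_pedigree(ped)
  A <- cpp_amatrix(r$sire, r$dam)
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(subset_ids)) {
    m <- match(as.character(subset_ids), rownames(A))
    if (anyNA(m)) stop("subset ids not in pedigree", call. = FALSE)
    A <- A[m, m, drop = FALSE]
  }
  A
}

#' Export a pedigree as CSV
#'
#' Four columns: id, sire, dam, generation (0 for unknown parents).
#'
#' @param ped pedigree tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), 0L, ped$sire),
                    dam = ifelse(is.na(ped$dam), 0L, ped$dam),
                    generation = if ("generation" %in% names(ped))
                      ped$generation else NA_integer_)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
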