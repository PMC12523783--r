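#' VanRaden additive genomic relationship matrix (method 1)
#'
#' `G = W W' / sum(2 p_j (1 - p_j))` with `W = M - 2p`, where `M` is the
#' allele-dosage matrix. Monomorphic markers (at the supplied or computed
#' reference frequencies) are dropped.
#'
#' @param M dosage matrix (individuals x markers), entries in \{0, 1, 2\}.
#' @param p reference allele frequencies; default column means / 2.
#' @return Symmetric matrix with dimnames from `rownames(M)`.
#' @export
vanraden_G <- function(M, p = NULL) {
  if (is.null(p)) p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic", call. = FALSE)
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / sum(2 * p * (1 - p))
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Su dominance genomic relationship matrix
#'
#' Heterozygosity coding `h = 1(dosage == 1) - 2p(1-p)`;
#' `D = H H' / sum(2 p q (1 - 2 p q))`.
#'
#' @inheritParams vanraden_G
#' @return Symmetric matrix with dimnames from `rownames(M)`.
#' @export
su_D <- function(M, p = NULL) {
  if (is.null(p)) p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic", call. = FALSE)
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  pq <- 2 * p * (1 - p)
  H <- sweep(M == 1, 2, pq)
  D <- tcrossprod(H) / sum(pq * (1 - pq))
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

# cross-block versions: rows x, columns y (same reference frequencies)
vanraden_G_cross <- function(Mx, My, p) {
  keep <- p > 0 & p < 1
  Wx <- sweep(Mx[, keep, drop = FALSE], 2, 2 * p[keep])
  Wy <- sweep(My[, keep, drop = FALSE], 2, 2 * p[keep])
  out <- tcrossprod(Wx, Wy) / sum(2 * p[keep] * (1 - p[keep]))
  dimnames(out) <- list(rownames(Mx), rownames(My))
  out
}

su_D_cross <- function(Mx, My, p) {
  keep <- p > 0 & p < 1
  pq <- 2 * p[keep] * (1 - p[keep])
  Hx <- sweep(Mx[, keep, drop = FALSE] == 1, 2, pq)
  Hy <- sweep(My[, keep, drop = FALSE] == 1, 2, pq)
  out <- tcrossprod(Hx, Hy) / sum(pq * (1 - pq))
  dimnames(out) <- list(rownames(Mx), rownames(My))
  out
}

#' Epistatic kernels by Hadamard products
#'
#' Additive x additive, additive x dominance (housing AxD + DxA) and
#' dominance x dominance covariance kernels as elementwise products of the
#' additive and dominance matrices, each rescaled so the mean diagonal is 1
#' (making variance components comparable across kernels).
#'
#' @param G,D additive and dominance relationship matrices (conformable).
#' @return A named list `AxA`, `AxD`, `DxD`.
#' @export
epistatic_kernels <- function(G, D) {
  stopifnot(all(dim(G) == dim(D)))
  scale1 <- function(K) K / mean(diag(K))
  list(AxA = scale1(G * G), AxD = scale1(G * D), DxD = scale1(D * D))
}

#' Genomic inbreeding coefficients
#'
#' `F_g = G_ii - 1` from the diagonal of the additive genomic relationship
#' matrix.
#'
#' @param G a VanRaden additive relationship matrix.
#' @return A tibble `id`, `F_genomic`.
#' @export
genomic_F <- function(G) {
  ids <- rownames(G)
  tibble::tibble(id = if (is.null(ids)) seq_len(nrow(G)) else ids,
                 F_genomic = unname(diag(G)) - 1)
}

# VanRaden diagonal only (no n x n matrix), for per-generation genomic F
vanraden_diag <- function(M, p = NULL) {
  if (is.null(p)) p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  W <- sweep(M[, keep, drop = FALSE], 2, 2 * p[keep])
  unname(rowSums(W^2)) / sum(2 * p[keep] * (1 - p[keep]))
}
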