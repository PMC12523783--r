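#' REML variance components and BLUP for kernel mixed models
#'
#' Fits `y = X beta + sum_k u_k + e`, `u_k ~ N(0, sigma_k^2 K_k)`,
#' `e ~ N(0, sigma_e^2 I)` by average-information REML with an
#' expectation-maximization fallback (used when the AI step fails or drives a
#' component negative), and returns BLUPs of every `u_k` for all units —
#' phenotyped or not — via the mixed-model solution
#' `u_k = sigma_k^2 K_k[, t] V^{-1} (y - X beta)`.
#'
#' Kernels may be given in two forms: a full square matrix over all units
#' (with `y` containing `NA` for unphenotyped units), or a list
#' `list(tt = , xt = )` with the phenotyped block and an extra-units x
#' phenotyped block (then `y` has no `NA` and predictions cover the
#' phenotyped units followed by the extra units). A small ridge
#' (`condition`) is added to each kernel's phenotyped diagonal before
#' solving.
#'
#' @param y response; `NA` marks genotyped-but-unphenotyped units when
#'   kernels are square matrices.
#' @param kernels named list of kernels (see Details).
#' @param X fixed-effect design over the phenotyped units; default intercept.
#' @param max_iter iteration cap; `0` evaluates at `start` without updating.
#' @param tol convergence tolerance on the maximum relative component change.
#' @param start optional named numeric of starting values
#'   (kernel names + `"residual"`).
#' @param condition diagonal ridge added to each kernel.
#' @param floor_frac variance floor as a fraction of `var(y)`.
#' @return An object of class `gs_reml` with elements `sigma` (tibble of
#'   variance components), `beta`, `u` (units x kernels BLUP matrix),
#'   `loglik`, `converged`, `iterations`, `n`.
#' @export
reml_fit <- function(y, kernels, X = NULL, max_iter = 50L, tol = 1e-6,
                     start = NULL, condition = 1e-6, floor_frac = 1e-8) {
  stopifnot(is.list(kernels), length(kernels) >= 1)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- paste0("K", seq_along(kernels))
  square <- is.matrix(kernels[[1]])
  if (square) {
    obs <- which(!is.na(y))
    yt <- y[obs]
    Ktt <- lapply(kernels, function(K) K[obs, obs, drop = FALSE])
    Kxt <- lapply(kernels, function(K) K[-obs, obs, drop = FALSE])
    if (length(obs) == length(y))
      Kxt <- lapply(Kxt, function(K) K[0, , drop = FALSE])
    pred_ids <- c(rownames(kernels[[1]])[obs], rownames(kernels[[1]])[-obs])
  } else {
    if (anyNA(y)) stop("y must be complete with tt/xt kernels", call. = FALSE)
    yt <- y
    Ktt <- lapply(kernels, `[[`, "tt")
    Kxt <- lapply(kernels, `[[`, "xt")
    pred_ids <- c(rownames(Ktt[[1]]), rownames(Kxt[[1]]))
  }
  n <- length(yt)
  if (n < 3) stop("need at least 3 phenotyped units", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (nrow(X) != n) stop("X must have one row per phenotyped unit",
                         call. = FALSE)

  nm <- c(names(kernels), "residual")
  vy <- var(yt)
  floorv <- floor_frac * vy
  s <- if (!is.null(start)) pmax(start[nm], floorv) else
    setNames(c(rep(0.5 * vy / length(kernels) /
                     vapply(Ktt, function(K) mean(diag(K)), 0), 1),
               0.5 * vy), nm)

  eval_at <- function(s) {
    # the conditioning ridge on each kernel is folded into the diagonal:
    # sum_k s_k (K_k + cI) + s_e I = sum_k s_k K_k + (s_e + c sum_k s_k) I
    V <- diag(s["residual"] + condition * sum(s[names(kernels)]), n)
    for (k in names(kernels)) V <- V + s[k] * Ktt[[k]]
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    logdetV <- 2 * sum(log(diag(C)))
    Vi <- chol2inv(C)
    rm(V, C)  # keep peak memory to one n x n copy beyond Vi
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViXi <- solve(XtViX)
    Pv <- function(v) Vi %*% v - ViX %*% (XtViXi %*% crossprod(ViX, v))
    Py <- Pv(yt)
    beta <- XtViXi %*% crossprod(ViX, yt)
    ll <- -0.5 * (logdetV + determinant(XtViX)$modulus + sum(yt * Py))
    tr_PK <- q <- vector("list", length(nm))
    names(tr_PK) <- names(q) <- nm
    for (k in nm) {
      if (k == "residual") {
        trViK <- sum(diag(Vi))
        corr <- sum(ViX * t(XtViXi %*% t(ViX)))
        q[[k]] <- Py
      } else {
        trViK <- sum(Vi * Ktt[[k]])          # tr(Vi K), K symmetric
        B <- XtViXi %*% crossprod(ViX, Ktt[[k]])
        corr <- sum(ViX * t(B))
        q[[k]] <- Ktt[[k]] %*% Py
      }
      tr_PK[[k]] <- trViK - corr
    }
    score <- vapply(nm, function(k)
      -0.5 * (tr_PK[[k]] - crossprod(Py, q[[k]])[1]), 0)
    list(Vi = Vi, Pv = Pv, Py = Py, beta = beta, ll = ll,
         tr_PK = tr_PK, q = q, score = score)
  }

  converged <- FALSE
  it <- 0L
  at_floor <- setNames(integer(length(nm)), nm)
  ev <- eval_at(s)
  if (is.null(ev)) stop("covariance matrix not positive definite",
                        call. = FALSE)
  while (it < max_iter) {
    it <- it + 1L
    # freeze components that sit on the variance floor with a negative
    # gradient for two consecutive iterations (boundary estimates)
    at_floor <- ifelse(s <= floorv * 1.01 & ev$score < 0, at_floor + 1L, 0L)
    act <- nm[at_floor < 2L]
    if (length(act) == 0L) { converged <- TRUE; break }
    AI <- matrix(0, length(act), length(act), dimnames = list(act, act))
    Pq <- lapply(ev$q[act], ev$Pv)
    for (i in seq_along(act)) for (j in i:length(act))
      AI[i, j] <- AI[j, i] <- 0.5 * crossprod(ev$q[[act[i]]], Pq[[j]])[1]
    delta_a <- tryCatch(solve(AI, ev$score[act]), error = function(e) NULL)
    s_new <- NULL
    if (!is.null(delta_a) && all(is.finite(delta_a))) {
      delta <- setNames(numeric(length(nm)), nm)
      delta[act] <- delta_a
      # AI step with halving so no component is driven below its floor
      step <- 1
      while (step > 1 / 64 && any(s + step * delta < floorv)) step <- step / 2
      cand <- pmax(s + step * delta, floorv)
      if (all(is.finite(cand))) s_new <- cand
    }
    if (is.null(s_new)) {
      # EM step: always moves components toward the mode, stays positive
      s_new <- vapply(nm, function(k)
        if (k %in% act)
          s[k] + (s[k]^2 / n) *
            (crossprod(ev$Py, ev$q[[k]])[1] - ev$tr_PK[[k]])
        else s[k], 0)
      s_new <- pmax(s_new, floorv)
    }
    ev_new <- eval_at(s_new)
    if (is.null(ev_new)) {  # halve toward previous point
      s_new <- (s + s_new) / 2
      ev_new <- eval_at(s_new)
      if (is.null(ev_new)) break
    }
    # relative change, measured against a scale that ignores components
    # too small to matter (< 0.1% of the phenotypic variance)
    rel <- max(abs(s_new - s) / pmax(abs(s_new), 1e-3 * vy))
    s <- setNames(as.numeric(s_new), nm)
    ev <- ev_new
    if (rel < tol) { converged <- TRUE; break }
  }

  n_x <- nrow(Kxt[[1]])
  u <- vapply(names(kernels), function(k)
    c(as.numeric(s[k] * (Ktt[[k]] %*% ev$Py)),
      if (n_x) as.numeric(s[k] * (Kxt[[k]] %*% ev$Py))),
    numeric(n + n_x))
  if (is.null(dim(u))) u <- matrix(u, ncol = length(kernels),
                                   dimnames = list(NULL, names(kernels)))
  rownames(u) <- pred_ids
  structure(list(
    sigma = tibble::tibble(term = nm, estimate = as.numeric(s)),
    beta = as.numeric(ev$beta),
    u = u,
    loglik = as.numeric(ev$ll),
    converged = converged || max_iter == 0L,
    iterations = it,
    n = n), class = "gs_reml")
}

#' @export
print.gs_reml <- function(x, ...) {
  cat("<gs_reml> n =", x$n, "| iterations =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$sigma)
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x a `gs_reml` object.
#' @param ... unused.
#' @return A tibble with one row per variance component.
#' @export
tidy.gs_reml <- function(x, ...) x$sigma

#' One-row summary of a REML fit
#'
#' @param x a `gs_reml` object.
#' @param ... unused.
#' @return A one-row tibble: `n`, `logLik`, `iterations`, `converged`,
#'   total variance and the ratio of the first kernel's component to the
#'   total (`h2_first`).
#' @export
glance.gs_reml <- function(x, ...) {
  tot <- sum(x$sigma$estimate)
  tibble::tibble(n = x$n, logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, total_variance = tot,
                 h2_first = x$sigma$estimate[1] / tot)
}

#' BLUPs from a REML fit
#'
#' @param object a `gs_reml` object.
#' @param kernel kernel name (default the first, conventionally the additive
#'   kernel used as the selection criterion).
#' @param ... unused.
#' @return Named numeric vector of predicted genetic values for all units.
#' @export
predict.gs_reml <- function(object, kernel = colnames(object$u)[1], ...) {
  setNames(object$u[, kernel], rownames(object$u))
}
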