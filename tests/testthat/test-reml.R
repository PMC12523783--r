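# simulate additive data over a marker panel: y = Z u + e
sim_additive <- function(n = 300, m = 500, h2 = 0.5, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(seq_len(n), NULL))
  b <- rnorm(m, 0, 1)
  g <- as.numeric(scale(M %*% b)) * sqrt(h2)
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  list(M = M, y = y, g = g)
}

test_that("single identity kernel recovers the total variance", {
  set.seed(5)
  y <- rnorm(200, 3, 2)
  fit <- reml_fit(y, list(id = diag(200)))
  tot <- sum(fit$sigma$estimate)
  expect_equal(tot, var(y), tolerance = 0.05 * var(y))
  expect_equal(fit$beta, mean(y), tolerance = 0.05)
})

test_that("REML recovers heritability on simulated additive data", {
  h2_hat <- vapply(1:20, function(r) {
    d <- sim_additive(n = 300, m = 500, h2 = 0.5, seed = r)
    G <- vanraden_G(d$M)
    fit <- reml_fit(d$y, list(additive = G))
    s <- setNames(fit$sigma$estimate, fit$sigma$term)
    s["additive"] / sum(s)
  }, 0)
  expect_equal(mean(h2_hat), 0.5, tolerance = 0.1)
  expect_lt(mean(abs(h2_hat - 0.5)), 0.15)
})

test_that("BLUPs equal the mixed-model-equation solution at fixed components", {
  # <= 20-individual instance; MME with K^{-1} is the independent oracle
  set.seed(6)
  n <- 15
  X <- matrix(rnorm(30), n, 2); X[, 1] <- 1
  L <- matrix(rnorm(n * n), n)
  K <- tcrossprod(L) / n + diag(n) * 0.1
  rownames(K) <- colnames(K) <- seq_len(n)
  y <- rnorm(n)
  s_u <- 0.7; s_e <- 0.4
  fit <- reml_fit(y, list(u = K), X = X, max_iter = 0,
                  start = c(u = s_u, residual = s_e), condition = 0)
  # Henderson MME: [X'X  X'Z; Z'X  Z'Z + Ki*se/su] [b; u] = [X'y; Z'y]
  lam <- s_e / s_u
  Ki <- solve(K)
  LHS <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + Ki * lam))
  RHS <- c(crossprod(X, y), y)
  sol <- solve(LHS, RHS)
  expect_equal(fit$beta, unname(sol[1:2]), tolerance = 1e-8)
  expect_equal(unname(fit$u[, "u"]), unname(sol[-(1:2)]), tolerance = 1e-8)
})

test_that("a pedigree-A kernel reproduces pedigree BLUP from the MME oracle", {
  set.seed(7)
  ped <- tibble::tibble(id = 1:30,
                        sire = c(rep(NA, 10), sample(1:5, 20, TRUE)),
                        dam = c(rep(NA, 10), sample(6:10, 20, TRUE)))
  A <- pedigree_A(ped)
  y <- rnorm(30, 5)
  s_a <- 0.5; s_e <- 0.5
  fit <- reml_fit(y, list(additive = A), max_iter = 0,
                  start = c(additive = s_a, residual = s_e), condition = 0)
  lam <- s_e / s_a
  X <- matrix(1, 30, 1)
  LHS <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(30) + solve(A) * lam))
  sol <- solve(LHS, c(sum(y), y))
  expect_equal(unname(fit$u[, 1]), unname(sol[-1]), tolerance = 1e-8)
})

test_that("variance components are invariant to phenotype mean shifts", {
  d <- sim_additive(n = 200, m = 300, h2 = 0.4, seed = 33)
  G <- vanraden_G(d$M)
  f1 <- reml_fit(d$y, list(a = G))
  f2 <- reml_fit(d$y + 100, list(a = G))
  expect_equal(f1$sigma$estimate, f2$sigma$estimate, tolerance = 1e-5)
  expect_equal(f2$beta - f1$beta, 100, tolerance = 1e-5)
})

test_that("predictions are linear in y and shrink with the variance ratio", {
  set.seed(8)
  n <- 40
  L <- matrix(rnorm(n * n), n)
  K <- tcrossprod(L) / n + diag(n) * 0.1
  rownames(K) <- colnames(K) <- seq_len(n)
  y1 <- rnorm(n); y2 <- rnorm(n)
  at <- function(y, s_u) reml_fit(y, list(u = K), max_iter = 0,
                                  start = c(u = s_u, residual = 1),
                                  condition = 0)$u[, 1]
  # linearity at fixed components: u(y1 + y2) = u(y1) + u(y2)
  expect_equal(at(y1 + y2, 0.5), at(y1, 0.5) + at(y2, 0.5),
               tolerance = 1e-8)
  # shrinkage toward zero as sigma_u^2 -> 0
  expect_lt(max(abs(at(y1, 1e-8))), 1e-6)
  expect_gt(max(abs(at(y1, 1))), 0.1)
})

test_that("unphenotyped units are predicted through the kernel", {
  d <- sim_additive(n = 250, m = 400, h2 = 0.6, seed = 9)
  G <- vanraden_G(d$M)
  y <- d$y
  y[201:250] <- NA  # candidates: genotyped, not phenotyped
  fit <- reml_fit(y, list(additive = G))
  expect_equal(nrow(fit$u), 250)
  r <- cor(fit$u[201:250, "additive"], d$g[201:250])
  expect_gt(r, 0.3)
  # tt/xt kernel form gives the same predictions
  fit2 <- reml_fit(d$y[1:200],
                   list(additive = list(tt = G[1:200, 1:200],
                                        xt = G[201:250, 1:200])),
                   start = setNames(fit$sigma$estimate, fit$sigma$term),
                   max_iter = 0)
  expect_equal(unname(fit2$u[201:250, 1]), unname(fit$u[201:250, 1]),
               tolerance = 1e-6)
})

test_that("tidy and glance summarise fits", {
  set.seed(10)
  y <- rnorm(100)
  fit <- reml_fit(y, list(id = diag(100)))
  td <- tidy(fit)
  expect_equal(td$term, c("id", "residual"))
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_true(is.finite(gl$logLik))
  expect_equal(gl$h2_first, td$estimate[1] / sum(td$estimate))
  expect_length(predict(fit), 100)
})
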