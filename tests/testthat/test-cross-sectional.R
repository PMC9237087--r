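test_that("spearman_corr handles monotone, anti-monotone and null pairs", {
  x <- 1:50
  d <- data.frame(a = x, b = exp(x / 10), c = -x^3)
  R <- spearman_corr(d)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)

  set.seed(3)
  u <- data.frame(matrix(runif(10000 * 3), ncol = 3))
  Ru <- spearman_corr(u)
  expect_lt(max(abs(Ru[upper.tri(Ru)])), 0.05)

  d$a <- 1
  expect_error(spearman_corr(d), "constant")
})

test_that("the glasso path spans empty to complete structures", {
  set.seed(11)
  m <- 4
  K <- diag(m)
  K[1, 2] <- K[2, 1] <- 0.45
  K[3, 4] <- K[4, 3] <- -0.4
  X <- MASS::mvrnorm(5000, rep(0, m), solve(K))
  S <- stats::cor(X)
  path <- glasso_path(S, nrow(X), n_lambda = 40)
  sizes <- vapply(path$structures, sum, numeric(1)) / 2
  expect_equal(min(sizes), 0)                       # full shrinkage
  expect_equal(max(sizes), m * (m - 1) / 2)         # penalty -> 0
  # the true structure appears somewhere on the path
  truth <- (K != 0) * 1L
  diag(truth) <- 0L
  expect_true(any(vapply(path$structures, identical, logical(1), truth)))
})

test_that("unregularised refits match closed forms and a numeric oracle", {
  set.seed(21)
  m <- 4
  X <- MASS::mvrnorm(800, rep(0, m), diag(m) + 0.4)
  S <- stats::cor(X)
  n <- nrow(X)

  complete <- matrix(1L, m, m); diag(complete) <- 0L
  fit_c <- refit_unregularized(S, n, complete)
  K <- solve(S)
  d <- 1 / sqrt(diag(K))
  pc <- -K * tcrossprod(d); diag(pc) <- 0
  expect_equal(fit_c$partial_corr, pc, tolerance = 1e-7)
  # saturated Gaussian log-likelihood, closed form
  expect_equal(fit_c$loglik,
               -0.5 * n * (m * log(2 * pi) +
                             as.numeric(determinant(S)$modulus) + m),
               tolerance = 1e-6)

  empty <- matrix(0L, m, m)
  fit_e <- refit_unregularized(S, n, empty)
  expect_equal(fit_e$precision, diag(1 / diag(S)), tolerance = 1e-8)

  # one constrained zero vs direct numeric optimisation over free entries
  st <- complete
  st[1, 2] <- st[2, 1] <- 0L
  fit_1 <- refit_unregularized(S, n, st)
  free_idx <- which(upper.tri(st) & st == 1L)
  obj <- function(par) {
    Th <- diag(exp(par[1:m]))
    Th[free_idx] <- par[-(1:m)]
    Th[lower.tri(Th)] <- t(Th)[lower.tri(Th)]
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(1e8)
    0.5 * n * (m * log(2 * pi) - determinant(Th)$modulus[1] + sum(Th * S))
  }
  o <- stats::optim(c(rep(0, m), rep(0.01, length(free_idx))), obj,
                    method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(-o$value, fit_1$loglik, tolerance = 1e-5)
})

test_that("EBIC scores and stepwise selection find the sparse truth", {
  expect_equal(ebic(-100, 3, 500, 6, 0), 200 + 3 * log(500))
  expect_equal(ebic(-100, 3, 500, 6, 0.5), 200 + 3 * log(500) + 6 * log(6))
  # adding an edge with no likelihood gain strictly worsens the score
  expect_gt(ebic(-100, 4, 500, 6, 0), ebic(-100, 3, 500, 6, 0))

  # diagonal-covariance data select the empty graph
  set.seed(41)
  d0 <- data.frame(matrix(rnorm(4000), ncol = 4))
  sel0 <- ggm_modselect(d0)
  expect_equal(sum(sel0$structure), 0)

  # determinism
  set.seed(42)
  d1 <- data.frame(MASS::mvrnorm(1500, rep(0, 4), diag(4) + 0.3))
  expect_identical(ggm_modselect(d1)$structure, ggm_modselect(d1)$structure)
})

test_that("redundancy screening flags duplicates and spares independents", {
  set.seed(8)
  X <- as.data.frame(MASS::mvrnorm(1500, rep(0, 4), diag(4) + 0.35))
  X$dup <- X$V4 + rnorm(1500, 0, 0.05)
  gb <- goldbricker(X, corr_min = 0.5)
  flagged <- gb[gb$redundant, ]
  expect_true(any(flagged$item_a == "V4" & flagged$item_b == "dup"))

  # threshold 0 can flag nothing
  gb0 <- goldbricker(X, corr_min = 0.5, prop_threshold = 0)
  expect_false(any(gb0$redundant))

  # mutually independent items: no pair is even screened at corr_min 0.5
  set.seed(9)
  ind <- as.data.frame(matrix(rnorm(5000 * 5), ncol = 5))
  gbi <- goldbricker(ind, corr_min = 0.5)
  expect_equal(nrow(gbi), 0)

  expect_error(goldbricker(X[, 1:3]), "4 items")
})
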