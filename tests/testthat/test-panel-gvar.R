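test_that("free-parameter accounting matches closed forms and adjacency", {
  expect_equal(count_free_parameters(1, 2),
               list(n_free = 4L, moments = 5L, df = 1L))
  # explicit slot enumeration at m=4, W=3: 4 means + 16 temporal +
  # (6 + 4) contemporaneous + (6 + 4) between = 40; K = 12 variables
  # carry 12 means + 78 (co)variances = 90 moments
  expect_equal(count_free_parameters(4, 3),
               list(n_free = 40L, moments = 90L, df = 50L))

  adj <- list(beta = diag(3), omega_zeta = matrix(0, 3, 3),
              omega_between = matrix(1, 3, 3))
  cf <- count_free_parameters(3, 3, adj)
  # 3 means + 3 autoregressions + (0 + 3) + (3 + 3) free slots
  expect_equal(cf$n_free, 15L)
  expect_equal(cf$df, cf$moments - 15L)
})

test_that("FIML equals closed forms and is invariant to grouping/order", {
  fx <- tiny_panel(n = 40, m = 3, W = 4, dropout = 0.35, seed = 13)
  p <- fx$params
  mom <- implied_moments(p, 4)
  X <- panelnet:::panel_to_wide(fx$panel, 4)

  # naive per-subject oracle
  ll_naive <- sum(vapply(seq_len(nrow(X)), function(i) {
    o <- which(!is.na(X[i, ]))
    S <- mom$covariance[o, o, drop = FALSE]
    d <- X[i, o] - mom$mean[o]
    -0.5 * (length(o) * log(2 * pi) +
              as.numeric(determinant(S)$modulus) +
              drop(t(d) %*% solve(S) %*% d))
  }, numeric(1)))
  expect_equal(fiml_loglik(p, fx$panel, 4), ll_naive, tolerance = 1e-10)

  # subject-order invariance
  shuffled <- fx$panel[rev(seq_len(nrow(fx$panel))), ]
  expect_equal(fiml_loglik(p, shuffled, 4), ll_naive, tolerance = 1e-10)

  # single subject, one observed variable: univariate normal density
  one <- fx$panel[1, ]
  one[, c("item2", "item3")] <- NA
  v <- mom$covariance[1, 1]
  z <- one$item1 - mom$mean[1]
  expect_equal(fiml_loglik(p, one, 4),
               unname(-0.5 * (log(2 * pi * v) + z^2 / v)),
               tolerance = 1e-10)
})

test_that("saturated and baseline likelihoods behave as ML estimators", {
  fx <- tiny_panel(n = 300, m = 3, W = 3, seed = 21)
  X <- panelnet:::panel_to_wide(fx$panel, 3)
  sat <- saturated_loglik(fx$panel, 3)
  # complete data: closed-form ML moments (n denominator)
  Sml <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  expect_equal(sat$mean, colMeans(X), tolerance = 1e-9)
  expect_equal(sat$covariance, Sml, tolerance = 1e-9)

  # EM under MCAR missingness recovers the truth within sampling error
  cfg <- tiny_truth(m = 2, W = 3, seed = 17)
  p <- default_true_parameters(cfg)
  pan <- simulate_panel(p, cfg, 3000, continuous = TRUE, seed = 23)
  items <- c("item1", "item2")
  set.seed(55)
  for (it in items) pan[[it]][runif(nrow(pan)) < 0.25] <- NA
  pan <- pan[rowSums(!is.na(pan[, items])) > 0, ]
  satm <- saturated_loglik(pan, 3)
  mom <- implied_moments(p, 3)
  expect_lt(max(abs(satm$covariance - mom$covariance)), 0.12)
  expect_true(satm$converged)
  # the saturated model dominates any structured fit
  fit <- fit_panel_gvar(pan, 3)
  expect_gte(satm$loglik, fit$loglik)

  # baseline df arithmetic and calibration on independent data
  expect_equal(baseline_loglik(fx$panel, 3)$df + 2L * 9L,
               count_free_parameters(3, 3)$moments)
  # fully independent wave-item variables (no intercepts, no dynamics)
  set.seed(31)
  wpan <- data.frame(subject_id = rep(sprintf("S%04d", 1:2000), each = 3),
                     wave = rep(1:3, 2000),
                     item1 = rnorm(6000), item2 = rnorm(6000),
                     item3 = rnorm(6000))
  bs <- baseline_loglik(wpan, 3)
  st <- saturated_loglik(wpan, 3)
  chisq_b <- 2 * (st$loglik - bs$loglik)
  expect_lt(abs(chisq_b - bs$df), 4 * sqrt(2 * bs$df))
})

test_that("fitting recovers the data-generating parameters", {
  cfg <- tiny_truth(m = 4, W = 4, seed = 7)
  p <- default_true_parameters(cfg)
  pan <- simulate_panel(p, cfg, 2000, continuous = TRUE, seed = 41)
  fit <- fit_panel_gvar(pan, 4)
  expect_true(fit$converged)
  expect_true(fit$stationary)
  expect_gt(stats::cor(as.numeric(p$beta), as.numeric(fit$params$beta)), 0.9)
  expect_lt(max(abs(fit$params$omega_zeta - p$omega_zeta)), 0.1)

  # adjacency of all ones is the saturated model
  ones <- list(beta = matrix(1, 4, 4), omega_zeta = matrix(1, 4, 4),
               omega_between = matrix(1, 4, 4))
  fit2 <- fit_panel_gvar(pan, 4, adjacency = ones)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-4)
  expect_equal(fit2$n_free, fit$n_free)
})

test_that("equality-constrained two-group fits honour their contracts", {
  fx <- tiny_panel(n = 400, m = 3, W = 3, seed = 2)
  single <- fit_panel_gvar(fx$panel, 3)
  dup <- fit_multigroup_equal(fx$panel, fx$panel, 3)
  expect_equal(dup$params$beta, single$params$beta, tolerance = 1e-4)
  expect_equal(dup$df, 2L * single$moments - single$n_free)

  # two samples from one truth: equality model fits well
  cfg <- fx$cfg
  p <- fx$params
  pan_a <- simulate_panel(p, cfg, 1200, continuous = TRUE, seed = 71)
  pan_b <- simulate_panel(p, cfg, 800, continuous = TRUE, seed = 72)
  eq <- fit_multigroup_equal(pan_a, pan_b, 3)
  rep_eq <- model_fit_report(eq, list(pan_a, pan_b))
  expect_lt(rep_eq$rmsea, 0.05)

  # different truths: equality misfit exceeds the free-groups chi-squares
  p2 <- default_true_parameters(tiny_truth(m = 3, W = 3, seed = 99,
                                           auto_mean = 0.45))
  p2$omega_zeta <- -p$omega_zeta
  pan_c <- simulate_panel(p2, cfg, 800, continuous = TRUE, seed = 73)
  eq_bad <- fit_multigroup_equal(pan_a, pan_c, 3)
  free_a <- fit_panel_gvar(pan_a, 3)
  free_c <- fit_panel_gvar(pan_c, 3)
  sat_ac <- saturated_loglik(pan_a, 3)$loglik + saturated_loglik(pan_c, 3)$loglik
  chisq_eq <- 2 * (sat_ac - eq_bad$loglik)
  chisq_free <- 2 * (sat_ac - free_a$loglik - free_c$loglik)
  expect_gt(chisq_eq, chisq_free + 100)
})

test_that("edge inference produces calibrated Wald machinery", {
  fx <- tiny_panel(n = 1500, m = 3, W = 3, seed = 12)
  fit <- edge_inference(fit_panel_gvar(fx$panel, 3), alpha = 1)
  # alpha = 1 flags every free edge
  expect_true(all(fit$significant$beta))
  expect_true(all(fit$significant$omega_zeta[upper.tri(diag(3))]))
  # a strong true autoregression is detected at any practical level
  strongest <- which.max(diag(fx$params$beta))
  expect_lt(fit$pvalues$beta[strongest, strongest], 1e-8)
  # CIs cover the point estimates
  expect_true(all(fit$ci_lower$beta <= fit$params$beta + 1e-12 &
                    fit$params$beta <= fit$ci_upper$beta + 1e-12))
})
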