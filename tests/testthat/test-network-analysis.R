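make_network_set <- function(temporal, contemporaneous = NULL,
                             between = NULL) {
  m <- nrow(temporal)
  z <- matrix(0, m, m, dimnames = dimnames(temporal))
  structure(list(temporal = temporal,
                 contemporaneous = contemporaneous %||% z,
                 between = between %||% z,
                 masks = list(), autoregressive = diag(temporal),
                 alpha = 1), class = "network_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expected influence sums signed edges without the self-loop", {
  tm <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tm["b", "a"] <- 0.2   # a -> b
  tm["c", "a"] <- 0.3   # a -> c
  diag(tm) <- 0.5       # self-loops must not count
  ei <- expected_influence(make_network_set(tm))
  expect_equal(ei$out_ei[ei$item == "a"], 0.5)
  expect_equal(ei$in_ei[ei$item == "b"], 0.2)
  expect_equal(ei$in_ei[ei$item == "a"], 0)
  # z columns standardised across items
  expect_equal(mean(ei$z_out_ei), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ei$z_out_ei), 1, tolerance = 1e-12)

  # zero network: EI 0, degenerate z reported as 0 with a flag
  ei0 <- expected_influence(make_network_set(matrix(0, 3, 3,
                            dimnames = list(letters[1:3], letters[1:3]))))
  expect_true(all(ei0$in_ei == 0))
  expect_true(all(ei0$z_in_ei == 0))
  expect_true("in_ei" %in% attr(ei0, "degenerate"))

  # permutation equivariance
  set.seed(5)
  tm2 <- matrix(rnorm(16), 4, dimnames = list(letters[1:4], letters[1:4]))
  perm <- c(3, 1, 4, 2)
  ei_a <- expected_influence(make_network_set(tm2))
  ei_b <- expected_influence(make_network_set(tm2[perm, perm]))
  expect_equal(ei_b$out_ei[match(ei_a$item, ei_b$item)], ei_a$out_ei)

  # undirected EI equals in-EI = out-EI of the symmetric embedding
  sym <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  sym[1, 2] <- sym[2, 1] <- 0.4
  sym[2, 3] <- sym[3, 2] <- -0.1
  ei_s <- expected_influence(make_network_set(sym, contemporaneous = sym))
  expect_equal(ei_s$ei_contemporaneous, ei_s$in_ei)
  expect_equal(ei_s$ei_contemporaneous, ei_s$out_ei)
})

test_that("density sums absolute weights over unique edges", {
  expect_equal(network_density(matrix(0, 4, 4)), 0)
  und <- matrix(0, 3, 3)
  und[1, 2] <- und[2, 1] <- 0.5
  und[1, 3] <- und[3, 1] <- -0.25
  expect_equal(network_density(und), 0.75)
  expect_equal(network_density(und, signed = TRUE), 0.25)
  expect_equal(network_density(und, directed = TRUE), 1.5)
  # permutation invariance
  perm <- c(2, 3, 1)
  expect_equal(network_density(und[perm, perm]), network_density(und))
})

test_that("network comparison is a rank correlation over unique edges", {
  set.seed(9)
  a <- matrix(rnorm(25), 5)
  a <- (a + t(a)) / 2
  expect_equal(compare_networks(a, a), 1)
  expect_equal(compare_networks(a, a^3), 1)          # monotone transform
  expect_equal(compare_networks(a, exp(2 * a)), 1)
  b <- matrix(rnorm(25), 5); b <- (b + t(b)) / 2
  expect_equal(compare_networks(a, b), compare_networks(b, a))
  expect_warning(r <- compare_networks(a, matrix(1, 5, 5)), "constant")
  expect_true(is.na(r))

  # null distribution: independent 16-node networks rarely exceed |r| .25
  set.seed(77)
  rs <- replicate(60, {
    x <- matrix(rnorm(256), 16); x <- (x + t(x)) / 2
    y <- matrix(rnorm(256), 16); y <- (y + t(y)) / 2
    compare_networks(x, y)
  })
  expect_lt(mean(abs(rs) >= 0.25), 0.05)
})

test_that("extract_networks carries estimates, masks and self-loops", {
  fx <- tiny_panel(n = 800, m = 3, W = 3, seed = 25)
  fit <- fit_panel_gvar(fx$panel, 3)
  nets <- extract_networks(fit, alpha = 1)
  expect_true(all(nets$masks$temporal))
  expect_equal(nets$temporal, fit$params$beta, ignore_attr = TRUE)
  expect_true(isSymmetric(nets$contemporaneous))
  expect_true(isSymmetric(nets$between))
  expect_equal(unname(nets$autoregressive), unname(diag(fit$params$beta)))

  el <- network_edge_list(nets$temporal, nets$masks$temporal, directed = TRUE)
  expect_equal(nrow(el), 6)  # off-diagonal ordered pairs of 3 nodes
  el_u <- network_edge_list(nets$contemporaneous)
  expect_equal(nrow(el_u), 3)

  # estimated Out-EI ranking tracks the true one (cross-lag magnitudes
  # large enough that the true EI spread dominates estimation noise)
  cfg <- tiny_truth(m = 6, W = 4, seed = 33, cross_mean = 0.15)
  p <- default_true_parameters(cfg)
  pan <- simulate_panel(p, cfg, 5000, continuous = TRUE, seed = 133)
  fit6 <- fit_panel_gvar(pan, 4)
  true_out <- colSums(p$beta) - diag(p$beta)
  est_out <- colSums(fit6$params$beta) - diag(fit6$params$beta)
  expect_gte(stats::cor(true_out, est_out, method = "spearman"), 0.8)
})
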