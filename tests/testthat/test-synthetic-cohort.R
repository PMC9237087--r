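test_that("config validation enforces the inclusion-rule geometry", {
  expect_error(truth_config(n_waves = 2), "n_waves")
  expect_error(truth_config(temporal_density = 1.2), "densities")
  expect_silent(truth_config(n_items = 2, n_waves = 3))
})

test_that("true parameters honour density settings and are reproducible", {
  cfg0 <- truth_config(n_items = 4, n_waves = 4, temporal_density = 0,
                       seed = 5)
  p0 <- default_true_parameters(cfg0)
  off <- p0$beta[row(p0$beta) != col(p0$beta)]
  expect_true(all(off == 0))
  expect_true(all(diag(p0$beta) != 0))

  cfg_white <- truth_config(n_items = 4, n_waves = 4, temporal_density = 0,
                            auto_mean = 0, contemporaneous_density = 0,
                            seed = 5)
  pw <- default_true_parameters(cfg_white)
  expect_equal(pw$beta, matrix(0, 4, 4))
  expect_equal(pw$omega_zeta, matrix(0, 4, 4))
  expect_equal(pw$omega_between, matrix(0, 4, 4))

  cfg <- truth_config(n_items = 4, n_waves = 4, seed = 11)
  expect_identical(default_true_parameters(cfg), default_true_parameters(cfg))
  expect_lt(max(Mod(eigen(default_true_parameters(cfg)$beta)$values)), 1)
})

test_that("simulated panels satisfy shape, inclusion and dropout contracts", {
  expect_equal(nrow(simulate_panel(default_true_parameters(tiny_truth()),
                                   tiny_truth(), 0)), 0)

  fx <- tiny_panel(n = 60, m = 4, W = 6, dropout = 0.3, seed = 9,
                   continuous = FALSE)
  waves_per <- table(fx$panel$subject_id)
  expect_true(all(waves_per >= 3))
  expect_false(anyDuplicated(fx$panel[, c("subject_id", "wave")]) > 0)
  items <- setdiff(names(fx$panel), c("subject_id", "wave"))
  vals <- unlist(fx$panel[, items])
  expect_true(all(vals[!is.na(vals)] %in% 0:3))
  # dropout is monotone: observed waves are a prefix 1..k
  by_subj <- split(fx$panel$wave, fx$panel$subject_id)
  expect_true(all(vapply(by_subj, function(w) all(w == seq_along(w)),
                         logical(1))))

  fx0 <- tiny_panel(n = 25, m = 4, W = 5, dropout = 0, seed = 9)
  expect_equal(nrow(fx0$panel), 25 * 5)  # complete and rectangular
})

test_that("sample moments of large simulations match the implied moments", {
  cfg <- tiny_truth(m = 4, W = 4, seed = 5)
  p <- default_true_parameters(cfg)
  panel <- simulate_panel(p, cfg, 20000, continuous = TRUE, seed = 99)
  X <- panelnet:::panel_to_wide(panel, 4)
  mom <- implied_moments(p, 4)
  # zero trend, mu = 0: per-wave sample means near 0
  expect_lt(max(abs(colMeans(X))), 0.05)
  Sc <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  expect_lt(max(abs(Sc - mom$covariance)), 0.05)
  # lag-1 cross-covariance block equals beta %*% stationary covariance
  # (plus the between-person block), read off the implied structure
  m <- 4
  lag_block <- Sc[(m + 1):(2 * m), 1:m]
  S_w <- stationary_within_cov(p$beta, ggm_covariance(p$omega_zeta,
                                                      p$delta_zeta))
  Sigma_B <- ggm_covariance(p$omega_between, p$delta_between)
  expect_lt(max(abs(lag_block - (Sigma_B + p$beta %*% S_w))), 0.05)
})

test_that("panel CSV round-trips through write_panel_csv and load_panel", {
  fx <- tiny_panel(n = 30, m = 3, W = 4, dropout = 0.4, seed = 3,
                   continuous = FALSE)
  path <- tempfile(fileext = ".csv")
  write_panel_csv(fx$panel, path)
  back <- load_panel(path, max_wave = 4)
  expect_equal(as.data.frame(back), as.data.frame(fx$panel))
})
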