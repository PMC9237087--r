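test_that("load_panel applies the inclusion rule and wave cap", {
  d <- handmade_panel()
  # subject "b" observed at only 2 waves
  d <- d[!(d$subject_id == "b" & d$wave > 2), ]
  path <- write_temp_csv(d)
  expect_message(panel <- load_panel(path, max_wave = 4), "excluding 1")
  expect_setequal(unique(panel$subject_id), c("a", "c"))

  # waves beyond the cap are discarded
  d2 <- handmade_panel()
  extra <- handmade_panel()
  extra$wave <- extra$wave + 5L
  path2 <- write_temp_csv(rbind(d2, extra))
  expect_message(p2 <- load_panel(path2, max_wave = 6), "beyond wave 6")
  expect_true(all(p2$wave <= 6))

  # empty file with valid header
  path3 <- write_temp_csv(handmade_panel()[0, ])
  expect_equal(nrow(load_panel(path3)), 0)

  # malformed inputs fail loudly
  dup <- handmade_panel()
  dup <- rbind(dup, dup[1, ])
  expect_error(load_panel(write_temp_csv(dup)), "duplicate")
  oor <- handmade_panel()
  oor$item1[2] <- 9
  expect_error(load_panel(write_temp_csv(oor)), "out-of-range")
})

test_that("split_sample partitions subjects at the requested ratio", {
  fx <- tiny_panel(n = 10, m = 3, W = 3, seed = 1)
  sp <- split_sample(fx$panel, 0.6, seed = 4)
  expect_equal(length(unique(sp$training$subject_id)), 6)
  expect_equal(length(unique(sp$holdout$subject_id)), 4)
  expect_identical(split_sample(fx$panel, 0.6, seed = 4)$training,
                   sp$training)

  # partition property over ratios and seeds
  ids <- unique(fx$panel$subject_id)
  for (ratio in c(0.2, 0.5, 0.77)) {
    for (seed in 1:3) {
      sp <- split_sample(fx$panel, ratio, seed)
      got <- c(unique(sp$training$subject_id), unique(sp$holdout$subject_id))
      expect_setequal(got, ids)
      expect_equal(length(got), length(ids))
      expect_lte(abs(length(unique(sp$training$subject_id)) -
                       ratio * length(ids)), 1)
    }
  }
  expect_error(split_sample(fx$panel, 1.2), "ratio")
})

test_that("trend_test detects real slopes and is calibrated under the null", {
  fx <- tiny_panel(n = 500, m = 3, W = 4, trend = -0.5, seed = 8)
  tt <- trend_test(fx$panel, "item1")
  expect_lt(tt$wald_p, 1e-3)
  expect_lt(abs(tt$slope - (-0.5)), 0.1)

  # type-I error over null replicates
  cfg <- tiny_truth(m = 2, W = 4, trend = 0, seed = 1)
  p <- default_true_parameters(cfg)
  set.seed(31)
  rej <- mean(replicate(200, {
    pan <- simulate_panel(p, cfg, 60, continuous = TRUE,
                          seed = sample.int(2^31 - 1, 1))
    trend_test(pan, "item1")$wald_p < 0.05
  }))
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.11)

  cons <- handmade_panel()
  cons$item1 <- 1
  expect_error(trend_test(cons, "item1"), "constant")
})

test_that("detrend standardises each item-wave cell and is idempotent", {
  fx <- tiny_panel(n = 80, m = 3, W = 4, trend = -0.3, dropout = 0.3,
                   seed = 6, continuous = FALSE)
  d <- detrend(fx$panel)
  for (w in unique(d$wave)) {
    for (it in c("item1", "item2", "item3")) {
      v <- d[[it]][d$wave == w]
      v <- v[!is.na(v)]
      expect_lt(abs(mean(v)), 1e-8)
      expect_lt(abs(stats::sd(v) - 1), 1e-8)
    }
  }
  # missingness preserved
  expect_identical(is.na(d$item1), is.na(fx$panel$item1))
  # idempotence
  expect_equal(as.data.frame(detrend(d)), as.data.frame(d), tolerance = 1e-12)
  # affine invariance per item
  shifted <- fx$panel
  shifted$item2 <- 3 * shifted$item2 - 7
  expect_equal(detrend(shifted)$item2, d$item2, tolerance = 1e-12)

  const <- handmade_panel()
  const$item1[const$wave == 2] <- 5
  expect_error(detrend(const), "item1 at wave 2")
})
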