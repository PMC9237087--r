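# Small in-code fixtures shared across test files.

tiny_truth <- function(m = 3, W = 3, seed = 2, trend = 0, dropout = 0, ...) {
  truth_config(n_items = m, n_waves = W, trend_slope = trend,
               dropout_hazard = dropout, seed = seed, ...)
}

tiny_panel <- function(n = 400, m = 3, W = 3, seed = 2, continuous = TRUE,
                       ...) {
  cfg <- tiny_truth(m = m, W = W, seed = seed, ...)
  p <- default_true_parameters(cfg)
  list(cfg = cfg, params = p,
       panel = simulate_panel(p, cfg, n, continuous = continuous))
}

# Hand-built long panel for parsing/prep tests.
handmade_panel <- function() {
  data.frame(
    subject_id = rep(c("a", "b", "c"), each = 4),
    wave = rep(1:4, 3),
    item1 = c(1, 2, 3, 2, 0, 1, 2, 3, 3, 2, 1, 0),
    item2 = c(0, 1, 1, 2, 2, 2, 3, 1, 1, 0, 2, 2))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
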