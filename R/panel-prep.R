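#' Load a symptom panel from long-format CSV
#'
#' Expects the header \code{subject_id,wave,<item columns>} with ordinal
#' item scores (empty fields for missing). Applies the study inclusion
#' rule: subjects observed at fewer than three waves are dropped (a
#' message reports the count), and waves beyond \code{max_wave} are
#' discarded so only the first six sessions enter the analysis.
#'
#' @param path CSV file path.
#' @param max_wave Highest session retained; default 6.
#' @param max_score Largest admissible item score; default 3 (items
#'   scored 0-3). Use \code{Inf} for continuous panels.
#' @return A \code{symptom_panel} data frame.
#' @export
load_panel <- function(path, max_wave = 6L, max_score = 3) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L || !identical(names(raw)[1:2], c("subject_id", "wave"))) {
    stop_panelnet("panel CSV must start with columns subject_id, wave")
  }
  items <- names(raw)[-(1:2)]
  raw$subject_id <- as.character(raw$subject_id)
  raw$wave <- as.integer(raw$wave)
  if (anyNA(raw$wave) && nrow(raw) > 0) stop_panelnet("non-integer wave values")
  for (it in items) {
    v <- raw[[it]]
    if (is.logical(v) && all(is.na(v))) {
      # empty or fully-missing column reads as logical NA
      v <- as.numeric(v)
      raw[[it]] <- v
    }
    if (!is.numeric(v)) stop_panelnet("non-numeric values in item ", it)
    bad <- !is.na(v) & (v < 0 | v > max_score)
    if (any(bad)) {
      stop_panelnet("out-of-range values in item ", it,
                    " (rows ", paste(utils::head(which(bad), 3), collapse = ", "), ")")
    }
  }
  if (anyDuplicated(raw[, c("subject_id", "wave")])) {
    stop_panelnet("duplicate (subject_id, wave) records")
  }
  n_trunc <- sum(raw$wave > max_wave)
  if (n_trunc > 0) {
    message("discarding ", n_trunc, " records beyond wave ", max_wave)
    raw <- raw[raw$wave <= max_wave, , drop = FALSE]
  }
  obs <- rowSums(!is.na(raw[, items, drop = FALSE])) > 0
  raw <- raw[obs, , drop = FALSE]
  waves_per <- table(raw$subject_id)
  excluded <- names(waves_per)[waves_per < 3L]
  if (length(excluded) > 0) {
    message("excluding ", length(excluded),
            " subject(s) with fewer than 3 observed sessions")
    raw <- raw[!(raw$subject_id %in% excluded), , drop = FALSE]
  }
  raw <- raw[order(raw$subject_id, raw$wave), , drop = FALSE]
  rownames(raw) <- NULL
  structure(raw, class = c("symptom_panel", "data.frame"))
}

#' Split a panel into training and holdout samples by subject
#'
#' Subjects (not records) are partitioned at random; the training share
#' is \code{round(ratio * n)} subjects. The same seed always yields the
#' same partition.
#'
#' @param panel A symptom panel.
#' @param ratio Training fraction, strictly between 0 and 1; default 0.6.
#' @param seed Integer seed.
#' @return List with elements \code{training} and \code{holdout}.
#' @export
split_sample <- function(panel, ratio = 0.6, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop_panelnet("ratio must be in (0, 1)")
  ids <- sort(unique(as.character(panel$subject_id)))
  n_train <- as.integer(round(ratio * length(ids)))
  train_ids <- with_seed(seed, sample(ids, n_train))
  keep_class <- function(x) structure(x, class = c("symptom_panel", "data.frame"))
  list(training = keep_class(panel[panel$subject_id %in% train_ids, , drop = FALSE]),
       holdout = keep_class(panel[!(panel$subject_id %in% train_ids), , drop = FALSE]))
}

#' Test an item for linear change across sessions
#'
#' Fits a random-intercept linear-growth model (fixed intercept, fixed
#' session slope, subject random intercept, residual) by maximum
#' likelihood with \pkg{lme4}, and returns the Wald test of the session
#' slope against zero.
#'
#' @param panel A symptom panel.
#' @param item Item column name.
#' @return Data frame with \code{item}, \code{slope} (score units per
#'   session), \code{slope_se}, and \code{wald_p}.
#' @export
trend_test <- function(panel, item) {
  if (!item %in% names(panel)) stop_panelnet("unknown item ", item)
  d <- data.frame(y = panel[[item]], wave = panel$wave,
                  subject_id = panel$subject_id)
  d <- d[!is.na(d$y), , drop = FALSE]
  if (length(unique(d$wave)) < 2L || length(unique(d$subject_id)) < 2L) {
    stop_panelnet("trend test needs >= 2 waves and >= 2 subjects for ", item)
  }
  if (stats::var(d$y) == 0) {
    stop_panelnet("item ", item, " is constant; trend model is degenerate")
  }
  fit <- lme4::lmer(y ~ wave + (1 | subject_id), data = d, REML = FALSE)
  co <- summary(fit)$coefficients
  slope <- co["wave", "Estimate"]
  se <- co["wave", "Std. Error"]
  data.frame(item = item, slope = slope, slope_se = se,
             wald_p = 2 * stats::pnorm(-abs(slope / se)))
}

#' Run trend tests for every item in a panel
#'
#' @param panel A symptom panel.
#' @return Data frame with one [trend_test()] row per item.
#' @export
trend_tests <- function(panel) {
  do.call(rbind, lapply(panel_item_cols(panel), function(it) trend_test(panel, it)))
}

#' Detrend a panel by per-item, per-wave standardisation
#'
#' Removes trend effects in means and variances by standardising each
#' item within each wave over its observed cases (sample SD, n-1
#' denominator). Missingness is preserved. The operation is idempotent
#' and invariant to affine per-item rescaling of the input.
#'
#' @param panel A symptom panel.
#' @return A \code{symptom_panel} with continuous values; each item-wave
#'   cell has mean 0 and SD 1 over its observed cases.
#' @export
detrend <- function(panel) {
  items <- panel_item_cols(panel)
  out <- as.data.frame(panel)
  for (w in sort(unique(out$wave))) {
    idx <- out$wave == w
    for (it in items) {
      v <- out[[it]][idx]
      obs <- !is.na(v)
      if (sum(obs) < 2L) {
        stop_panelnet("cannot detrend item ", it, " at wave ", w,
                      ": fewer than 2 observed values")
      }
      s <- stats::sd(v[obs])
      if (s == 0) {
        stop_panelnet("zero variance for item ", it, " at wave ", w)
      }
      out[[it]][idx] <- (v - mean(v[obs])) / s
    }
  }
  structure(out, class = c("symptom_panel", "data.frame"), detrended = TRUE)
}
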