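#' Configuration of a synthetic symptom-panel cohort
#'
#' Describes the data-generating conditions for a simulated psychotherapy
#' cohort: each subject answers \code{n_items} ordinal symptom items
#' (0 to \code{ordinal_levels - 1}) at up to \code{n_waves} sessions,
#' symptom means decline linearly across sessions, within-person dynamics
#' follow a stationary lag-1 VAR with GGM-structured innovations, stable
#' between-person differences follow a second GGM, and subjects may drop
#' out monotonically after the third session, so every emitted subject
#' still satisfies the minimum-three-sessions inclusion rule.
#'
#' @param n_items Number of symptom items (default 16: 9 depression
#'   items followed by 7 anxiety items).
#' @param n_waves Number of sessions (waves), at least 3; default 6.
#' @param temporal_density Fraction of off-diagonal temporal (cross-lag)
#'   effects that are nonzero; default 0.8 (a dense temporal network).
#' @param auto_mean Mean autoregressive effect (diagonal of the temporal
#'   matrix); default 0.2.
#' @param cross_mean Mean magnitude of nonzero cross-lagged effects,
#'   signs random; default 0.03 (dense but weak).
#' @param contemporaneous_density Fraction of nonzero partial
#'   correlations in the contemporaneous and between-person GGMs;
#'   default 0.5.
#' @param trend_slope Linear change in latent item means per session, in
#'   score units; negative values encode improvement. Default -0.1.
#' @param dropout_hazard Per-session probability of monotone dropout,
#'   applying only after wave 3; default 0.15.
#' @param ordinal_levels Number of ordinal score levels (default 4,
#'   emulating 0-3 items).
#' @param seed Integer seed making parameter draws and simulation
#'   reproducible.
#' @return An object of class \code{truth_config}.
#' @export
truth_config <- function(n_items = 16L, n_waves = 6L,
                         temporal_density = 0.8, auto_mean = 0.2,
                         cross_mean = 0.03, contemporaneous_density = 0.5,
                         trend_slope = -0.1, dropout_hazard = 0.15,
                         ordinal_levels = 4L, seed = 1L) {
  cfg <- list(n_items = as.integer(n_items), n_waves = as.integer(n_waves),
              temporal_density = temporal_density, auto_mean = auto_mean,
              cross_mean = cross_mean,
              contemporaneous_density = contemporaneous_density,
              trend_slope = trend_slope, dropout_hazard = dropout_hazard,
              ordinal_levels = as.integer(ordinal_levels),
              seed = as.integer(seed))
  validate_truth_config(cfg)
  structure(cfg, class = "truth_config")
}

validate_truth_config <- function(cfg) {
  with(cfg, {
    if (n_items < 1L) stop_panelnet("n_items must be >= 1")
    if (n_waves < 3L) stop_panelnet("n_waves must be >= 3 (inclusion rule)")
    for (d in c(temporal_density, contemporaneous_density, dropout_hazard)) {
      if (d < 0 || d > 1) stop_panelnet("densities and hazards must lie in [0, 1]")
    }
    if (ordinal_levels < 2L) stop_panelnet("ordinal_levels must be >= 2")
  })
  invisible(cfg)
}

#' Draw a stationary ground-truth parameter set
#'
#' Samples a \code{panel_gvar_params} object consistent with the
#' configured densities and effect sizes: autoregressive effects centred
#' on \code{auto_mean}, cross-lagged effects present with probability
#' \code{temporal_density} and magnitudes centred on \code{cross_mean}
#' with random signs, and GGM partial correlations for the
#' contemporaneous and between-person blocks present with probability
#' \code{contemporaneous_density}. Draws are repeated (up to 100 times)
#' until the temporal matrix is stationary (spectral radius below 1) and
#' both GGM blocks are positive-definite; unreachable configurations
#' raise an error.
#'
#' @param cfg A [truth_config()].
#' @return A \code{panel_gvar_params} object (see [panel_gvar_params()]).
#' @export
default_true_parameters <- function(cfg) {
  validate_truth_config(cfg)
  m <- cfg$n_items
  with_seed(cfg$seed, {
    for (attempt in seq_len(100L)) {
      beta <- matrix(0, m, m)
      diag(beta) <- cfg$auto_mean * (1 + stats::runif(m, -0.25, 0.25))
      if (m > 1 && cfg$temporal_density > 0) {
        off <- which(row(beta) != col(beta))
        on <- off[stats::runif(length(off)) < cfg$temporal_density]
        beta[on] <- sample(c(-1, 1), length(on), replace = TRUE) *
          abs(stats::rnorm(length(on), cfg$cross_mean, cfg$cross_mean / 2))
      }
      omega_z <- draw_sparse_omega(m, cfg$contemporaneous_density, 0.15)
      omega_b <- draw_sparse_omega(m, cfg$contemporaneous_density, 0.15)
      ok <- spectral_radius(beta) < 0.95 &&
        is_pd(diag(m) - omega_z) && is_pd(diag(m) - omega_b)
      if (ok) {
        return(panel_gvar_params(
          mu = rep(0, m), beta = beta,
          omega_zeta = omega_z, delta_zeta = rep(1, m),
          omega_between = omega_b, delta_between = rep(0.8, m),
          items = default_item_names(m)))
      }
    }
  })
  stop_panelnet("could not draw stationary, positive-definite parameters ",
                "for this configuration after 100 attempts")
}

draw_sparse_omega <- function(m, density, magnitude) {
  omega <- matrix(0, m, m)
  if (m > 1 && density > 0) {
    up <- which(upper.tri(omega))
    on <- up[stats::runif(length(up)) < density]
    omega[on] <- sample(c(-1, 1), length(on), replace = TRUE) *
      abs(stats::rnorm(length(on), magnitude, magnitude / 2))
    omega <- omega + t(omega)
    # shrink towards diagonal dominance so (I - omega) stays PD
    rs <- max(rowSums(abs(omega)))
    if (rs >= 0.95) omega <- omega * 0.9 / rs
  }
  omega
}

is_pd <- function(x) {
  ev <- tryCatch(eigen((x + t(x)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values,
                 error = function(e) -Inf)
  min(ev) > 1e-10
}

#' Simulate a symptom panel from known parameters
#'
#' Per subject: a stable intercept vector is drawn from the
#' between-person GGM covariance; the wave-1 within-person deviation is
#' drawn from the stationary within-person covariance; subsequent waves
#' evolve by the lag-1 VAR with contemporaneous-GGM innovations; the
#' linear session trend is added to the means; latent values are
#' optionally ordinalised by fixed quantile thresholds of the latent
#' marginal (uniform margins across the score levels); monotone dropout
#' is applied after wave 3 with the configured per-session hazard.
#'
#' @param params A stationary [panel_gvar_params()] set.
#' @param cfg The [truth_config()] supplying trend, dropout, and
#'   ordinalisation settings.
#' @param n_subjects Number of subjects to simulate.
#' @param continuous If \code{TRUE}, emit the latent continuous values
#'   instead of ordinal scores.
#' @param seed Optional seed overriding \code{cfg$seed}.
#' @return A long-format data frame (\code{subject_id}, \code{wave}, one
#'   column per item) of class \code{symptom_panel}; missing cells are
#'   \code{NA}. Every subject has at least three observed waves.
#' @export
simulate_panel <- function(params, cfg, n_subjects,
                           continuous = FALSE, seed = cfg$seed) {
  validate_params(params)
  m <- length(params$mu)
  W <- cfg$n_waves
  items <- params$items %||% default_item_names(m)
  if (n_subjects == 0L) {
    out <- as.data.frame(c(list(subject_id = character(0), wave = integer(0)),
                           stats::setNames(rep(list(numeric(0)), m), items)))
    return(structure(out, class = c("symptom_panel", "data.frame")))
  }
  if (spectral_radius(params$beta) >= 1) {
    stop_panelnet("temporal matrix is not stationary (spectral radius >= 1)")
  }

  sigma_zeta <- ggm_covariance(params$omega_zeta, params$delta_zeta)
  sigma_b <- ggm_covariance(params$omega_between, params$delta_between)
  S_w <- stationary_within_cov(params$beta, sigma_zeta)

  with_seed(seed, {
    b <- MASS::mvrnorm(n_subjects, rep(0, m), sigma_b)
    if (n_subjects == 1L) b <- matrix(b, 1L)
    # within-person deviations, wave-major list of n x m matrices
    within <- vector("list", W)
    within[[1]] <- MASS::mvrnorm(n_subjects, rep(0, m), S_w)
    if (n_subjects == 1L) within[[1]] <- matrix(within[[1]], 1L)
    for (t in 2:W) {
      eta <- MASS::mvrnorm(n_subjects, rep(0, m), sigma_zeta)
      if (n_subjects == 1L) eta <- matrix(eta, 1L)
      within[[t]] <- within[[t - 1]] %*% t(params$beta) + eta
    }
    trend <- cfg$trend_slope * (seq_len(W) - 1)
    # last observed wave per subject: monotone dropout after wave 3
    last <- rep(W, n_subjects)
    if (cfg$dropout_hazard > 0 && W > 3L) {
      for (t in seq(4L, W)) {
        at_risk <- last == W
        drop_now <- at_risk & (stats::runif(n_subjects) < cfg$dropout_hazard)
        last[drop_now] <- t - 1L
      }
    }

    # marginal latent moments for fixed ordinalisation thresholds
    lat_sd <- sqrt(diag(S_w) + diag(sigma_b))
    probs <- seq_len(cfg$ordinal_levels - 1L) / cfg$ordinal_levels

    rows <- vector("list", W)
    for (t in seq_len(W)) {
      y <- sweep(within[[t]] + b, 2, params$mu + trend[t], `+`)
      if (!continuous) {
        for (j in seq_len(m)) {
          cuts <- stats::qnorm(probs, mean = params$mu[j] + trend[t],
                               sd = lat_sd[j])
          y[, j] <- findInterval(y[, j], cuts)
        }
      }
      y[last < t, ] <- NA_real_
      rows[[t]] <- data.frame(subject_id = sprintf("S%06d", seq_len(n_subjects)),
                              wave = t, y)
    }
  })
  out <- do.call(rbind, rows)
  names(out) <- c("subject_id", "wave", items)
  # drop fully-missing records (post-dropout waves)
  keep <- rowSums(!is.na(out[, items, drop = FALSE])) > 0
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$subject_id, out$wave), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("symptom_panel", "data.frame"))
}

#' Write a symptom panel to long-format CSV
#'
#' Header is \code{subject_id,wave,<item columns>}; missing values are
#' written as empty fields.
#'
#' @param panel A symptom panel data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}
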