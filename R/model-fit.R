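#' Likelihood-ratio chi-square against the saturated model
#'
#' \code{chisq = 2 * (LL_sat - LL_model)}, clipped at zero, with
#' \code{df = moments - n_free}. A model log-likelihood above the
#' saturated one beyond numerical tolerance signals a broken
#' optimisation and raises an error.
#'
#' @param model_loglik Fitted-model log-likelihood.
#' @param saturated_loglik Saturated-model log-likelihood (summed over
#'   groups for multigroup fits).
#' @param n_free Free-parameter count of the fitted model.
#' @param moments Number of observed first and second moments (summed
#'   over groups for multigroup fits).
#' @param tol Numerical tolerance for a negative statistic.
#' @return List with \code{chisq} and \code{df}.
#' @export
chisquare <- function(model_loglik, saturated_loglik, n_free, moments,
                      tol = 1e-6) {
  stat <- 2 * (saturated_loglik - model_loglik)
  if (stat < -tol * (abs(saturated_loglik) + 1)) {
    stop_panelnet("model log-likelihood exceeds the saturated log-likelihood",
                  " (chisq = ", signif(stat, 6), "); optimisation is broken")
  }
  list(chisq = max(stat, 0), df = as.integer(moments - n_free))
}

#' SEM fit-index battery
#'
#' Computes the incremental and noncentrality-based indices from the
#' model and independence-baseline chi-squares:
#' NFI, PNFI, TLI, RFI, IFI, CFI, and RMSEA. The RMSEA uses the
#' multigroup convention
#' \deqn{RMSEA = \sqrt{G \, \max(\chi^2_m - df_m, 0) / (df_m (N - G))}}
#' with G groups and total sample size N, which reduces to the standard
#' single-group formula at G = 1. TLI and RFI are reported uncapped.
#' Indices with a zero denominator are returned as \code{NA}.
#'
#' @param chisq_m,df_m Model chi-square and degrees of freedom.
#' @param chisq_b,df_b Baseline chi-square and degrees of freedom.
#' @param n_total Total number of subjects across groups.
#' @param n_groups Number of groups (default 1).
#' @return List of class \code{fit_indices} with \code{chisq}, \code{df},
#'   \code{nfi}, \code{pnfi}, \code{tli}, \code{rfi}, \code{ifi},
#'   \code{cfi}, \code{rmsea}, \code{n_total}, \code{n_groups}.
#' @export
fit_indices <- function(chisq_m, df_m, chisq_b, df_b, n_total, n_groups = 1L) {
  stopifnot(chisq_m >= 0, chisq_b >= 0)
  if (df_b < df_m) {
    # a model sparser than the independence baseline (heavily masked
    # confirmatory fits at small m): incremental indices are undefined
    warning("baseline df (", df_b, ") below model df (", df_m,
            "); incremental indices reported as NA")
    rmsea <- if (df_m == 0 || n_total <= n_groups) NA_real_ else {
      sqrt(n_groups * max(chisq_m - df_m, 0) / (df_m * (n_total - n_groups)))
    }
    return(structure(list(chisq = chisq_m, df = df_m, nfi = NA_real_,
                          pnfi = NA_real_, tli = NA_real_, rfi = NA_real_,
                          ifi = NA_real_, cfi = NA_real_, rmsea = rmsea,
                          n_total = n_total, n_groups = n_groups),
                     class = "fit_indices"))
  }
  safe_div <- function(num, den) if (!is.finite(den) || den == 0) NA_real_ else num / den
  nfi <- safe_div(chisq_b - chisq_m, chisq_b)
  pnfi <- if (df_b == 0) NA_real_ else (df_m / df_b) * nfi
  rb <- safe_div(chisq_b, df_b)
  rm_ <- safe_div(chisq_m, df_m)
  tli <- safe_div(rb - rm_, rb - 1)
  rfi <- if (is.na(rb) || is.na(rm_)) NA_real_ else 1 - rm_ / rb
  ifi <- safe_div(chisq_b - chisq_m, chisq_b - df_m)
  num_c <- max(chisq_m - df_m, 0)
  den_c <- max(chisq_m - df_m, chisq_b - df_b, 0)
  cfi <- if (den_c == 0) 1 else 1 - num_c / den_c
  rmsea <- if (df_m == 0 || n_total <= n_groups) NA_real_ else {
    sqrt(n_groups * max(chisq_m - df_m, 0) / (df_m * (n_total - n_groups)))
  }
  structure(list(chisq = chisq_m, df = df_m, nfi = nfi, pnfi = pnfi,
                 tli = tli, rfi = rfi, ifi = ifi, cfi = cfi, rmsea = rmsea,
                 n_total = n_total, n_groups = n_groups),
            class = "fit_indices")
}

#' RMSEA confidence interval by noncentral chi-square inversion
#'
#' Finds the noncentrality parameters whose noncentral chi-square
#' distributions place the observed statistic at the
#' \code{(1 +/- level) / 2} tail probabilities, then converts each to
#' the RMSEA scale \code{sqrt(G * lambda / (df * (N - G)))}.
#' Noncentralities are floored at zero, so the lower bound is 0 whenever
#' \code{chisq <= df}.
#'
#' @param chisq Observed chi-square.
#' @param df Degrees of freedom (> 0).
#' @param n_total Total subjects.
#' @param n_groups Number of groups.
#' @param level Confidence level (default 0.95).
#' @return Numeric \code{c(lower, upper)}.
#' @export
rmsea_ci <- function(chisq, df, n_total, n_groups = 1L, level = 0.95) {
  stopifnot(df > 0, n_total > n_groups)
  a <- (1 - level) / 2
  # lambda_upper: P(X_{df,lambda} <= chisq) = a ; lambda_lower: = 1 - a
  solve_lambda <- function(target_p) {
    f <- function(lam) stats::pchisq(chisq, df, ncp = lam) - target_p
    if (f(0) < 0) return(0)   # even lambda = 0 puts too little mass below
    hi <- max(chisq, df)
    while (f(hi) > 0 && hi < 1e10) hi <- hi * 2
    if (f(hi) > 0) {
      warning("noncentrality inversion failed; bound floored")
      return(0)
    }
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lam_lower <- solve_lambda(1 - a)
  lam_upper <- solve_lambda(a)
  to_rmsea <- function(lam) sqrt(n_groups * lam / (df * (n_total - n_groups)))
  c(lower = to_rmsea(lam_lower), upper = to_rmsea(lam_upper))
}

#' Full fit report for a fitted panel GVAR
#'
#' Convenience wrapper: computes the saturated and baseline
#' log-likelihoods for the fitted panels, the model chi-square, the
#' index battery, and the RMSEA confidence interval.
#'
#' @param model A \code{panel_gvar_fit}.
#' @param panels List of the panel(s) the model was fitted to (one per
#'   group).
#' @param level Confidence level for the RMSEA interval.
#' @return A \code{fit_indices} list augmented with \code{rmsea_ci},
#'   \code{n_free}, and the underlying log-likelihoods.
#' @export
model_fit_report <- function(model, panels, level = 0.95) {
  if (inherits(panels, "data.frame")) panels <- list(panels)
  stopifnot(length(panels) == model$n_groups)
  sat <- lapply(panels, saturated_loglik, W = model$W)
  base <- lapply(panels, baseline_loglik, W = model$W)
  ll_sat <- sum(vapply(sat, `[[`, numeric(1), "loglik"))
  ll_base <- sum(vapply(base, `[[`, numeric(1), "loglik"))
  n_total <- sum(vapply(sat, `[[`, numeric(1), "n"))
  moments_total <- model$n_groups * model$moments
  cs_m <- chisquare(model$loglik, ll_sat, model$n_free, moments_total)
  df_base <- sum(vapply(base, function(b) b$df, integer(1)))
  cs_b <- chisquare(ll_base, ll_sat, moments_total - df_base, moments_total)
  fi <- fit_indices(cs_m$chisq, cs_m$df, cs_b$chisq, df_base,
                    n_total, model$n_groups)
  ci <- if (cs_m$df > 0) {
    rmsea_ci(cs_m$chisq, cs_m$df, n_total, model$n_groups, level)
  } else c(lower = NA_real_, upper = NA_real_)
  fi$rmsea_ci <- ci
  fi$level <- level
  fi$n_free <- model$n_free
  fi$loglik_model <- model$loglik
  fi$loglik_saturated <- ll_sat
  fi$loglik_baseline <- ll_base
  fi
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chisq %.2f on df %d (n = %d, groups = %d)\n",
              x$chisq, x$df, x$n_total, x$n_groups))
  cat(sprintf("NFI %.3f  PNFI %.3f  TLI %.3f  RFI %.3f  IFI %.3f  CFI %.3f\n",
              x$nfi, x$pnfi, x$tli, x$rfi, x$ifi, x$cfi))
  if (!is.null(x$rmsea_ci)) {
    cat(sprintf("RMSEA %.3f (%d%% CI %.3f; %.3f)\n", x$rmsea,
                round(100 * (x$level %||% 0.95)), x$rmsea_ci[["lower"]],
                x$rmsea_ci[["upper"]]))
  } else {
    cat(sprintf("RMSEA %.3f\n", x$rmsea))
  }
  invisible(x)
}
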