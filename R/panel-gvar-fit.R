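# Internal parameterisation machinery for panel-GVAR fitting.
#
# Two coordinate systems are used over the same free-parameter set
# (mu, free beta entries, contemporaneous block, between block):
#   * "chol"  — each fully-free GGM block is carried as the lower
#     triangular factor L of its covariance (Sigma = L L'), so positive
#     definiteness is unconstrained during optimisation;
#   * "report" — each block is carried as free partial-correlation
#     entries plus log scalings, the form in which estimates, standard
#     errors and Wald tests are reported, and the only form that can
#     express structural zeros in omega.
# A block with masked omega entries is always optimised in report form
# (a zero partial correlation has no triangular-factor expression).

make_pspec <- function(m, items, adjacency = NULL) {
  adj <- complete_adjacency(adjacency %||% list(), m)
  beta_free <- adj$beta != 0
  oz_free <- adj$omega_zeta != 0 & upper.tri(adj$omega_zeta)
  ob_free <- adj$omega_between != 0 & upper.tri(adj$omega_between)
  zeta_chol <- sum(oz_free) == m * (m - 1) / 2
  between_chol <- sum(ob_free) == m * (m - 1) / 2
  n_free <- m + sum(beta_free) + (sum(oz_free) + m) + (sum(ob_free) + m)
  list(m = m, items = items, beta_free = beta_free,
       oz_free = oz_free, ob_free = ob_free,
       zeta_chol = zeta_chol, between_chol = between_chol,
       n_free = as.integer(n_free),
       adjacency = adj)
}

block_lengths <- function(spec, form) {
  m <- spec$m
  zeta <- if (form == "chol" && spec$zeta_chol) m * (m + 1) / 2 else sum(spec$oz_free) + m
  betw <- if (form == "chol" && spec$between_chol) m * (m + 1) / 2 else sum(spec$ob_free) + m
  c(mu = m, beta = sum(spec$beta_free), zeta = zeta, between = betw)
}

pack_ggm_block <- function(omega, delta, free_upper, use_chol) {
  if (use_chol) {
    L <- cov_to_chol(ggm_covariance(omega, delta))
    L[lower.tri(L, diag = TRUE)]
  } else {
    c(omega[free_upper], log(delta))
  }
}

unpack_ggm_block <- function(theta, m, free_upper, use_chol) {
  if (use_chol) {
    L <- matrix(0, m, m)
    L[lower.tri(L, diag = TRUE)] <- theta
    sigma <- chol_to_cov(L)
    gg <- tryCatch(cov_to_ggm(sigma), error = function(e) NULL)
    if (is.null(gg)) return(NULL)
    c(gg, list(sigma = sigma))
  } else {
    omega <- matrix(0, m, m)
    omega[free_upper] <- theta[seq_len(sum(free_upper))]
    omega <- omega + t(omega)
    delta <- exp(theta[sum(free_upper) + seq_len(m)])
    sigma <- tryCatch(ggm_covariance(omega, delta), error = function(e) NULL)
    if (is.null(sigma)) return(NULL)
    list(omega = omega, delta = delta, sigma = sigma)
  }
}

pack_theta <- function(params, spec, form) {
  c(params$mu,
    params$beta[spec$beta_free],
    pack_ggm_block(params$omega_zeta, params$delta_zeta, spec$oz_free,
                   form == "chol" && spec$zeta_chol),
    pack_ggm_block(params$omega_between, params$delta_between, spec$ob_free,
                   form == "chol" && spec$between_chol))
}

# Returns NULL when the coordinates do not describe a valid model
# (non-PD block); the likelihood then applies a penalty.
unpack_theta <- function(theta, spec, form) {
  m <- spec$m
  len <- block_lengths(spec, form)
  i <- 0L
  mu <- theta[i + seq_len(len["mu"])]; i <- i + len["mu"]
  beta <- matrix(0, m, m)
  beta[spec$beta_free] <- theta[i + seq_len(len["beta"])]; i <- i + len["beta"]
  bz <- unpack_ggm_block(theta[i + seq_len(len["zeta"])], m, spec$oz_free,
                         form == "chol" && spec$zeta_chol)
  i <- i + len["zeta"]
  bb <- unpack_ggm_block(theta[i + seq_len(len["between"])], m, spec$ob_free,
                         form == "chol" && spec$between_chol)
  if (is.null(bz) || is.null(bb)) return(NULL)
  list(mu = mu, beta = beta,
       omega_zeta = bz$omega, delta_zeta = bz$delta, sigma_zeta = bz$sigma,
       omega_between = bb$omega, delta_between = bb$delta,
       sigma_between = bb$sigma, items = spec$items)
}

# Implied mean/covariance without validation or dimnames, for the inner
# optimisation loop.
implied_cov_fast <- function(p, W) {
  m <- length(p$mu)
  sr <- spectral_radius(p$beta)
  if (sr >= 1) return(NULL)
  S_w <- tryCatch(stationary_within_cov(p$beta, p$sigma_zeta),
                  error = function(e) NULL)
  if (is.null(S_w)) return(NULL)
  pow <- vector("list", W)
  pow[[1]] <- diag(m)
  for (k in seq_len(W - 1)) pow[[k + 1]] <- pow[[k]] %*% p$beta
  K <- W * m
  Sigma <- matrix(0, K, K)
  for (t in seq_len(W)) {
    for (s in seq_len(t)) {
      blk <- p$sigma_between + pow[[t - s + 1]] %*% S_w
      rows <- ((t - 1) * m + 1):(t * m)
      cols <- ((s - 1) * m + 1):(s * m)
      Sigma[rows, cols] <- blk
      if (t != s) Sigma[cols, rows] <- t(blk)
    }
  }
  list(mean = rep(p$mu, W), covariance = (Sigma + t(Sigma)) / 2)
}

BIG_PENALTY <- 1e10

make_negloglik <- function(pstats_groups, W, spec, form, group_idx = NULL) {
  function(theta) {
    total <- 0
    for (g in seq_along(pstats_groups)) {
      th <- if (is.null(group_idx)) theta else theta[group_idx[[g]]]
      p <- unpack_theta(th, spec, form)
      if (is.null(p)) return(BIG_PENALTY)
      mom <- implied_cov_fast(p, W)
      if (is.null(mom)) return(BIG_PENALTY * (1 + spectral_radius(p$beta)))
      ll <- loglik_patterns(mom$mean, mom$covariance, pstats_groups[[g]])
      if (!is.finite(ll)) return(BIG_PENALTY)
      total <- total + ll
    }
    -total
  }
}

# Cheap consistent starting values from the wide data matrix: subject
# means feed the between block, within-person deviations feed a lag-1
# least-squares estimate of beta and the innovation covariance.
start_values <- function(X, m, W, spec) {
  mu_w <- matrix(colMeans(X, na.rm = TRUE), nrow = m)
  mu0 <- rowMeans(mu_w, na.rm = TRUE)
  mu0[!is.finite(mu0)] <- 0

  n <- nrow(X)
  subj_mean <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    subj_mean[, j] <- rowMeans(X[, seq(j, W * m, by = m), drop = FALSE],
                               na.rm = TRUE)
  }
  subj_mean[!is.finite(subj_mean)] <- NA
  Sigma_B0 <- 0.5 * stats::cov(subj_mean, use = "pairwise.complete.obs")
  Sigma_B0[!is.finite(Sigma_B0)] <- 0
  Sigma_B0 <- pdify(Sigma_B0)

  # within-person deviations stacked over waves
  D <- do.call(rbind, lapply(seq_len(W), function(t) {
    X[, ((t - 1) * m + 1):(t * m), drop = FALSE] - subj_mean
  }))
  S_w0 <- stats::cov(D, use = "pairwise.complete.obs")
  S_w0[!is.finite(S_w0)] <- 0
  S_w0 <- pdify(S_w0)

  P <- do.call(rbind, lapply(seq_len(W - 1), function(t) {
    X[, ((t - 1) * m + 1):(t * m), drop = FALSE] - subj_mean
  }))
  N <- do.call(rbind, lapply(seq_len(W - 1), function(t) {
    X[, (t * m + 1):((t + 1) * m), drop = FALSE] - subj_mean
  }))
  cc <- stats::complete.cases(P) & stats::complete.cases(N)
  beta0 <- if (sum(cc) > 5 * m) {
    Pc <- P[cc, , drop = FALSE]
    Nc <- N[cc, , drop = FALSE]
    t(solve(crossprod(Pc) + diag(1e-6, m), crossprod(Pc, Nc)))
  } else {
    diag(0.1, m)
  }
  sr <- spectral_radius(beta0)
  if (sr >= 0.9) beta0 <- beta0 * 0.85 / sr
  beta0[!spec$beta_free] <- 0

  sigma_z0 <- pdify(S_w0 - beta0 %*% S_w0 %*% t(beta0))
  gz <- cov_to_ggm(sigma_z0)
  gb <- cov_to_ggm(Sigma_B0)
  free_oz <- spec$oz_free | t(spec$oz_free)
  free_ob <- spec$ob_free | t(spec$ob_free)
  gz$omega[!free_oz] <- 0
  gb$omega[!free_ob] <- 0
  diag(gz$omega) <- 0
  diag(gb$omega) <- 0
  if (!is_pd(diag(m) - gz$omega)) gz$omega <- gz$omega * 0.5
  if (!is_pd(diag(m) - gb$omega)) gb$omega <- gb$omega * 0.5
  list(mu = mu0, beta = beta0,
       omega_zeta = gz$omega, delta_zeta = gz$delta,
       omega_between = gb$omega, delta_between = gb$delta,
       items = spec$items)
}

pdify <- function(S, floor_frac = 1e-3) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floor_val <- max(e$values) * floor_frac
  if (floor_val <= 0) return(diag(1, nrow(S)))
  v <- pmax(e$values, floor_val)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

fit_core <- function(pstats_groups, W, spec, start, control = list(),
                     group_idx = NULL, theta0 = NULL, n_free = spec$n_free) {
  form <- if ((spec$zeta_chol && spec$between_chol)) "chol" else "report"
  maxit <- control$maxit %||% 2000L
  reltol <- control$reltol %||% 1e-12
  nll <- make_negloglik(pstats_groups, W, spec, form, group_idx)
  if (is.null(theta0)) theta0 <- pack_theta(start, spec, form)
  ctl <- list(maxit = maxit, reltol = reltol,
              ndeps = rep(1e-6, length(theta0)))
  o <- stats::optim(theta0, nll, method = "BFGS", control = ctl)
  o <- stats::optim(o$par, nll, method = "BFGS", control = ctl)  # polish
  grad <- num_grad(nll, o$par)
  n_total <- sum(vapply(pstats_groups,
                        function(ps) attr(ps, "n_total"), numeric(1)))

  # per-group reported parameters
  to_params <- function(th) {
    p <- unpack_theta(th, spec, form)
    panel_gvar_params(p$mu, p$beta, p$omega_zeta, p$delta_zeta,
                      p$omega_between, p$delta_between, items = spec$items)
  }
  group_params <- if (is.null(group_idx)) {
    list(to_params(o$par))
  } else {
    lapply(group_idx, function(ix) to_params(o$par[ix]))
  }
  params <- group_params[[1]]

  moments <- count_free_parameters(spec$m, W)$moments
  df <- length(pstats_groups) * moments - n_free
  stationary <- all(vapply(group_params,
                           function(p) spectral_radius(p$beta) < 1, logical(1)))
  grad_norm <- max(abs(grad))
  structure(list(
    params = params, group_params = group_params,
    loglik = -o$value, n_subjects = n_total,
    n_free = as.integer(n_free), moments = as.integer(moments),
    df = as.integer(df), n_groups = length(pstats_groups),
    converged = o$convergence == 0 && grad_norm < 1e-2 * max(1, n_total),
    grad_norm = grad_norm, stationary = stationary,
    adjacency = spec$adjacency, items = spec$items, W = W,
    .spec = spec, .form = form, .pstats = pstats_groups,
    .group_idx = group_idx, .theta = o$par
  ), class = "panel_gvar_fit")
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

#' Fit a lag-1 panel graphical VAR by FIML
#'
#' Maximises the full-information likelihood over the free parameters.
#' Positive definiteness of the two GGM blocks is maintained by
#' optimising an unconstrained triangular-factor (Cholesky)
#' parameterisation; estimates are reported back as partial correlations
#' and scalings. When adjacency masks fix entries to zero, the affected
#' block is optimised directly in partial-correlation coordinates.
#' Stationarity of the temporal matrix is checked, not enforced, at the
#' optimum (the \code{stationary} flag).
#'
#' @param panel A (typically detrended) symptom panel.
#' @param W Wave count.
#' @param adjacency Optional list of 0/1 masks (\code{beta},
#'   \code{omega_zeta}, \code{omega_between}); masked entries are fixed
#'   at zero.
#' @param control List of optimisation settings (\code{maxit},
#'   \code{reltol}).
#' @return A \code{panel_gvar_fit} with the estimated
#'   [panel_gvar_params()], log-likelihood, free-parameter count,
#'   degrees of freedom, and convergence diagnostics.
#' @export
fit_panel_gvar <- function(panel, W, adjacency = NULL, control = list()) {
  items <- panel_item_cols(panel)
  m <- length(items)
  X <- panel_to_wide(panel, W, items)
  if (nrow(X) == 0L) stop_panelnet("empty panel")
  pstats <- pattern_stats(X)
  spec <- make_pspec(m, items, adjacency)
  start <- start_values(X, m, W, spec)
  fit_core(list(pstats), W, spec, start, control)
}

#' Two-group panel GVAR with equality constraints
#'
#' Joint FIML fit over two panels with parameter blocks shared between
#' groups. Blocks are \code{"mu"}, \code{"beta"}, \code{"zeta"}
#' (contemporaneous partial correlations and scalings), and
#' \code{"between"}; \code{equal_sets = "all"} (the default) shares all
#' \code{2 m^2 + 2 m} parameters. The joint degrees of freedom are
#' \code{2 * moments - n_free}.
#'
#' @param panel_a,panel_b Two panels with the same items.
#' @param W Wave count.
#' @param equal_sets \code{"all"} or a character subset of
#'   \code{c("mu", "beta", "zeta", "between")}.
#' @param adjacency Optional masks applied to both groups.
#' @param control Optimisation settings.
#' @return A \code{panel_gvar_fit}; \code{group_params} holds the two
#'   groups' (possibly shared) parameter sets.
#' @export
fit_multigroup_equal <- function(panel_a, panel_b, W, equal_sets = "all",
                                 adjacency = NULL, control = list()) {
  items <- panel_item_cols(panel_a)
  if (!identical(items, panel_item_cols(panel_b))) {
    stop_panelnet("panels have different item sets")
  }
  m <- length(items)
  spec <- make_pspec(m, items, adjacency)
  form <- if (spec$zeta_chol && spec$between_chol) "chol" else "report"
  blocks <- c("mu", "beta", "zeta", "between")
  shared <- if (identical(equal_sets, "all")) blocks else {
    map <- c(mu = "mu", beta = "beta", zeta = "zeta", between = "between",
             omega_zeta = "zeta", delta_zeta = "zeta",
             omega_between = "between", delta_between = "between")
    unique(unname(map[intersect(names(map), equal_sets)]))
  }
  len <- block_lengths(spec, form)
  len_rep <- block_lengths(spec, "report")

  # joint theta layout: shared copies once, unshared per group
  idxA <- integer(0); idxB <- integer(0); pos <- 0L
  for (b in blocks) {
    if (b %in% shared) {
      ix <- pos + seq_len(len[b]); pos <- pos + len[b]
      idxA <- c(idxA, ix); idxB <- c(idxB, ix)
    } else {
      ixa <- pos + seq_len(len[b]); pos <- pos + len[b]
      ixb <- pos + seq_len(len[b]); pos <- pos + len[b]
      idxA <- c(idxA, ixa); idxB <- c(idxB, ixb)
    }
  }
  n_free <- sum(len_rep[shared]) + 2 * sum(len_rep[setdiff(blocks, shared)])

  XA <- panel_to_wide(panel_a, W, items)
  XB <- panel_to_wide(panel_b, W, items)
  psA <- pattern_stats(XA)
  psB <- pattern_stats(XB)
  start <- start_values(rbind(XA, XB), m, W, spec)
  th0_single <- pack_theta(start, spec, form)
  theta0 <- numeric(pos)
  theta0[idxA] <- th0_single
  theta0[idxB] <- th0_single

  fit_core(list(psA, psB), W, spec, start, control,
           group_idx = list(idxA, idxB), theta0 = theta0,
           n_free = as.integer(n_free))
}

#' @export
print.panel_gvar_fit <- function(x, ...) {
  cat("Lag-1 panel GVAR fit (FIML)\n")
  cat("  items:", length(x$items), " waves:", x$W,
      " subjects:", x$n_subjects, " groups:", x$n_groups, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10),
      " free parameters:", x$n_free, " df:", x$df, "\n")
  cat("  converged:", x$converged,
      " stationary:", x$stationary,
      " max|grad|:", signif(x$grad_norm, 3), "\n")
  invisible(x)
}

#' Wald inference for every free parameter of a fitted panel GVAR
#'
#' Standard errors come from the inverse of the observed information,
#' obtained by central-difference numerical differentiation of the
#' log-likelihood at the optimum in reporting coordinates (partial
#' correlations and log scalings). Wald z tests and 95% confidence
#' intervals are attached per parameter matrix; the significance masks
#' use the supplied alpha.
#'
#' @param model A \code{panel_gvar_fit}.
#' @param alpha Significance level for the edge masks (the study
#'   convention is 1e-4).
#' @param level Confidence level for the intervals.
#' @return The model augmented with \code{se}, \code{pvalues},
#'   \code{ci_lower}, \code{ci_upper}, \code{significant}, and
#'   \code{alpha} (each a list of per-matrix entries, per group).
#' @export
edge_inference <- function(model, alpha = 1e-4, level = 0.95) {
  spec <- model$.spec
  m <- spec$m
  # reporting-coordinate likelihood: re-pack the optimum in report form
  group_thetas <- lapply(model$group_params,
                         function(p) pack_theta(p, spec, "report"))
  if (is.null(model$.group_idx)) {
    theta <- group_thetas[[1]]
    gidx <- NULL
  } else {
    # rebuild the joint vector in report coordinates
    nj <- max(vapply(model$.group_idx, max, numeric(1)))
    # block lengths equal in report form, so index maps carry over
    len_form <- block_lengths(spec, model$.form)
    len_rep <- block_lengths(spec, "report")
    if (!all(len_form == len_rep)) {
      # rebuild index maps on report lengths
      stop_panelnet("internal: mixed-form multigroup inference unsupported")
    }
    theta <- numeric(nj)
    for (g in seq_along(group_thetas)) theta[model$.group_idx[[g]]] <- group_thetas[[g]]
    gidx <- model$.group_idx
  }
  nll <- make_negloglik(model$.pstats, model$W, spec, "report", gidx)
  H <- num_hessian(nll, theta)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    warning("observed information is singular or indefinite; ",
            "standard errors reported as NA")
    se_theta <- rep(NA_real_, length(theta))
  } else {
    se_theta <- sqrt(diag(vc))
  }

  zq <- stats::qnorm(1 - (1 - level) / 2)
  unpack_se <- function(th, se) {
    # both th and se are in report coordinates for one group
    len <- block_lengths(spec, "report")
    i <- 0L
    take <- function(k) { out <- list(est = th[i + seq_len(k)], se = se[i + seq_len(k)]); i <<- i + k; out }
    mu <- take(len["mu"])
    beta <- take(len["beta"])
    zeta <- take(len["zeta"])
    betw <- take(len["between"])
    shape <- function(vals, where) {
      M <- matrix(NA_real_, m, m, dimnames = list(spec$items, spec$items))
      M[where] <- vals
      M
    }
    n_oz <- sum(spec$oz_free)
    n_ob <- sum(spec$ob_free)
    sym <- function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
    res <- list()
    for (fld in c("est", "se")) {
      res[[fld]] <- list(
        mu = stats::setNames(mu[[fld]], spec$items),
        beta = shape(beta[[fld]], spec$beta_free),
        omega_zeta = sym(shape(zeta[[fld]][seq_len(n_oz)], spec$oz_free)),
        delta_zeta = stats::setNames(zeta[[fld]][n_oz + seq_len(m)], spec$items),
        omega_between = sym(shape(betw[[fld]][seq_len(n_ob)], spec$ob_free)),
        delta_between = stats::setNames(betw[[fld]][n_ob + seq_len(m)], spec$items))
    }
    res
  }

  per_group <- lapply(seq_along(model$group_params), function(g) {
    th_g <- group_thetas[[g]]
    se_g <- if (is.null(gidx)) se_theta else se_theta[gidx[[g]]]
    u <- unpack_se(th_g, se_g)
    lapply(stats::setNames(names(u$est), names(u$est)), function(nm) {
      est <- u$est[[nm]]; se <- u$se[[nm]]
      if (startsWith(nm, "delta")) {
        # estimated on the log scale; delta-method back-transform
        d <- exp(est)
        se_d <- d * se
        z <- est / se  # test of log-delta = 0 is not meaningful; keep NA
        list(estimate = d, se = se_d, p = rep(NA_real_, length(d)),
             lower = exp(est - zq * se), upper = exp(est + zq * se))
      } else {
        z <- est / se
        list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(z)),
             lower = est - zq * se, upper = est + zq * se)
      }
    })
  })

  g1 <- per_group[[1]]
  model$se <- lapply(g1, `[[`, "se")
  model$pvalues <- lapply(g1, `[[`, "p")
  model$ci_lower <- lapply(g1, `[[`, "lower")
  model$ci_upper <- lapply(g1, `[[`, "upper")
  model$significant <- lapply(g1, function(x) {
    p <- x$p
    if (is.null(dim(p))) !is.na(p) & p < alpha else {
      s <- !is.na(p) & p < alpha
      dim(s) <- dim(p); dimnames(s) <- dimnames(p); s
    }
  })
  model$alpha <- alpha
  model$inference_by_group <- per_group
  model
}

num_hessian <- function(f, x, h_rel = 1e-4) {
  p <- length(x)
  h <- h_rel * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) {
      for (j in seq((i + 1), p)) {
        ej <- numeric(p); ej[j] <- h[j]
        H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                      f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
        H[j, i] <- H[i, j]
      }
    }
  }
  H
}
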