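#' Spearman correlation matrix with pairwise-complete cases
#'
#' Columns are rank-transformed (average ranks for ties) and correlated
#' pairwise over complete cases. Pairwise deletion can break positive
#' definiteness; downstream fitting repairs the matrix by
#' nearest-correlation projection (see [ggm_modselect()]).
#'
#' @param data Numeric data frame or matrix (items in columns).
#' @return Symmetric correlation matrix.
#' @export
spearman_corr <- function(data) {
  X <- as.matrix(data)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop_panelnet("item ", colnames(X)[j] %||% j,
                    " is constant; Spearman correlation undefined")
    }
  }
  n_pairs <- crossprod(!is.na(X))
  if (any(n_pairs[upper.tri(n_pairs)] < 3)) {
    stop_panelnet("fewer than 3 complete cases for some item pair")
  }
  stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
}

# ---- graphical lasso (block coordinate descent) -------------------------

# One lasso sub-problem: minimise 1/2 b' V b - s' b + rho |b|_1 by
# coordinate descent with soft thresholding.
lasso_cd <- function(V, s, rho, b0 = NULL, tol = 1e-8, max_iter = 500L) {
  p <- length(s)
  b <- b0 %||% numeric(p)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      r <- s[j] - sum(V[j, ] * b) + V[j, j] * b[j]
      bj <- sign(r) * max(abs(r) - rho, 0) / V[j, j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

# Friedman-style graphical lasso: returns the penalised covariance W,
# precision Theta and the exact-zero structure at penalty rho.
glasso_fit <- function(S, rho, W_init = NULL, B_init = NULL,
                       tol = 1e-6, max_iter = 200L) {
  p <- nrow(S)
  W <- W_init %||% (S + rho * diag(p))
  B <- B_init %||% matrix(0, p, p)   # column j: lasso coefficients for j
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      b <- lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], rho, b0 = B[idx, j])
      B[idx, j] <- b
      w12 <- W[idx, idx, drop = FALSE] %*% b
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol * mean(abs(diag(S)))) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- t22
    Theta[idx, j] <- -B[idx, j] * t22
  }
  Theta <- (Theta + t(Theta)) / 2
  structure_mat <- (B != 0) | t(B != 0)
  diag(structure_mat) <- FALSE
  list(W = W, Theta = Theta, structure = structure_mat * 1L)
}

#' Candidate edge structures along a graphical-lasso path
#'
#' Runs L1-penalised precision estimation on a log-spaced grid of
#' \code{n_lambda} penalties from the largest absolute off-diagonal of
#' \code{S} down to \code{lambda_min_ratio} times it (warm starts down
#' the path) and collects the distinct nonzero structures encountered.
#'
#' @param S Correlation (or covariance) matrix.
#' @param n Sample size (recorded for downstream scoring).
#' @param n_lambda Grid size; default 100.
#' @param lambda_min_ratio Smallest penalty as a fraction of the
#'   largest; default 0.01.
#' @return List with \code{structures} (distinct 0/1 matrices, ordered
#'   from sparse to dense) and \code{lambda} (the grid).
#' @export
glasso_path <- function(S, n, n_lambda = 100L, lambda_min_ratio = 0.01) {
  p <- nrow(S)
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max <= 0) {
    return(list(structures = list(matrix(0L, p, p)), lambda = numeric(0)))
  }
  lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                    length.out = n_lambda))
  structures <- list()
  keys <- character(0)
  W <- NULL; B <- NULL
  for (rho in lambda) {
    fit <- tryCatch(glasso_fit(S, rho, W_init = W, B_init = B),
                    warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit)) {
      warning("penalised fit failed at lambda = ", signif(rho, 4), "; skipped")
      next
    }
    W <- fit$W; B <- NULL  # warm-start covariance only; B reset per rho
    key <- paste(fit$structure[upper.tri(fit$structure)], collapse = "")
    if (!key %in% keys) {
      keys <- c(keys, key)
      structures[[length(structures) + 1L]] <- fit$structure
    }
  }
  # always include the empty structure
  empty_key <- paste(rep(0L, p * (p - 1) / 2), collapse = "")
  if (!empty_key %in% keys) structures <- c(list(matrix(0L, p, p)), structures)
  list(structures = structures, lambda = lambda)
}

#' Unregularised GGM refit under a fixed edge structure
#'
#' Maximum-likelihood Gaussian concentration-model fit with precision
#' entries outside \code{structure} constrained to zero, by iterative
#' regression-based conditional fitting on the covariance scale.
#'
#' @param S Correlation/covariance matrix (positive-definite).
#' @param n Sample size.
#' @param structure Symmetric 0/1 edge mask.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A \code{ggm_result} list: \code{partial_corr},
#'   \code{structure}, \code{precision}, \code{loglik}, \code{n},
#'   \code{n_edges}.
#' @export
refit_unregularized <- function(S, n, structure, tol = 1e-8, max_iter = 500L) {
  p <- nrow(S)
  structure <- (structure != 0) * 1L
  diag(structure) <- 0L
  if (!isSymmetric(structure)) stop_panelnet("structure must be symmetric")
  W <- S
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      nb <- idx[structure[idx, j] == 1L]
      w12 <- numeric(p - 1)
      if (length(nb) > 0) {
        b <- solve(W[nb, nb, drop = FALSE], S[nb, j])
        w12 <- drop(W[idx, nb, drop = FALSE] %*% b)
      }
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol * mean(abs(diag(S)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_panelnet("constrained GGM refit did not converge for structure with ",
                  sum(structure) / 2, " edges")
  }
  Theta <- solve(W)
  Theta[structure == 0L & row(Theta) != col(Theta)] <- 0   # numerical zeros
  Theta <- (Theta + t(Theta)) / 2
  d <- 1 / sqrt(diag(Theta))
  pc <- -Theta * tcrossprod(d)
  diag(pc) <- 0
  loglik <- -0.5 * n * (p * log(2 * pi) - determinant(Theta)$modulus[1] +
                          sum(Theta * S))
  structure(list(partial_corr = pc, structure = structure, precision = Theta,
                 loglik = as.numeric(loglik), n = n,
                 n_edges = sum(structure) / 2L),
            class = "ggm_result")
}

#' Extended Bayesian Information Criterion for a GGM
#'
#' \code{-2 loglik + k log(n) + 4 gamma k log(m)} with k the edge count;
#' gamma = 0 reduces to an ordinary BIC penalty on edges.
#'
#' @param loglik Fitted Gaussian log-likelihood.
#' @param n_edges Number of edges.
#' @param n Sample size.
#' @param m Number of items.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return Scalar score (smaller is better).
#' @export
ebic <- function(loglik, n_edges, n, m, gamma = 0) {
  stopifnot(n > 0, gamma >= 0)
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(m)
}

#' Stepwise unregularised GGM selection by EBIC
#'
#' Reproduces the stepwise model-selection procedure: compute the
#' Spearman correlation matrix, generate candidate structures along a
#' 100-model graphical-lasso path, refit each without regularisation,
#' seed a hill-climb from the best-EBIC candidate, then add and remove
#' single edges (best strict improvement per sweep) until EBIC no longer
#' improves. Deterministic given the data.
#'
#' @param data Per-wave item table (rows: subjects observed at that
#'   wave).
#' @param gamma EBIC hyperparameter; default 0.
#' @param n_lambda,lambda_min_ratio Passed to [glasso_path()].
#' @return The selected \code{ggm_result}, with \code{ebic} and
#'   \code{gamma} recorded.
#' @export
ggm_modselect <- function(data, gamma = 0, n_lambda = 100L,
                          lambda_min_ratio = 0.01) {
  X <- as.matrix(data)
  n <- nrow(X)
  m <- ncol(X)
  S <- spearman_corr(X)
  # pairwise-complete matrices need not be PD; project if broken
  if (!is_pd(S)) {
    S <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
    message("correlation matrix repaired by nearest-correlation projection")
  }
  path <- glasso_path(S, n, n_lambda, lambda_min_ratio)
  score_of <- function(structure) {
    fit <- refit_unregularized(S, n, structure)
    fit$ebic <- ebic(fit$loglik, fit$n_edges, n, m, gamma)
    fit
  }
  fits <- lapply(path$structures, function(st) {
    tryCatch(score_of(st), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop_panelnet("no candidate structure could be refitted")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ebic"))]]

  up <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  repeat {
    improved <- FALSE
    best_step <- best
    for (k in seq_len(nrow(up))) {
      st <- best$structure
      i <- up[k, 1]; j <- up[k, 2]
      st[i, j] <- st[j, i] <- 1L - st[i, j]
      cand <- tryCatch(score_of(st), error = function(e) NULL)
      if (!is.null(cand) && cand$ebic < best_step$ebic - 1e-10) {
        best_step <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
    best <- best_step
  }
  best$gamma <- gamma
  best
}

#' Screen item pairs for topological overlap (node redundancy)
#'
#' For every item pair correlated at least \code{corr_min} (zero-order
#' Spearman), each third item supplies a test of whether the two items'
#' correlations with it differ, using the dependent-correlation z test
#' with the back-transformed-average (Fisher-z) method. A pair is
#' flagged as redundant when fewer than \code{prop_threshold} of those
#' third-item tests are significant at \code{alpha} — the two items then
#' have statistically indistinguishable correlation profiles.
#'
#' @param data Item table.
#' @param corr_min Minimum zero-order correlation for a pair to be
#'   screened; default 0.5.
#' @param alpha Per-test significance level; default 0.01.
#' @param prop_threshold Flag a pair when the proportion of significant
#'   profile differences is below this; default 0.25.
#' @return Data frame (class \code{redundancy_report}) with one row per
#'   screened pair: items, zero-order correlation, proportion of
#'   significantly different third-item correlations, and the flag.
#' @export
goldbricker <- function(data, corr_min = 0.5, alpha = 0.01,
                        prop_threshold = 0.25) {
  X <- as.matrix(data)
  m <- ncol(X)
  if (m < 4L) stop_panelnet("redundancy screening needs at least 4 items")
  R <- spearman_corr(X)
  nm <- colnames(X) %||% paste0("item", seq_len(m))
  rows <- list()
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      if (abs(R[a, b]) < corr_min) next
      third <- setdiff(seq_len(m), c(a, b))
      ps <- vapply(third, function(k) {
        cc <- stats::complete.cases(X[, c(a, b, k)])
        n_abk <- sum(cc)
        if (n_abk < 10L) return(NA_real_)
        hittner_test(R[a, k], R[b, k], R[a, b], n_abk)
      }, numeric(1))
      if (all(is.na(ps))) {
        warning("insufficient cases to screen pair ", nm[a], "/", nm[b])
        next
      }
      prop_sig <- mean(ps < alpha, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        item_a = nm[a], item_b = nm[b], correlation = R[a, b],
        prop_significant = prop_sig,
        redundant = prop_sig < prop_threshold)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(item_a = character(0), item_b = character(0),
               correlation = numeric(0), prop_significant = numeric(0),
               redundant = logical(0))
  }
  structure(out, class = c("redundancy_report", "data.frame"),
            corr_min = corr_min, alpha = alpha,
            prop_threshold = prop_threshold)
}

# Two-sided p for H0: rho(a,k) = rho(b,k), overlapping dependent
# correlations, back-transformed-average Fisher-z method.
hittner_test <- function(r_ak, r_bk, r_ab, n) {
  z_ak <- atanh(r_ak)
  z_bk <- atanh(r_bk)
  rm_ <- tanh((z_ak + z_bk) / 2)
  cov_term <- (r_ab * (1 - 2 * rm_^2) - 0.5 * rm_^2 *
                 (1 - 2 * rm_^2 - r_ab^2)) / (1 - rm_^2)^2
  z <- (z_ak - z_bk) * sqrt((n - 3) / (2 - 2 * cov_term))
  2 * stats::pnorm(-abs(z))
}
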