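#' Parameter set of a lag-1 panel graphical VAR
#'
#' Collects the parameters of the panel GVAR: item means \code{mu}
#' (constant across waves), the temporal matrix \code{beta} (entry
#' \code{[j, i]} is the lag-1 effect of item i on item j), and two
#' Gaussian graphical models — the contemporaneous network
#' (\code{omega_zeta}, \code{delta_zeta}) describing innovation partial
#' correlations within a wave, and the between-person network
#' (\code{omega_between}, \code{delta_between}) describing partial
#' correlations among subjects' stable means. The saturated model has
#' \code{2 m^2 + 2 m} free parameters.
#'
#' @param mu Length-m mean vector.
#' @param beta m-by-m temporal matrix; spectral radius below 1 for
#'   stationarity.
#' @param omega_zeta,omega_between Symmetric partial-correlation
#'   matrices with zero diagonal; \code{I - omega} positive-definite.
#' @param delta_zeta,delta_between Positive scaling vectors.
#' @param items Optional item names.
#' @return An object of class \code{panel_gvar_params}.
#' @export
panel_gvar_params <- function(mu, beta, omega_zeta, delta_zeta,
                              omega_between, delta_between, items = NULL) {
  p <- structure(list(mu = as.numeric(mu), beta = beta,
                      omega_zeta = omega_zeta, delta_zeta = as.numeric(delta_zeta),
                      omega_between = omega_between,
                      delta_between = as.numeric(delta_between),
                      items = items %||% default_item_names(length(mu))),
                 class = "panel_gvar_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  m <- length(p$mu)
  stopifnot(is_square(p$beta), nrow(p$beta) == m,
            is_square(p$omega_zeta), nrow(p$omega_zeta) == m,
            is_square(p$omega_between), nrow(p$omega_between) == m,
            length(p$delta_zeta) == m, length(p$delta_between) == m)
  if (any(p$delta_zeta <= 0) || any(p$delta_between <= 0)) {
    stop_panelnet("delta scalings must be positive")
  }
  invisible(p)
}

#' Stationary within-person covariance of a VAR(1)
#'
#' Solves the discrete Lyapunov equation
#' \eqn{S = B S B' + \Sigma_\zeta} for the wave-invariant within-person
#' covariance implied by the temporal structure, by vectorising to the
#' linear system \eqn{(I - B \otimes B) vec(S) = vec(\Sigma_\zeta)}.
#'
#' @param beta Temporal matrix with spectral radius below 1.
#' @param sigma_zeta Positive-definite innovation covariance.
#' @return The stationary covariance matrix S.
#' @export
stationary_within_cov <- function(beta, sigma_zeta) {
  if (spectral_radius(beta) >= 1) {
    stop_panelnet("temporal matrix is non-stationary (spectral radius >= 1)")
  }
  m <- nrow(beta)
  vecS <- solve(diag(m * m) - kronecker(beta, beta), as.numeric(sigma_zeta))
  S <- matrix(vecS, m, m)
  (S + t(S)) / 2
}

#' Model-implied mean and covariance over all wave-item variables
#'
#' The implied mean tiles \code{mu} across the W waves. The implied
#' covariance between waves t >= s is
#' \eqn{\Sigma_B + B^{t-s} S_w}, where \eqn{S_w} is the stationary
#' within-person covariance and \eqn{\Sigma_B} the between-person GGM
#' covariance — a random-intercept cross-lagged panel structure in which
#' the first wave already carries the covariance implied by the temporal
#' dynamics.
#'
#' @param params A [panel_gvar_params()] set.
#' @param W Number of waves (>= 2).
#' @return List with \code{mean} (length W*m) and \code{covariance}
#'   (W*m by W*m, symmetric positive-definite).
#' @export
implied_moments <- function(params, W) {
  validate_params(params)
  if (W < 2) stop_panelnet("W must be >= 2")
  m <- length(params$mu)
  sigma_zeta <- ggm_covariance(params$omega_zeta, params$delta_zeta)
  sigma_b <- ggm_covariance(params$omega_between, params$delta_between)
  S_w <- stationary_within_cov(params$beta, sigma_zeta)

  pow <- vector("list", W)        # beta^0 .. beta^(W-1)
  pow[[1]] <- diag(m)
  for (k in seq_len(W - 1)) pow[[k + 1]] <- pow[[k]] %*% params$beta

  K <- W * m
  Sigma <- matrix(0, K, K)
  for (t in seq_len(W)) {
    for (s in seq_len(t)) {
      blk <- sigma_b + pow[[t - s + 1]] %*% S_w
      rows <- ((t - 1) * m + 1):(t * m)
      cols <- ((s - 1) * m + 1):(s * m)
      Sigma[rows, cols] <- blk
      if (t != s) Sigma[cols, rows] <- t(blk)
    }
  }
  nm <- paste0(rep(params$items, W), "_w", rep(seq_len(W), each = m))
  dimnames(Sigma) <- list(nm, nm)
  list(mean = stats::setNames(rep(params$mu, W), nm),
       covariance = (Sigma + t(Sigma)) / 2)
}

#' Free-parameter and degrees-of-freedom accounting
#'
#' The saturated lag-1 panel GVAR with m items has \code{2*m^2 + 2*m}
#' free parameters: m means (constant across waves), m^2 temporal
#' effects, and for each of the two GGM blocks m*(m-1)/2 partial
#' correlations plus m scalings. The observed first and second moments
#' over K = W*m variables number K*(K+3)/2; degrees of freedom are
#' moments minus free parameters. Adjacency masks (0/1 matrices for
#' \code{beta}, \code{omega_zeta}, \code{omega_between}) fix masked
#' entries to zero and reduce the free count accordingly.
#'
#' @param m Item count.
#' @param W Wave count (>= 2).
#' @param adjacency Optional list of masks (\code{beta},
#'   \code{omega_zeta}, \code{omega_between}).
#' @return List with \code{n_free}, \code{moments}, and \code{df}.
#' @examples
#' count_free_parameters(16, 6)  # 544 parameters, df 4208
#' @export
count_free_parameters <- function(m, W, adjacency = NULL) {
  stopifnot(m >= 1, W >= 2)
  moments <- (W * m) * (W * m + 3) / 2
  if (is.null(adjacency)) {
    n_free <- 2 * m^2 + 2 * m
  } else {
    adjacency <- complete_adjacency(adjacency, m)
    n_free <- m +                                  # means
      sum(adjacency$beta != 0) +                   # temporal effects
      sum(adjacency$omega_zeta[upper.tri(adjacency$omega_zeta)] != 0) + m +
      sum(adjacency$omega_between[upper.tri(adjacency$omega_between)] != 0) + m
  }
  list(n_free = as.integer(n_free), moments = as.integer(moments),
       df = as.integer(moments - n_free))
}

complete_adjacency <- function(adjacency, m) {
  out <- list(beta = adjacency$beta %||% matrix(1, m, m),
              omega_zeta = adjacency$omega_zeta %||% matrix(1, m, m),
              omega_between = adjacency$omega_between %||% matrix(1, m, m))
  for (nm in c("omega_zeta", "omega_between")) diag(out[[nm]]) <- 0
  lapply(out, function(x) (x != 0) * 1)
}

# ---- data layout and missingness-pattern sufficient statistics ----------

# Wide n x (W*m) matrix, wave-major column order, NA for missing cells.
panel_to_wide <- function(panel, W, items = panel_item_cols(panel)) {
  m <- length(items)
  ids <- unique(as.character(panel$subject_id))
  X <- matrix(NA_real_, length(ids), W * m,
              dimnames = list(ids, paste0(rep(items, W),
                                          "_w", rep(seq_len(W), each = m))))
  wv <- as.integer(panel$wave)
  keep <- wv >= 1L & wv <= W
  ridx <- match(as.character(panel$subject_id), ids)[keep]
  wvk <- wv[keep]
  for (j in seq_along(items)) {
    X[cbind(ridx, (wvk - 1L) * m + j)] <- panel[[items[j]]][keep]
  }
  X
}

# Group rows of X by missingness pattern; per pattern keep the observed
# column index, case count, mean vector and ML scatter about the pattern
# mean. Rows with nothing observed are dropped with a warning.
pattern_stats <- function(X) {
  obs <- !is.na(X)
  none <- rowSums(obs) == 0L
  if (any(none)) {
    warning(sum(none), " subject(s) with no observed values excluded from FIML")
    X <- X[!none, , drop = FALSE]
    obs <- obs[!none, , drop = FALSE]
  }
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  out <- lapply(split(seq_len(nrow(X)), key), function(rows) {
    o <- which(obs[rows[1L], ])
    Y <- X[rows, o, drop = FALSE]
    n <- nrow(Y)
    xbar <- colMeans(Y)
    Yc <- sweep(Y, 2L, xbar)
    list(obs = o, n = n, mean = xbar, scatter = crossprod(Yc))
  })
  attr(out, "n_total") <- nrow(X)
  out
}

# Log-likelihood of (mu, Sigma) over pattern sufficient statistics.
loglik_patterns <- function(mu, Sigma, pstats) {
  ll <- 0
  for (p in pstats) {
    k <- length(p$obs)
    Sp <- Sigma[p$obs, p$obs, drop = FALSE]
    ch <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    d <- p$mean - mu[p$obs]
    A <- p$scatter + p$n * tcrossprod(d)
    tr <- sum(chol2inv(ch) * A)   # tr(Sp^{-1} A), both symmetric
    ll <- ll - 0.5 * (p$n * k * log(2 * pi) + p$n * logdet + tr)
  }
  ll
}

#' Full-information maximum-likelihood log-likelihood of a panel GVAR
#'
#' Each subject contributes the multivariate-normal log-density of
#' exactly their observed wave-item values under the corresponding
#' subset of the model-implied moments. Subjects are grouped by
#' missingness pattern for efficiency; the result is identical to
#' per-subject evaluation.
#'
#' @param params A [panel_gvar_params()] set.
#' @param panel A (typically detrended) symptom panel.
#' @param W Wave count.
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, panel, W) {
  mom <- implied_moments(params, W)
  X <- panel_to_wide(panel, W, items = params$items)
  loglik_patterns(mom$mean, mom$covariance, pattern_stats(X))
}

#' Saturated-model log-likelihood under missing data
#'
#' Maximum-likelihood estimate of an unstructured mean vector and
#' covariance matrix over all wave-item variables, by EM for the
#' multivariate normal when data are incomplete (closed-form sample
#' moments, n denominator, when complete). Iterated until the relative
#' log-likelihood change falls below \code{tol}.
#'
#' @param panel A symptom panel.
#' @param W Wave count.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List with \code{loglik}, \code{mean}, \code{covariance},
#'   \code{iterations}, \code{converged}, and \code{n} (subjects used).
#' @export
saturated_loglik <- function(panel, W, tol = 1e-9, max_iter = 1000L) {
  X <- panel_to_wide(panel, W)
  pstats <- pattern_stats(X)
  n <- attr(pstats, "n_total")
  K <- ncol(X)
  if (n <= K) {
    stop_panelnet("saturated model is not estimable: ", n,
                  " subjects for ", K, " wave-item variables")
  }

  complete <- length(pstats) == 1L && length(pstats[[1L]]$obs) == K
  if (complete) {
    mu <- pstats[[1L]]$mean
    Sigma <- pstats[[1L]]$scatter / n
    return(list(loglik = loglik_patterns(mu, Sigma, pstats), mean = mu,
                covariance = Sigma, iterations = 0L, converged = TRUE, n = n))
  }

  # init from available-case moments
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, K)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: expected sufficient statistics per missingness pattern
    sum_x <- numeric(K)
    sum_xx <- matrix(0, K, K)
    for (p in pstats) {
      o <- p$obs
      mis <- setdiff(seq_len(K), o)
      ch_o <- tryCatch(chol(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
      if (is.null(ch_o)) {
        stop_panelnet("saturated-model EM hit a singular covariance ",
                      "(too few cases for the observed variables)")
      }
      Soo_inv <- chol2inv(ch_o)
      xbar <- p$mean
      d <- xbar - mu[o]
      # first moments
      Ex <- numeric(K)
      Ex[o] <- xbar
      C <- NULL
      if (length(mis) > 0) {
        B <- Sigma[mis, o, drop = FALSE] %*% Soo_inv      # regression coefs
        Ex[mis] <- mu[mis] + drop(B %*% d)
        C <- Sigma[mis, mis, drop = FALSE] -
          B %*% Sigma[o, mis, drop = FALSE]
      }
      sum_x <- sum_x + p$n * Ex
      # second moments: E[(x - Ex_pattern)(x - Ex_pattern)'] pieces
      Voo <- p$scatter
      EE <- matrix(0, K, K)
      EE[o, o] <- Voo
      if (length(mis) > 0) {
        B <- Sigma[mis, o, drop = FALSE] %*% Soo_inv
        EE[mis, o] <- B %*% Voo
        EE[o, mis] <- t(EE[mis, o, drop = FALSE])
        EE[mis, mis] <- B %*% Voo %*% t(B) + p$n * C
      }
      sum_xx <- sum_xx + EE + p$n * tcrossprod(Ex)
    }
    mu <- sum_x / n
    Sigma <- sum_xx / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_patterns(mu, Sigma, pstats)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop_panelnet("saturated-model EM did not converge in ", max_iter,
                  " iterations (last loglik ", signif(ll_old, 10), ")")
  }
  list(loglik = ll_old, mean = mu, covariance = Sigma, iterations = it,
       converged = TRUE, n = n)
}

#' Independence-baseline log-likelihood
#'
#' The baseline model frees a mean and variance per wave-item variable
#' and fixes all covariances at zero; under independence the FIML
#' likelihood factorises, so the ML solution is each variable's
#' observed-case mean and (n denominator) variance. Its degrees of
#' freedom are \code{moments - 2*W*m}.
#'
#' @param panel A symptom panel.
#' @param W Wave count.
#' @return List with \code{loglik}, \code{df}, and \code{n}.
#' @export
baseline_loglik <- function(panel, W) {
  X <- panel_to_wide(panel, W)
  K <- ncol(X)
  ll <- 0
  for (j in seq_len(K)) {
    x <- X[, j]
    x <- x[!is.na(x)]
    nj <- length(x)
    if (nj < 2L) stop_panelnet("variable ", colnames(X)[j],
                               " has fewer than 2 observations")
    vj <- mean((x - mean(x))^2)
    if (vj <= 0) stop_panelnet("zero variance in variable ", colnames(X)[j])
    ll <- ll - 0.5 * nj * (log(2 * pi) + log(vj) + 1)
  }
  moments <- K * (K + 3) / 2
  list(loglik = ll, df = as.integer(moments - 2L * K), n = nrow(X))
}
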