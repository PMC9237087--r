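#' Covariance matrix implied by a Gaussian graphical model
#'
#' A GGM is parameterised by a symmetric partial-correlation matrix
#' \code{omega} (zero diagonal, off-diagonals in (-1, 1)) and a vector of
#' positive scaling constants \code{delta}. The implied covariance is
#' \deqn{\Sigma = \Delta (I - \Omega)^{-1} \Delta,}
#' whose standardised negative inverse off-diagonals reproduce
#' \code{omega}, so zeros in \code{omega} encode conditional independence.
#'
#' @param omega Symmetric m-by-m partial-correlation matrix with zero
#'   diagonal; \code{I - omega} must be positive-definite.
#' @param delta Length-m vector of positive scalings (residual-scale
#'   standard deviations).
#' @return The m-by-m implied covariance matrix.
#' @examples
#' ggm_covariance(matrix(c(0, .5, .5, 0), 2), c(1, 1))
#' @export
ggm_covariance <- function(omega, delta) {
  stopifnot(is_square(omega), length(delta) == nrow(omega), all(delta > 0))
  if (any(abs(diag(omega)) > 1e-12)) {
    stop_panelnet("omega must have a zero diagonal")
  }
  m <- nrow(omega)
  iom <- diag(m) - omega
  ev <- eigen((iom + t(iom)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop_panelnet("(I - omega) is singular or not positive-definite")
  }
  D <- diag(delta, m)
  sigma <- D %*% solve(iom) %*% D
  (sigma + t(sigma)) / 2
}

#' Partial correlations and scalings of a covariance matrix
#'
#' Inverse of [ggm_covariance()]: standardises the negated precision
#' matrix into partial correlations and recovers the scaling vector.
#'
#' @param sigma Positive-definite covariance matrix.
#' @return List with \code{omega} (partial correlations, zero diagonal)
#'   and \code{delta} (positive scalings) such that
#'   \code{ggm_covariance(omega, delta)} reproduces \code{sigma}.
#' @export
cov_to_ggm <- function(sigma) {
  K <- solve((sigma + t(sigma)) / 2)
  d <- 1 / sqrt(diag(K))
  omega <- -K * tcrossprod(d)
  diag(omega) <- 0
  list(omega = (omega + t(omega)) / 2, delta = d)
}

# Lower-triangular Cholesky-style factor -> covariance; the unconstrained
# triangular factor is the internal optimisation parameterisation of both
# GGM blocks.
chol_to_cov <- function(L) tcrossprod(L)

cov_to_chol <- function(sigma) t(chol((sigma + t(sigma)) / 2))
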