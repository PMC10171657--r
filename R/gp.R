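# The GP prior on the link at projected indices: kernel construction and the
# collapsed marginal with the link integrated out.

#' Squared-exponential kernel on projected indices
#'
#' Builds the n x n covariance `C[i, j] = gamma * exp(-(x_i'beta -
#' x_j'beta)^2) + jitter * 1[i == j]`. Leaving the norm of `beta`
#' unconstrained absorbs the kernel bandwidth, so no separate length-scale
#' appears.
#'
#' @param X n x p design matrix.
#' @param beta Index vector of length p.
#' @param gamma Positive amplitude.
#' @param jitter Nonnegative diagonal jitter (absolute).
#' @return Symmetric n x n matrix.
#' @export
build_kernel <- function(X, beta, gamma, jitter = 0) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(beta), gamma > 0, jitter >= 0)
  kernel_cpp(X, as.numeric(beta), gamma, jitter)
}

#' Collapse the composite likelihood to per-observation pseudo-data
#'
#' Each quantile level contributes a conditionally Gaussian pseudo-datum
#' `z[i, m] = y_i - alpha_m - (1 - 2 tau_m) e[i, m]` with variance
#' `2 sigma e[i, m]` for the shared link value \eqn{\eta_i}. Combining the M
#' levels by precision summation yields one pseudo-observation per i:
#' variance `etilde_i = (sum_m (2 sigma e_im)^{-1})^{-1}`, precision-weighted
#' sum `F_i = sum_m z_im / (2 sigma e_im)`, so the pseudo-observation is
#' `etilde_i * F_i` with variance `etilde_i`.
#'
#' @param y Response vector of length n.
#' @param alpha Intercept vector of length M.
#' @param e n x M matrix of positive latent ALD scales.
#' @param sigma Positive ALD scale.
#' @param taus Quantile levels of length M.
#' @return List with components `z` (n x M), `etilde`, `F` (length n) and
#'   `q = sum(z^2 / (2 sigma e))`.
#' @export
collapse_pseudo_data <- function(y, alpha, e, sigma, taus) {
  e <- as.matrix(e)
  stopifnot(length(alpha) == length(taus), nrow(e) == length(y),
            ncol(e) == length(taus))
  if (any(e <= 0)) stop("all latent scales e must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  Y <- matrix(y, nrow = length(y), ncol = length(taus))
  out <- collapse_cpp(Y, as.numeric(alpha), e, sigma, as.numeric(taus))
  out$etilde <- as.numeric(out$etilde)
  out$F <- as.numeric(out$F)
  out
}

#' Collapsed log density with the link integrated out
#'
#' Computes `log A(beta, alpha, e, gamma, sigma)` -- the log marginal density
#' of the stacked pseudo-observations after integrating the GP-distributed
#' link values out -- up to an additive constant free of `(beta, alpha,
#' gamma)`:
#' \deqn{\log A = \tfrac12\log|E| - \tfrac12\log|C_n+E| -
#'   \tfrac12\sum_{i,m} z_{im}^2/(2\sigma e_{im}) + \tfrac12 F'\Sigma F.}
#' All determinants and quadratic forms go through one Cholesky of
#' \eqn{C_n + E}; the diagonal jitter starts at `jitter_rel * gamma` and
#' escalates tenfold up to \eqn{10^{-2}\gamma} before failing.
#'
#' @inheritParams collapse_pseudo_data
#' @param beta Index vector.
#' @param gamma Positive kernel amplitude.
#' @param X n x p design matrix.
#' @param jitter_rel Starting relative jitter.
#' @return A single numeric value.
#' @export
collapsed_logdensity <- function(beta, alpha, e, gamma, sigma, X, y, taus,
                                 jitter_rel = 1e-8) {
  X <- as.matrix(X)
  e <- as.matrix(e)
  stopifnot(ncol(X) == length(beta), nrow(X) == length(y),
            nrow(e) == length(y), ncol(e) == length(taus),
            length(alpha) == length(taus))
  if (any(e <= 0)) stop("all latent scales e must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  Y <- matrix(y, nrow = length(y), ncol = length(taus))
  logA_cpp(X, Y, as.numeric(beta), as.numeric(alpha), e, gamma, sigma,
           as.numeric(taus), jitter_rel)
}
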