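# Full-conditional samplers and log-conditional evaluators for each block of
# the partially collapsed scheme.

#' Full conditional of the link values
#'
#' Given the collapsed pseudo-data and the kernel \eqn{C_n}, the link values
#' at the data projections are Gaussian with
#' \deqn{\Sigma = C_n (C_n + E)^{-1} E, \qquad \mu = \Sigma F,}
#' computed through one Cholesky of \eqn{C_n + E} (never forming
#' \eqn{\Sigma^{-1}}).
#'
#' @param stats Output of [collapse_pseudo_data()].
#' @param K Kernel matrix from [build_kernel()] (jitter already applied).
#' @return List with components `mean` (length n) and `cov` (n x n PSD).
#' @export
eta_full_conditional <- function(stats, K) {
  stopifnot(is.list(stats), !is.null(stats$etilde), !is.null(stats$F),
            nrow(K) == length(stats$etilde))
  out <- eta_cond_cpp(as.matrix(K), as.numeric(stats$etilde),
                      as.numeric(stats$F))
  out$mean <- as.numeric(out$mean)
  out
}

#' Draw the link values
#'
#' Exact Gaussian draw from the conditional returned by
#' [eta_full_conditional()], via Cholesky with small jitter and a
#' clipped-eigenvalue fallback for rank-deficient covariances. A zero
#' covariance returns the mean exactly.
#'
#' @param cond List with `mean` and `cov`.
#' @return Numeric vector of link values.
#' @export
sample_eta <- function(cond) {
  stopifnot(is.list(cond), length(cond$mean) == nrow(cond$cov))
  as.numeric(sample_eta_cpp(as.numeric(cond$mean), as.matrix(cond$cov)))
}

#' Collapsed log targets for the Metropolis blocks
#'
#' Log targets (up to additive constants) of the three Metropolis updates,
#' each with the link integrated out: the index vector has a N(0, sigma I)
#' prior, the intercepts a flat prior (optionally Gaussian via
#' `alpha_prior_var`), and the amplitude an IG(a_gamma, b_gamma) prior. When
#' `gamma` is proposed on the log scale the Metropolis ratio must add the
#' Jacobian `+log gamma`, which is *not* included here.
#'
#' @inheritParams collapsed_logdensity
#' @param a_gamma,b_gamma IG prior parameters for the amplitude.
#' @param alpha_prior_var Variance of the optional Gaussian intercept prior;
#'   `Inf` is flat.
#' @return A single numeric value.
#' @export
log_target_beta <- function(beta, alpha, e, gamma, sigma, X, y, taus,
                            jitter_rel = 1e-8) {
  collapsed_logdensity(beta, alpha, e, gamma, sigma, X, y, taus, jitter_rel) -
    sum(beta^2) / (2 * sigma)
}

#' @rdname log_target_beta
#' @export
log_target_alpha <- function(alpha, beta, e, gamma, sigma, X, y, taus,
                             jitter_rel = 1e-8, alpha_prior_var = Inf) {
  lp <- if (is.finite(alpha_prior_var)) {
    -sum(alpha^2) / (2 * alpha_prior_var)
  } else 0
  collapsed_logdensity(beta, alpha, e, gamma, sigma, X, y, taus, jitter_rel) +
    lp
}

#' @rdname log_target_beta
#' @export
log_target_gamma <- function(gamma, beta, alpha, e, sigma, X, y, taus,
                             a_gamma = 0.5, b_gamma = 0.5,
                             jitter_rel = 1e-8) {
  if (gamma <= 0) stop("gamma must be positive")
  collapsed_logdensity(beta, alpha, e, gamma, sigma, X, y, taus, jitter_rel) -
    (a_gamma + 1) * log(gamma) - b_gamma / gamma
}

#' Draw the latent ALD scales
#'
#' Each latent scale is conditionally generalized inverse Gaussian,
#' \deqn{e_{im} \mid \cdot \sim \mathrm{GIG}\!\left(\tfrac12,\;
#'   \chi = (y_i - \alpha_m - \eta_i)^2/(2\sigma),\;
#'   \psi = 1/(2\sigma)\right)} in the
#' \eqn{x^{\rho-1}\exp\{-(\chi/x+\psi x)/2\}} convention, independent across
#' observations and levels. A zero residual falls back to the exact
#' Gamma(1/2, rate \eqn{\psi/2}) limit.
#'
#' @param y Response vector.
#' @param alpha Intercepts (length M).
#' @param eta Link values (length n).
#' @param sigma Positive ALD scale.
#' @param taus Quantile levels (length M; only its length is used here).
#' @return n x M matrix of positive draws.
#' @export
sample_e <- function(y, alpha, eta, sigma, taus) {
  stopifnot(length(alpha) == length(taus), length(eta) == length(y))
  if (sigma <= 0) stop("sigma must be positive")
  U <- outer(y - eta, alpha, "-")
  sample_e_cpp(U, sigma)
}

#' Draw the ALD scale sigma
#'
#' The full conditional is inverse gamma,
#' \deqn{\sigma \mid \cdot \sim \mathrm{IG}\!\left(\tfrac{3Mn}{2} +
#'   \tfrac{p}{2} + a_\sigma,\; \sum_{i,m}\Big[\tfrac{(z_{im}-\eta_i)^2}
#'   {4e_{im}} + \tau_m(1-\tau_m)e_{im}\Big] + \tfrac{\beta'\beta}{2} +
#'   b_\sigma\right).}
#' The shape collects Mn/2 from the conditionally Gaussian likelihood, Mn
#' from the \eqn{\sigma^{-1}} normalization of each latent-scale exponential
#' prior, and p/2 from the N(0, sigma) index prior.
#'
#' @param y Response vector.
#' @param beta Index vector.
#' @param alpha Intercepts.
#' @param e n x M latent scales.
#' @param eta Link values.
#' @param taus Quantile levels.
#' @param a_sigma,b_sigma IG hyperparameters.
#' @return One positive draw.
#' @export
sample_sigma <- function(y, beta, alpha, e, eta, taus, a_sigma = 0.5,
                         b_sigma = 0.5) {
  e <- as.matrix(e)
  n <- length(y)
  M <- length(taus)
  stopifnot(nrow(e) == n, ncol(e) == M, length(eta) == n)
  z <- outer(y, alpha, "-") - sweep(e, 2, 1 - 2 * taus, "*")
  rate <- sum((z - eta)^2 / (4 * e)) +
    sum(sweep(e, 2, taus * (1 - taus), "*")) +
    sum(beta^2) / 2 + b_sigma
  shape <- 1.5 * M * n + length(beta) / 2 + a_sigma
  rinvgamma(1, shape, rate)
}
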