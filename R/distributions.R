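# Elementary densities and samplers: check loss, asymmetric Laplace,
# generalized inverse Gaussian, inverse gamma.

#' Quantile check loss
#'
#' The piecewise-linear loss \eqn{\rho_\tau(t) = t(\tau - I(t < 0))} whose
#' minimizer is the \eqn{\tau}-quantile. Summing it over a grid of levels
#' gives the composite quantile regression objective.
#'
#' @param t Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Nonnegative numeric vector, same length as `t`.
#' @export
#' @examples
#' check_loss(c(-2, 0, 1), tau = 0.3)
check_loss <- function(t, tau) {
  stopifnot(is.numeric(t), length(tau) == 1L, is.finite(tau))
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly in (0, 1)")
  t * (tau - (t < 0))
}

#' Asymmetric Laplace density
#'
#' Density \eqn{\tau(1-\tau)/\sigma \exp\{-\rho_\tau(y - \mu)/\sigma\}} used
#' as the working likelihood for Bayesian quantile regression: its location
#' parameter is the \eqn{\tau}-quantile of the distribution.
#'
#' @param x Numeric vector of evaluation points.
#' @param mu Location (the \eqn{\tau}-quantile).
#' @param sigma Positive scale.
#' @param tau Quantile level in (0, 1).
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @export
dald <- function(x, mu = 0, sigma = 1, tau = 0.5, log = FALSE) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly in (0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  ld <- log(tau) + log1p(-tau) - log(sigma) - check_loss(x - mu, tau) / sigma
  if (log) ld else exp(ld)
}

#' Composite quantile grid
#'
#' Equally spaced quantile levels \eqn{\tau_m = m/(M+1)}, m = 1..M.
#'
#' @param M Number of quantile levels (positive integer).
#' @return Strictly increasing numeric vector of length `M` inside (0, 1).
#' @export
quantile_grid <- function(M) {
  stopifnot(length(M) == 1L, M >= 1, M == round(M))
  seq_len(M) / (M + 1)
}

#' Generalized inverse Gaussian draws
#'
#' Samples from the density proportional to
#' \eqn{x^{\rho-1}\exp\{-(\chi/x + \psi x)/2\}} on \eqn{x > 0}.
#' In the three-argument (\eqn{\rho}, m, n) convention used for the latent
#' ALD scales, \eqn{\chi = m^2} and \eqn{\psi = n^2}. The order
#' \eqn{\rho = 1/2} -- the only one the sampler needs, arising as the full
#' conditional of a latent scale -- is drawn exactly as the reciprocal of an
#' inverse Gaussian variate; other orders use ratio-of-uniforms rejection
#' with a mode shift. `chi = 0` with \eqn{\rho > 0} degenerates to a
#' Gamma(\eqn{\rho}, rate \eqn{\psi/2}) draw; `psi = 0` with \eqn{\rho < 0}
#' to an inverse gamma. Both zero is an error.
#'
#' @param nr Number of draws.
#' @param rho Real order.
#' @param chi,psi Nonnegative parameters, not both zero.
#' @return Numeric vector of positive draws.
#' @export
rgig <- function(nr, rho, chi, psi) {
  stopifnot(length(rho) == 1L, length(chi) == 1L, length(psi) == 1L)
  if (chi < 0 || psi < 0) stop("chi and psi must be nonnegative")
  if (chi == 0 && psi == 0) stop("chi and psi must not both be zero")
  if (chi == 0) {
    if (rho <= 0) stop("chi = 0 requires rho > 0")
    return(rgamma(nr, shape = rho, rate = psi / 2))
  }
  if (psi == 0) {
    if (rho >= 0) stop("psi = 0 requires rho < 0")
    return(1 / rgamma(nr, shape = -rho, rate = chi / 2))
  }
  if (rho == 0.5) return(rgig_half_cpp(nr, chi, psi))
  if (rho == -0.5) return(1 / rgig_half_cpp(nr, psi, chi))
  # two-parameter standard form: x = sqrt(chi/psi) z, omega = sqrt(chi psi)
  omega <- sqrt(chi * psi)
  scl <- sqrt(chi / psi)
  lam <- rho
  flip <- lam < 0
  if (flip) lam <- -lam
  g <- function(z) z^(lam - 1) * exp(-omega * (z + 1 / z) / 2)
  mode <- ((lam - 1) + sqrt((lam - 1)^2 + omega^2)) / omega
  sg <- function(z) sqrt(g(z))
  umax <- sg(mode)
  # bracket the support where (z - mode) sqrt(g) is non-negligible
  hi <- mode + 1
  while (sg(hi) * (hi - mode) > 1e-14 * umax) hi <- hi * 2
  vmax <- optimize(function(z) (z - mode) * sg(z), c(mode, hi),
                   maximum = TRUE)$objective
  vmin <- -optimize(function(z) (mode - z) * sg(z),
                    c(.Machine$double.xmin, mode), maximum = TRUE)$objective
  out <- numeric(nr)
  for (i in seq_len(nr)) {
    repeat {
      u <- runif(1, 0, umax)
      v <- runif(1, vmin, vmax)
      z <- v / u + mode
      if (z > 0 && u * u <= g(z)) break
    }
    out[i] <- z
  }
  z <- if (flip) 1 / out else out
  z * scl
}

#' Inverse gamma draws
#'
#' Density proportional to \eqn{x^{-a-1} e^{-b/x}}; mean \eqn{b/(a-1)} for
#' \eqn{a > 1}. Used for the ALD scale and kernel-amplitude hyperpriors.
#'
#' @param nr Number of draws.
#' @param shape,rate Positive parameters \eqn{a}, \eqn{b}.
#' @return Numeric vector of positive draws.
#' @export
rinvgamma <- function(nr, shape, rate) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  1 / rgamma(nr, shape = shape, rate = rate)
}

#' @rdname rinvgamma
#' @param x Evaluation points.
#' @param log Return the log density?
#' @export
dinvgamma <- function(x, shape, rate, log = FALSE) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  ld <- ifelse(x > 0,
               shape * base::log(rate) - lgamma(shape) -
                 (shape + 1) * base::log(x) - rate / x,
               -Inf)
  if (log) ld else exp(ld)
}
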