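# Fixed quantities of the statistical model and the sampler configuration.

#' Model specification
#'
#' Collects the fixed quantities of the composite quantile single-index
#' model: the quantile grid \eqn{\tau_m = m/(M+1)} and the inverse-gamma
#' hyperparameters of the ALD scale \eqn{\sigma} and the kernel amplitude
#' \eqn{\gamma}. All four hyperparameters default to 0.5; posterior results
#' are insensitive to them over a wide range.
#'
#' @param M Number of quantile levels.
#' @param p Covariate dimension (optional until data are seen).
#' @param a_sigma,b_sigma Shape and rate of the IG prior on \eqn{\sigma}.
#' @param a_gamma,b_gamma Shape and rate of the IG prior on \eqn{\gamma}.
#' @param alpha_prior_var Variance of an optional Gaussian prior on the
#'   quantile intercepts; `Inf` (the default) is the flat prior.
#' @return An object of class `bcqr_spec`.
#' @export
model_spec <- function(M = 9, p = NULL, a_sigma = 0.5, b_sigma = 0.5,
                       a_gamma = 0.5, b_gamma = 0.5, alpha_prior_var = Inf) {
  stopifnot(M >= 1, M == round(M),
            a_sigma > 0, b_sigma > 0, a_gamma > 0, b_gamma > 0,
            alpha_prior_var > 0)
  structure(list(M = as.integer(M), taus = quantile_grid(M), p = p,
                 a_sigma = a_sigma, b_sigma = b_sigma,
                 a_gamma = a_gamma, b_gamma = b_gamma,
                 alpha_prior_var = alpha_prior_var),
            class = "bcqr_spec")
}

#' Sampler configuration
#'
#' Settings of the partially collapsed Metropolis-within-Gibbs chain.
#' Proposal scales are adapted during burn-in by a diminishing Robbins-Monro
#' rule targeting an acceptance rate of `accept_target`, then frozen, which
#' keeps the post-burn-in acceptance rates inside `accept_band` on the
#' designs this package ships.
#'
#' @param n_iter Total iterations (default 20000).
#' @param n_burnin Burn-in iterations discarded (default 10000).
#' @param thin Thinning interval for stored draws.
#' @param prop_sd Named numeric vector of initial random-walk scales for the
#'   `beta`, `alpha` and `loggamma` blocks.
#' @param adapt Adapt proposal scales during burn-in?
#' @param accept_target Acceptance rate targeted by adaptation.
#' @param accept_band Acceptance interval the tuned chain should report.
#' @param alpha_update `"joint"` (one M-dimensional random walk, the default)
#'   or `"per-m"` (cycle through the intercepts one at a time).
#' @param jitter_rel Initial diagonal jitter for kernel factorizations,
#'   relative to the amplitude \eqn{\gamma}; escalated tenfold up to
#'   \eqn{10^{-2}\gamma} on failure.
#' @param seed Optional integer seed set before the chain starts.
#' @return An object of class `bcqr_control`.
#' @export
sampler_control <- function(n_iter = 20000, n_burnin = 10000, thin = 1,
                            prop_sd = c(beta = 0.1, alpha = 0.1,
                                        loggamma = 0.5),
                            adapt = TRUE, accept_target = 0.2,
                            accept_band = c(0.10, 0.30),
                            alpha_update = c("joint", "per-m"),
                            jitter_rel = 1e-8, seed = NULL) {
  stopifnot(n_burnin < n_iter, n_burnin >= 0, thin >= 1,
            all(prop_sd > 0), accept_target > 0, accept_target < 1,
            length(accept_band) == 2L, accept_band[1] < accept_band[2],
            accept_band[1] > 0, accept_band[2] < 1, jitter_rel >= 0)
  alpha_update <- match.arg(alpha_update)
  pd <- c(beta = 0.1, alpha = 0.1, loggamma = 0.5)
  pd[names(prop_sd)] <- prop_sd
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 prop_sd = pd, adapt = adapt, accept_target = accept_target,
                 accept_band = accept_band, alpha_update = alpha_update,
                 jitter_rel = jitter_rel, seed = seed),
            class = "bcqr_control")
}

#' Robbins-Monro proposal-scale update
#'
#' One step of the burn-in adaptation: the log scale moves by
#' \eqn{t^{-0.6}(\mathrm{accepted} - \mathrm{target})}, so persistent
#' acceptance inflates the scale and persistent rejection shrinks it, with a
#' diminishing step that freezes the scales in distribution before burn-in
#' ends.
#'
#' @param scale Current positive proposal scale.
#' @param accepted Logical: was the last proposal accepted?
#' @param t Iteration index (1-based) within burn-in.
#' @param target Targeted acceptance rate.
#' @return Updated scale.
#' @export
adapt_proposal <- function(scale, accepted, t, target = 0.2) {
  stopifnot(scale > 0, t >= 1)
  scale * exp(t^-0.6 * (as.numeric(accepted) - target))
}
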