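# The partially collapsed Metropolis-within-Gibbs driver.

#' Initial chain state
#'
#' Deterministic-in-seed initialization: `beta ~ N(0, 0.1^2 I)`, intercepts
#' at the empirical tau-quantiles of `y`, all latent scales 1, `sigma = 1`,
#' `gamma = 1`, and the link drawn once from its full conditional.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param spec A [model_spec()].
#' @return List with components `beta`, `alpha`, `e`, `sigma`, `gamma`,
#'   `eta`.
#' @export
initialize_state <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 observations")
  stopifnot(length(y) == n, all(is.finite(X)), all(is.finite(y)))
  beta <- rnorm(p, 0, 0.1)
  alpha <- as.numeric(quantile(y, probs = spec$taus, type = 7))
  e <- matrix(1, n, spec$M)
  sigma <- 1
  gamma <- 1
  K <- build_kernel(X, beta, gamma, jitter = 1e-8 * gamma)
  stats <- collapse_pseudo_data(y, alpha, e, sigma, spec$taus)
  eta <- sample_eta(eta_full_conditional(stats, K))
  list(beta = beta, alpha = alpha, e = e, sigma = sigma, gamma = gamma,
       eta = eta)
}

run_chain <- function(X, y, spec, control, gaussian = FALSE,
                      init = NULL, fix_gamma = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!is.null(control$seed)) set.seed(control$seed)
  if (is.null(init)) init <- initialize_state(X, y, spec)
  if (gaussian) {
    if (spec$M != 1L) stop("the Gaussian baseline uses a single intercept")
    init$e <- matrix(0.5, n, 1)
  }
  update_gamma <- is.null(fix_gamma)
  if (!update_gamma) init$gamma <- fix_gamma
  res <- run_mcmc_cpp(X, matrix(y, n, spec$M), spec$taus,
                      spec$a_sigma, spec$b_sigma, spec$a_gamma, spec$b_gamma,
                      spec$alpha_prior_var, gaussian,
                      control$n_iter, control$n_burnin, control$thin,
                      control$prop_sd[["beta"]], control$prop_sd[["alpha"]],
                      control$prop_sd[["loggamma"]],
                      control$adapt, control$accept_target,
                      init$beta, init$alpha, init$e, init$sigma, init$gamma,
                      control$jitter_rel,
                      control$alpha_update == "per-m", update_gamma)
  colnames(res$beta) <- colnames(X) %||% paste0("beta", seq_len(ncol(X)))
  structure(list(beta = res$beta, alpha = res$alpha, sigma = res$sigma,
                 gamma = res$gamma, eta = res$eta,
                 accept = res$accept, scales = res$scales,
                 spec = spec, control = control, gaussian = gaussian,
                 X = X, y = y, init = init,
                 method = if (gaussian) "BLR"
                          else if (spec$M == 1L) "BQR"
                          else paste0("BCQR", spec$M)),
            class = "bcqr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Bayesian composite quantile single-index model
#'
#' Runs the partially collapsed Metropolis-within-Gibbs sampler for the model
#' \eqn{y = \eta(x'\beta) + \epsilon}: per iteration the index vector, the M
#' quantile intercepts and the log kernel amplitude are updated by random-walk
#' Metropolis against targets with the link integrated out; the link values
#' are then redrawn exactly, followed by the latent ALD scales (GIG) and the
#' ALD scale (inverse gamma). This block order is part of the partially
#' collapsed scheme and is not permutable.
#'
#' `bqr()` is the single-quantile special case (M = 1, tau = 0.5) and runs
#' the identical code path; `blr()` is the Gaussian-likelihood mean
#' regression counterpart with one intercept (same GP single-index
#' hierarchy, latent scales fixed).
#'
#' @param X n x p design matrix (no missing values).
#' @param y Response vector of length n.
#' @param M Number of quantile levels (ignored when `spec` is given).
#' @param spec A [model_spec()]; built from `M` when `NULL`.
#' @param control A [sampler_control()].
#' @param init Optional initial state from [initialize_state()].
#' @param fix_gamma Optional fixed kernel amplitude (disables its update);
#'   mainly for diagnostics.
#' @return An object of class `bcqr_fit`: stored post-burn-in draws of
#'   `beta`, `alpha`, `sigma`, `gamma`, `eta`, post-burn-in Metropolis
#'   acceptance rates, final proposal scales, and the configuration.
#' @seealso [normalize_beta()], [estimate_link()], [predict.bcqr_fit()]
#' @export
#' @examples
#' d <- generate_example(sim_design(example = 2, n = 40, reps = 1,
#'                                  base_seed = 1), 1)
#' fit <- bcqr(d$X, d$y, M = 3,
#'             control = sampler_control(n_iter = 200, n_burnin = 100,
#'                                       seed = 1))
#' normalize_beta(fit)$estimate
bcqr <- function(X, y, M = 9, spec = NULL, control = sampler_control(),
                 init = NULL, fix_gamma = NULL) {
  if (is.null(spec)) spec <- model_spec(M = M, p = ncol(as.matrix(X)))
  run_chain(X, y, spec, control, gaussian = FALSE, init = init,
            fix_gamma = fix_gamma)
}

#' @rdname bcqr
#' @param ... Passed on to [bcqr()].
#' @export
bqr <- function(X, y, control = sampler_control(), ...) {
  bcqr(X, y, M = 1, control = control, ...)
}

#' @rdname bcqr
#' @export
blr <- function(X, y, control = sampler_control(), spec = NULL, init = NULL) {
  if (is.null(spec)) spec <- model_spec(M = 1, p = ncol(as.matrix(X)))
  run_chain(X, y, spec, control, gaussian = TRUE, init = init)
}

#' @export
print.bcqr_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, p = %d, M = %d, %d stored draws\n",
              x$method, nrow(x$X), ncol(x$X), x$spec$M, length(x$sigma)))
  est <- normalize_beta(x)
  cat("normalized index estimate:\n")
  print(round(est$estimate, 4))
  cat(sprintf("acceptance rates: beta %.2f, alpha %.2f, gamma %.2f\n",
              x$accept[["beta"]], x$accept[["alpha"]], x$accept[["gamma"]]))
  invisible(x)
}

#' @export
summary.bcqr_fit <- function(object, level = 0.95, ...) {
  est <- normalize_beta(object, level = level)
  out <- data.frame(estimate = est$estimate, ci_lower = est$ci_lower,
                    ci_upper = est$ci_upper, ci_length = est$ci_length)
  rownames(out) <- colnames(object$beta)
  structure(list(method = object$method, table = out,
                 accept = object$accept,
                 sigma = stats::median(object$sigma),
                 gamma = stats::median(object$gamma)),
            class = "summary.bcqr_fit")
}

#' @export
print.summary.bcqr_fit <- function(x, ...) {
  cat(sprintf("%s: normalized index estimates (unit norm, first component positive)\n",
              x$method))
  print(round(x$table, 4))
  cat(sprintf("posterior median sigma %.4g, gamma %.4g\n", x$sigma, x$gamma))
  invisible(x)
}

#' Trace plots of the index draws
#'
#' @param x A `bcqr_fit`.
#' @param pars Which components of `beta` to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bcqr_fit <- function(x, pars = seq_len(ncol(x$beta)), ...) {
  op <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(op))
  for (j in pars) {
    plot(x$beta[, j], type = "l", ylab = colnames(x$beta)[j],
         xlab = "iteration", ...)
  }
  invisible(x)
}

#' Getting-it-right simulators
#'
#' Two ways of drawing from the same joint law of (parameters, latents,
#' data): `geweke_marginal()` draws parameters from their priors and data
#' from the hierarchy (independent draws); `geweke_successive()` alternates
#' the package's posterior sweep with a data redraw (a Markov chain whose
#' stationary law is the same joint). Under a correct sampler, moments of any
#' parameter function agree between the two. Both operate on the n x M data
#' matrix the mixture representation generates (one response copy per
#' quantile level). Requires proper priors: finite `alpha_prior_var` and
#' hyperparameters with finite prior moments.
#'
#' @param n_draws Number of draws/sweeps.
#' @param X Fixed design matrix.
#' @param spec A [model_spec()] with finite `alpha_prior_var`.
#' @param prop_sd Fixed Metropolis scales (no adaptation).
#' @return Matrix with columns `sigma`, `gamma`, `beta1`.
#' @keywords internal
#' @export
geweke_marginal <- function(n_draws, X, spec) {
  stopifnot(is.finite(spec$alpha_prior_var))
  X <- as.matrix(X)
  p <- ncol(X)
  out <- matrix(NA_real_, n_draws, 3,
                dimnames = list(NULL, c("sigma", "gamma", "beta1")))
  for (s in seq_len(n_draws)) {
    sigma <- rinvgamma(1, spec$a_sigma, spec$b_sigma)
    gamma <- rinvgamma(1, spec$a_gamma, spec$b_gamma)
    beta <- rnorm(p, 0, sqrt(sigma))
    out[s, ] <- c(sigma, gamma, beta[1])
  }
  out
}

#' @rdname geweke_marginal
#' @export
geweke_successive <- function(n_draws, X, spec,
                              prop_sd = c(beta = 0.5, alpha = 0.5,
                                          loggamma = 0.5)) {
  stopifnot(is.finite(spec$alpha_prior_var))
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  M <- spec$M
  # initialize from the prior hierarchy
  sigma <- rinvgamma(1, spec$a_sigma, spec$b_sigma)
  gamma <- rinvgamma(1, spec$a_gamma, spec$b_gamma)
  beta <- rnorm(p, 0, sqrt(sigma))
  alpha <- rnorm(M, 0, sqrt(spec$alpha_prior_var))
  e <- matrix(rexp(n * M), n, M) /
    matrix(spec$taus * (1 - spec$taus) / sigma, n, M, byrow = TRUE)
  K <- build_kernel(X, beta, gamma, jitter = 1e-8 * gamma)
  eta <- sample_eta(list(mean = rep(0, n), cov = K))
  Y <- outer(eta, alpha, "+") + sweep(e, 2, 1 - 2 * spec$taus, "*") +
    matrix(rnorm(n * M), n, M) * sqrt(2 * sigma * e)
  rec <- geweke_cpp(X, spec$taus, spec$a_sigma, spec$b_sigma, spec$a_gamma,
                    spec$b_gamma, spec$alpha_prior_var, n_draws,
                    prop_sd[["beta"]], prop_sd[["alpha"]],
                    prop_sd[["loggamma"]], beta, alpha, e, sigma, gamma, Y,
                    1e-8)
  colnames(rec) <- c("sigma", "gamma", "beta1")
  rec
}
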