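# Post-processing: identifiability normalization, link-curve estimation with
# bands, and prediction.

#' Identifiability normalization of the index draws
#'
#' The scale and sign of the index vector are absorbed by the link, so each
#' stored draw is mapped to unit Euclidean norm with positive first
#' component: `sign(beta_1) * beta / ||beta||`. The point estimate is the
#' mean of the normalized draws, re-normalized; intervals are componentwise
#' equal-tailed quantiles of the normalized draws.
#'
#' @param draws A `bcqr_fit` or a matrix of index draws (rows = draws).
#' @param level Credible level of the equal-tailed intervals.
#' @return An object of class `bcqr_estimate`: `estimate` (unit norm, first
#'   component positive), `ci_lower`, `ci_upper`, `ci_length`, and the matrix
#'   of normalized draws.
#' @export
normalize_beta <- function(draws, level = 0.95) {
  B <- if (inherits(draws, "bcqr_fit")) draws$beta else as.matrix(draws)
  nrm <- sqrt(rowSums(B^2))
  if (any(nrm == 0)) stop("cannot normalize a zero index draw")
  sgn <- ifelse(B[, 1] < 0, -1, 1)
  Bn <- B * (sgn / nrm)
  est <- colMeans(Bn)
  est <- est / sqrt(sum(est^2))
  a <- (1 - level) / 2
  ci <- apply(Bn, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  structure(list(estimate = est, ci_lower = ci[1, ], ci_upper = ci[2, ],
                 ci_length = ci[2, ] - ci[1, ], draws = Bn, level = level),
            class = "bcqr_estimate")
}

#' @export
print.bcqr_estimate <- function(x, ...) {
  out <- data.frame(estimate = x$estimate, ci_lower = x$ci_lower,
                    ci_upper = x$ci_upper, ci_length = x$ci_length)
  print(round(out, 4))
  invisible(x)
}

#' Posterior link curve with credible band
#'
#' For each stored draw, the GP conditional mean of the link at grid points
#' given that draw's link values, index and amplitude (kernel interpolation
#' through `K_* K_n^{-1} eta`); the curve is the pointwise posterior mean and
#' the band the pointwise equal-tailed quantiles of those conditional-mean
#' curves. Because the flat quantile intercepts and the GP level trade off,
#' each draw's curve is level-identified by adding its composite intercept
#' and recentering by the posterior-mean intercept before the band is
#' formed; without this the band width reflects the unidentified level
#' split rather than uncertainty about the link's shape. Grid points
#' outside the range of the posterior-mean projections are extrapolations
#' that revert toward the zero prior mean and are flagged.
#'
#' @param fit A `bcqr_fit`.
#' @param grid Numeric vector of index values; defaults to an equispaced
#'   grid over the range of the posterior-mean projections.
#' @param ndraws Number of stored draws to use (evenly thinned).
#' @param level Credible level of the band.
#' @return A data frame with columns `grid`, `mean`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
estimate_link <- function(fit, grid = NULL, ndraws = 1000, level = 0.95) {
  stopifnot(inherits(fit, "bcqr_fit"))
  S <- nrow(fit$beta)
  if (S == 0) stop("empty chain")
  keep <- unique(round(seq(1, S, length.out = min(ndraws, S))))
  proj_hat <- as.numeric(fit$X %*% colMeans(fit$beta))
  if (is.null(grid)) grid <- seq(min(proj_hat), max(proj_hat), length.out = 60)
  curves <- link_cond_cpp(fit$X, fit$beta[keep, , drop = FALSE],
                          fit$gamma[keep], fit$eta[keep, , drop = FALSE],
                          as.matrix(grid), TRUE, fit$control$jitter_rel)
  ic <- intercept_draws(fit)[keep]
  curves <- curves + (ic - mean(ic))
  a <- (1 - level) / 2
  qs <- apply(curves, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(grid = grid, mean = colMeans(curves), lower = qs[1, ],
             upper = qs[2, ],
             extrapolated = grid < min(proj_hat) | grid > max(proj_hat))
}

#' Plot an estimated link curve
#'
#' @param curve Data frame from [estimate_link()].
#' @param truth Optional true link function to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_link <- function(curve, truth = NULL, ...) {
  plot(curve$grid, curve$mean, type = "n", xlab = "index t",
       ylab = "eta(t)", ylim = range(curve$lower, curve$upper), ...)
  polygon(c(curve$grid, rev(curve$grid)), c(curve$lower, rev(curve$upper)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(curve$grid, curve$mean, col = "red", lwd = 2)
  if (!is.null(truth)) lines(curve$grid, truth(curve$grid), col = "black")
  invisible(curve)
}

#' In-sample fitted values
#'
#' Posterior mean of the link values at the training projections plus the
#' composite intercept (the average of the quantile intercepts, or the
#' middle-level intercept).
#'
#' @param object A `bcqr_fit`.
#' @param intercept `"mean"` averages the M quantile intercepts; `"middle"`
#'   uses the middle quantile level's intercept.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
fitted.bcqr_fit <- function(object, intercept = c("mean", "middle"), ...) {
  intercept <- match.arg(intercept)
  a <- intercept_draws(object, intercept)
  colMeans(object$eta) + mean(a)
}

intercept_draws <- function(fit, intercept = c("mean", "middle")) {
  intercept <- match.arg(intercept)
  if (intercept == "mean") rowMeans(fit$alpha)
  else fit$alpha[, ceiling(ncol(fit$alpha) / 2)]
}

#' Predict responses at new covariate values
#'
#' For each stored draw, the GP conditional mean of the link at the new
#' projections `x_new' beta` plus the composite intercept; the prediction is
#' the posterior mean over draws.
#'
#' @param object A `bcqr_fit`.
#' @param newdata Matrix or data frame with the training covariate columns.
#' @param intercept See [fitted.bcqr_fit()].
#' @param ndraws Number of stored draws to use.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.bcqr_fit <- function(object, newdata,
                             intercept = c("mean", "middle"),
                             ndraws = 1000, ...) {
  intercept <- match.arg(intercept)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$X))
    stop("newdata must have the same covariate columns as the training data")
  S <- nrow(object$beta)
  keep <- unique(round(seq(1, S, length.out = min(ndraws, S))))
  etas <- link_cond_cpp(object$X, object$beta[keep, , drop = FALSE],
                        object$gamma[keep], object$eta[keep, , drop = FALSE],
                        Xn, FALSE, object$control$jitter_rel)
  a <- intercept_draws(object, intercept)[keep]
  colMeans(etas + a)
}

#' Mean absolute prediction error
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Mean of `|predicted - observed|`.
#' @export
mape <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  mean(abs(predicted - observed))
}
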