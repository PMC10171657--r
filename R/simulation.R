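# Synthetic-data generators for the three simulation examples and the
# replicated bias/SD study engine.

EX1_A <- sqrt(3) / 2 - 1.645 / sqrt(12)
EX1_C <- sqrt(3) / 2 + 1.645 / sqrt(12)

#' True link functions of the simulation examples
#'
#' Example 1: `sin(pi (t - A) / (C - A))` with `A = sqrt(3)/2 -
#' 1.645/sqrt(12)`, `C = sqrt(3)/2 + 1.645/sqrt(12)` (the standard design
#' constants for a sine link over a uniform index). Example 2:
#' `t^2 exp(t)`. Example 3: `sin(2 t) + 2 exp(-16 t^2)`.
#'
#' @param example Example id, 1, 2 or 3.
#' @return A function of the index value.
#' @export
true_link <- function(example) {
  switch(as.character(example),
         "1" = function(t) sin(pi * (t - EX1_A) / (EX1_C - EX1_A)),
         "2" = function(t) t^2 * exp(t),
         "3" = function(t) sin(2 * t) + 2 * exp(-16 * t^2),
         stop("unknown example id: ", example))
}

#' True index vectors of the simulation examples
#'
#' @inheritParams true_link
#' @return Unit-norm index vector.
#' @export
true_beta <- function(example) {
  switch(as.character(example),
         "1" = c(2, 1, 1, 1) / sqrt(7),
         "2" = c(1, 2) / sqrt(5),
         "3" = c(1, 2) / sqrt(5),
         stop("unknown example id: ", example))
}

#' Simulation scenario
#'
#' One scenario of the replicated study: example id, sample size, error law,
#' replication count and base seed. The error laws are standard normal, t
#' with 3 degrees of freedom, exponential with rate 0.5, and the bimodal
#' normal mixture `0.5 N(-2, 1) + 0.5 N(2, 1)`; each draw is multiplied by
#' the example's noise scale (0.1, 0.2, 0.1 for examples 1-3).
#'
#' @param example Example id, 1, 2 or 3.
#' @param n Sample size per replication.
#' @param error_law One of `"normal"`, `"t3"`, `"exp05"`, `"mixnormal"`.
#' @param reps Number of replications.
#' @param base_seed Integer base seed; replication r uses seed
#'   `base_seed + r` for its data.
#' @param noise_scale Positive error multiplier; defaults to the example's.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(example, n = 100,
                       error_law = c("normal", "t3", "exp05", "mixnormal"),
                       reps = 100, base_seed = 1, noise_scale = NULL) {
  error_law <- match.arg(error_law)
  if (!example %in% 1:3) stop("unknown example id: ", example)
  if (is.null(noise_scale)) noise_scale <- c(0.1, 0.2, 0.1)[example]
  stopifnot(reps >= 1, n >= 1, noise_scale > 0)
  structure(list(example = example, n = as.integer(n),
                 error_law = error_law, reps = as.integer(reps),
                 base_seed = as.integer(base_seed),
                 noise_scale = noise_scale),
            class = "sim_design")
}

draw_error <- function(nr, law) {
  switch(law,
         normal = rnorm(nr),
         t3 = rt(nr, df = 3),
         exp05 = rexp(nr, rate = 0.5),
         mixnormal = rnorm(nr, mean = ifelse(runif(nr) < 0.5, -2, 2), sd = 1),
         stop("unknown error law: ", law))
}

#' Generate one replication of a simulation example
#'
#' Covariates are uniform on `[0,1]^4` (example 1), `[-1,1]^2` (example 2)
#' or `[0,1]^2` (example 3); the response is the example's link of the true
#' index plus the scaled error. Deterministic given `(base_seed,
#' rep_index)`.
#'
#' @param design A [sim_design()].
#' @param rep_index Replication number (1-based).
#' @return List with `X`, `y`, `beta_true`, `link`, `design`.
#' @export
generate_example <- function(design, rep_index = 1) {
  stopifnot(inherits(design, "sim_design"), rep_index >= 1)
  set.seed(design$base_seed + as.integer(rep_index))
  n <- design$n
  beta <- true_beta(design$example)
  X <- switch(as.character(design$example),
              "1" = matrix(runif(n * 4), n, 4),
              "2" = matrix(runif(n * 2, -1, 1), n, 2),
              "3" = matrix(runif(n * 2), n, 2))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  link <- true_link(design$example)
  eps <- draw_error(n, design$error_law)
  y <- link(as.numeric(X %*% beta)) + design$noise_scale * eps
  list(X = X, y = y, beta_true = beta, link = link, design = design)
}

#' Fit one method of the comparison study
#'
#' `BCQR5`/`BCQR9` are the composite model with M = 5 or 9 quantile levels;
#' `BQR` is the identical machinery at the single level tau = 0.5; `BLR` is
#' the Gaussian-likelihood mean-regression counterpart of the same GP
#' single-index hierarchy.
#'
#' @param method One of `"BLR"`, `"BQR"`, `"BCQR5"`, `"BCQR9"`.
#' @param X,y Data.
#' @param control A [sampler_control()].
#' @return List with the `bcqr_estimate` (`estimate`), the fit, and the
#'   in-sample `fitted` values.
#' @export
fit_method <- function(method, X, y, control = sampler_control()) {
  fit <- switch(method,
                BLR = blr(X, y, control = control),
                BQR = bqr(X, y, control = control),
                BCQR5 = bcqr(X, y, M = 5, control = control),
                BCQR9 = bcqr(X, y, M = 9, control = control),
                stop("unknown method: ", method))
  list(estimate = normalize_beta(fit), fit = fit, fitted = fitted(fit))
}

#' Replicated bias/SD comparison study
#'
#' For each replication of the design, fits each requested method and
#' collects the normalized index estimate and the in-sample fitted values.
#' Reports, per method and index component, `100 * mean(estimate - truth)`
#' and `100 * sd(estimate)` across replications, and per method the
#' fitted-response summary: `100 *` the across-replication mean of the mean
#' fitted-minus-observed residual, and the across-replication mean of the
#' per-replication SD of the fitted values.
#'
#' @param design A [sim_design()].
#' @param methods Character vector of methods (see [fit_method()]).
#' @param control A [sampler_control()] used for every fit; its seed is
#'   ignored (per-replication seeds derive from the design's base seed).
#' @return List with `table` (per-component rows), `fitted_table` (one row
#'   per method), the array of estimates, and any replication failures.
#' @export
run_study <- function(design, methods = c("BLR", "BQR", "BCQR5", "BCQR9"),
                      control = sampler_control()) {
  stopifnot(inherits(design, "sim_design"))
  p <- length(true_beta(design$example))
  est <- array(NA_real_, c(design$reps, length(methods), p),
               dimnames = list(NULL, methods, NULL))
  fit_bias <- matrix(NA_real_, design$reps, length(methods),
                     dimnames = list(NULL, methods))
  fit_sd <- fit_bias
  failures <- list()
  for (r in seq_len(design$reps)) {
    dat <- generate_example(design, r)
    for (k in seq_along(methods)) {
      ctl <- control
      ctl$seed <- (design$base_seed + 7919L * as.integer(r) + 104729L * k) %%
        2147483546L
      res <- tryCatch(fit_method(methods[k], dat$X, dat$y, control = ctl),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(rep = r, method = methods[k], message = conditionMessage(res))
        next
      }
      est[r, k, ] <- res$estimate$estimate
      fit_bias[r, k] <- mean(res$fitted - dat$y)
      fit_sd[r, k] <- sd(res$fitted)
    }
  }
  truth <- true_beta(design$example)
  rows <- list()
  for (k in seq_along(methods)) {
    for (j in seq_len(p)) {
      v <- est[, k, j]
      ok <- !is.na(v)
      rows[[length(rows) + 1L]] <- data.frame(
        method = methods[k], param = paste0("beta", j),
        bias100 = 100 * mean(v[ok] - truth[j]),
        sd100 = if (sum(ok) > 1) 100 * sd(v[ok]) else NA_real_,
        n_ok = sum(ok))
    }
  }
  tab <- do.call(rbind, rows)
  ftab <- data.frame(
    method = methods,
    bias100 = 100 * colMeans(fit_bias, na.rm = TRUE),
    sdY = colMeans(fit_sd, na.rm = TRUE))
  list(table = tab, fitted_table = ftab, estimates = est,
       failures = failures, design = design)
}
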