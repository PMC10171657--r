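test_that("initialization is finite, ordered and seed-deterministic", {
  for (law in c("normal", "t3", "exp05", "mixnormal")) {
    d <- generate_example(sim_design(1, n = 50, error_law = law, reps = 1,
                                     base_seed = 3), 1)
    set.seed(1)
    st <- initialize_state(d$X, d$y, model_spec(M = 5))
    expect_true(all(is.finite(unlist(st))))
    expect_true(all(diff(st$alpha) >= 0))  # empirical quantiles nondecreasing
    set.seed(1)
    st2 <- initialize_state(d$X, d$y, model_spec(M = 5))
    expect_identical(st, st2)
  }
  expect_error(initialize_state(matrix(1:6, 2, 3), c(1, 2)), "observations")
})

test_that("identical seeds give identical chains", {
  d <- generate_example(sim_design(2, n = 30, reps = 1, base_seed = 5), 1)
  ctl <- sampler_control(n_iter = 300, n_burnin = 100, seed = 11)
  f1 <- bcqr(d$X, d$y, M = 3, control = ctl)
  f2 <- bcqr(d$X, d$y, M = 3, control = ctl)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$eta, f2$eta)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$accept, f2$accept)
})

test_that("adaptation moves scales in the right direction and freezes", {
  s <- 1
  for (t in 1:50) s <- adapt_proposal(s, TRUE, t)
  expect_gt(s, 1)           # constant acceptance inflates the scale
  s2 <- 1
  for (t in 1:50) s2 <- adapt_proposal(s2, FALSE, t)
  expect_lt(s2, 1)          # constant rejection shrinks it
  expect_error(adapt_proposal(-1, TRUE, 1))
})

test_that("adapted chains land inside the acceptance band", {
  d <- generate_example(sim_design(1, n = 60, reps = 1, base_seed = 8), 1)
  fit <- bcqr(d$X, d$y, M = 5,
              control = sampler_control(n_iter = 3000, n_burnin = 1500,
                                        seed = 21))
  expect_true(all(fit$accept >= 0.10 & fit$accept <= 0.30))
})

test_that("per-m intercept updates are available and valid", {
  d <- generate_example(sim_design(2, n = 30, reps = 1, base_seed = 9), 1)
  fit <- bcqr(d$X, d$y, M = 3,
              control = sampler_control(n_iter = 400, n_burnin = 200,
                                        alpha_update = "per-m", seed = 2))
  expect_true(all(is.finite(fit$alpha)))
  expect_true(fit$accept[["alpha"]] >= 0 && fit$accept[["alpha"]] <= 1)
})

test_that("single-quantile fit is exactly the composite fit with M = 1", {
  d <- generate_example(sim_design(2, n = 25, reps = 1, base_seed = 4), 1)
  ctl <- sampler_control(n_iter = 200, n_burnin = 100, seed = 33)
  f1 <- bqr(d$X, d$y, control = ctl)
  f2 <- bcqr(d$X, d$y, M = 1, control = ctl)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma, f2$sigma)
})

test_that("with the amplitude pinned near zero the index samples its prior", {
  # zero-information configuration: a vanishing kernel amplitude makes the
  # collapsed likelihood flat in beta, so the beta chain must reproduce its
  # N(0, sigma I) prior mixed over the sigma draws
  set.seed(70)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n, 0, 0.3)
  fit <- bcqr(X, y, M = 1,
              control = sampler_control(n_iter = 12000, n_burnin = 2000,
                                        seed = 71),
              fix_gamma = 1e-12)
  stdz <- fit$beta[, 1] / sqrt(fit$sigma)
  expect_lt(abs(mean(stdz)) / batch_se(stdz), 4)
  expect_lt(abs(mean(stdz^2) - 1) / batch_se(stdz^2), 4)
})

test_that("index recovery on model-generated data", {
  d <- generate_example(sim_design(2, n = 60, reps = 1, base_seed = 12), 1)
  fit <- bcqr(d$X, d$y, M = 5,
              control = sampler_control(n_iter = 3000, n_burnin = 1500,
                                        seed = 13))
  est <- normalize_beta(fit)
  psd <- apply(est$draws, 2, sd)
  expect_true(all(abs(est$estimate - d$beta_true) <= 3 * psd))
})

test_that("split-chain convergence diagnostic stays near one", {
  d <- generate_example(sim_design(3, n = 50, reps = 1, base_seed = 6), 1)
  fit <- bcqr(d$X, d$y, M = 5,
              control = sampler_control(n_iter = 4000, n_burnin = 2000,
                                        seed = 17))
  # split-half potential scale reduction for the normalized first component
  b <- normalize_beta(fit)$draws[, 1]
  h <- length(b) %/% 2
  halves <- list(b[1:h], b[(h + 1):(2 * h)])
  W <- mean(sapply(halves, var))
  B <- h * var(sapply(halves, mean))
  rhat <- sqrt(((h - 1) / h * W + B / h) / W)
  expect_lt(rhat, 1.1)
})
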