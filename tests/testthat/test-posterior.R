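test_that("link full conditional matches joint-Gaussian conditioning", {
  for (seed in c(3, 8, 21)) {
    inst <- random_instance(n = 3, M = 2, seed = seed)
    K <- with(inst, build_kernel(X, beta, gamma, jitter = 1e-10))
    st <- with(inst, collapse_pseudo_data(y, alpha, e, sigma, taus))
    cond <- eta_full_conditional(st, K)
    oracle <- brute_eta_conditional(inst)
    expect_equal(cond$mean, oracle$mean, tolerance = 1e-8)
    expect_equal(cond$cov, oracle$cov, tolerance = 1e-8)
  }
})

test_that("link conditional has the right limits", {
  inst <- random_instance(n = 3, M = 1, seed = 2)
  K <- with(inst, build_kernel(X, beta, gamma, jitter = 1e-10))
  # enormous pseudo-variances: posterior reverts to the prior
  stw <- with(inst, collapse_pseudo_data(y, alpha, e * 1e10, sigma, taus))
  cw <- eta_full_conditional(stw, K)
  expect_equal(cw$mean, rep(0, 3), tolerance = 1e-6)
  expect_equal(cw$cov, K, tolerance = 1e-6)
  # vanishing prior pins the link at zero
  st <- with(inst, collapse_pseudo_data(y, alpha, e, sigma, taus))
  c0 <- eta_full_conditional(st, 1e-12 * K)
  expect_equal(c0$mean, rep(0, 3), tolerance = 1e-6)
  expect_lt(max(abs(c0$cov)), 1e-6)
})

test_that("link draws reproduce the conditional's first two moments", {
  mu <- c(1, -2, 0.5)
  A <- matrix(c(2, 0.8, 0.3, 0.8, 1.5, 0.5, 0.3, 0.5, 1), 3, 3)
  S <- crossprod(A)
  set.seed(14)
  draws <- t(replicate(2e4, sample_eta(list(mean = mu, cov = S))))
  expect_lt(max(abs(colMeans(draws) - mu) / sqrt(diag(S) / 2e4)), 4)
  emp <- cov(draws)
  se <- sqrt((diag(S) %o% diag(S) + S^2) / 2e4)  # SE of a normal covariance
  expect_lt(max(abs(emp - S) / se), 4)
  # zero covariance returns the mean exactly
  expect_identical(sample_eta(list(mean = mu, cov = matrix(0, 3, 3))), mu)
})

test_that("collapsed Metropolis targets agree with the brute-force oracle", {
  inst <- random_instance(n = 3, M = 2, seed = 31)
  b2 <- inst$beta + c(0.4, -0.7)
  d_pkg <- with(inst,
    log_target_beta(beta, alpha, e, gamma, sigma, X, y, taus,
                    jitter_rel = 0) -
    log_target_beta(b2, alpha, e, gamma, sigma, X, y, taus, jitter_rel = 0))
  d_or <- with(inst,
    (brute_logmarg(inst) - 0.5 * sum(beta^2) / sigma) -
    (brute_logmarg(inst, beta = b2) - 0.5 * sum(b2^2) / sigma))
  expect_equal(d_pkg, d_or, tolerance = 1e-8)

  a2 <- inst$alpha + c(-0.3, 0.6)
  d_pkg <- with(inst,
    log_target_alpha(alpha, beta, e, gamma, sigma, X, y, taus) -
    log_target_alpha(a2, beta, e, gamma, sigma, X, y, taus))
  d_or <- brute_logmarg(inst) - brute_logmarg(inst, alpha = a2)
  expect_equal(d_pkg, d_or, tolerance = 1e-8)

  g2 <- inst$gamma * 1.9
  ag <- 0.5; bg <- 0.5
  d_pkg <- with(inst,
    log_target_gamma(gamma, beta, alpha, e, sigma, X, y, taus, ag, bg) -
    log_target_gamma(g2, beta, alpha, e, sigma, X, y, taus, ag, bg))
  d_or <- with(inst,
    (brute_logmarg(inst) - (ag + 1) * log(gamma) - bg / gamma) -
    (brute_logmarg(inst, gamma = g2) - (ag + 1) * log(g2) - bg / g2))
  expect_equal(d_pkg, d_or, tolerance = 1e-8)
  expect_error(with(inst, log_target_gamma(-1, beta, alpha, e, sigma, X, y,
                                           taus)), "positive")
})

test_that("gamma prior term matches its closed form at gamma = 1", {
  inst <- random_instance(n = 3, M = 1, seed = 4)
  lt <- with(inst, log_target_gamma(1, beta, alpha, e, sigma, X, y, taus,
                                    a_gamma = 0.5, b_gamma = 0.5))
  la <- with(inst, collapsed_logdensity(beta, alpha, e, 1, sigma, X, y, taus))
  expect_equal(lt - la, -0.5)
})

test_that("latent scale draws follow the GIG conditional law", {
  set.seed(77)
  sigma <- 0.6
  u <- 1.4  # residual y - alpha - eta
  chi <- u^2 / (2 * sigma)
  psi <- 1 / (2 * sigma)
  e <- sample_e(y = u, alpha = 0, eta = 0, sigma = sigma, taus = 0.5)
  expect_true(e > 0)
  draws <- replicate(4e4, sample_e(u, 0, 0, sigma, 0.5)[1, 1])
  m1 <- gig_moment(1, chi, psi)
  m2 <- gig_moment(2, chi, psi)
  expect_lt(abs(mean(draws) - m1) / (sd(draws) / sqrt(length(draws))), 4)
  expect_lt(abs(mean(draws^2) - m2) / (sd(draws^2) / sqrt(length(draws))), 4)
  # zero residual: the Gamma limit, still strictly positive
  z <- replicate(200, sample_e(0, 0, 0, sigma, 0.5)[1, 1])
  expect_true(all(z > 0))
})

test_that("latent scale Gibbs draws preserve a quadrature joint", {
  # one observation, one level: alternate e | sigma-fixed toy conditional
  # draws and compare the stationary e-marginal against 1-D quadrature of
  # prior x likelihood
  set.seed(31)
  y <- 0.9; alphav <- 0.1; etav <- 0.2; sigma <- 0.5; tau <- 0.5
  u <- y - alphav - etav
  post_un <- function(e) {
    z <- y - alphav - (1 - 2 * tau) * e
    dnorm(z, etav, sqrt(2 * sigma * e)) *
      (tau * (1 - tau) / sigma) * exp(-tau * (1 - tau) * e / sigma)
  }
  Z <- integrate(post_un, 0, Inf)$value
  m1 <- integrate(function(e) e * post_un(e), 0, Inf)$value / Z
  draws <- replicate(4e4, sample_e(y, alphav, etav, sigma, tau)[1, 1])
  expect_lt(abs(mean(draws) - m1) / (sd(draws) / sqrt(length(draws))), 4)
})

test_that("sigma conditional is the IG implied by the full hierarchy", {
  # grid oracle: the joint log density as a function of sigma differs from
  # the IG(3Mn/2 + p/2 + a, rate) log pdf by a constant
  set.seed(55)
  n <- 2; M <- 2
  taus <- quantile_grid(M)
  y <- rnorm(n); alphav <- rnorm(M); etav <- rnorm(n)
  e <- matrix(rexp(n * M) + 0.3, n, M); betav <- rnorm(3)
  a_s <- 0.5; b_s <- 0.5
  joint_log <- function(s) {
    z <- outer(y, alphav, "-") - sweep(e, 2, 1 - 2 * taus, "*")
    sum(dnorm(z, etav, sqrt(2 * s * e), log = TRUE)) +
      sum(log(taus * (1 - taus) / s) -
            sweep(e, 2, taus * (1 - taus), "*") / s) +
      sum(dnorm(betav, 0, sqrt(s), log = TRUE)) +
      dinvgamma(s, a_s, b_s, log = TRUE)
  }
  shape <- 1.5 * M * n + length(betav) / 2 + a_s
  z <- outer(y, alphav, "-") - sweep(e, 2, 1 - 2 * taus, "*")
  rate <- sum((z - etav)^2 / (4 * e)) +
    sum(sweep(e, 2, taus * (1 - taus), "*")) + sum(betav^2) / 2 + b_s
  grid <- seq(0.2, 5, length.out = 30)
  diffs <- sapply(grid, joint_log) - dinvgamma(grid, shape, rate, log = TRUE)
  expect_lt(max(diffs) - min(diffs), 1e-8)
  # and the sampler's draws match that IG law
  set.seed(56)
  draws <- replicate(2e4, sample_sigma(y, betav, alphav, e, etav, taus,
                                       a_s, b_s))
  expect_lt(abs(mean(draws) - rate / (shape - 1)) /
              (sd(draws) / sqrt(length(draws))), 4)
})

test_that("sampled positivity holds over long runs", {
  set.seed(60)
  inst <- random_instance(n = 4, M = 2, seed = 60)
  ok <- TRUE
  for (k in 1:200) {
    e <- with(inst, sample_e(y, alpha, rnorm(n), sigma, taus))
    s <- with(inst, sample_sigma(y, beta, alpha, e, rnorm(n), taus))
    ok <- ok && all(e > 0) && s > 0
  }
  expect_true(ok)
})
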