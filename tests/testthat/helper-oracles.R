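# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: dense joint-Gaussian algebra, quadrature of
# stated densities, and small random instances.

log_dmvnorm <- function(x, mu, S) {
  R <- chol(S)
  w <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(w^2)
}

# A small random model instance (data + latents) for oracle comparisons.
random_instance <- function(n = 3, M = 2, p = 2, seed = 1) {
  set.seed(seed)
  list(n = n, M = M, p = p,
       X = matrix(rnorm(n * p), n, p),
       y = rnorm(n),
       taus = quantile_grid(M),
       alpha = rnorm(M),
       e = matrix(rexp(n * M) + 0.2, n, M),
       sigma = 0.5 + runif(1),
       gamma = 0.5 + runif(1),
       beta = rnorm(p))
}

# Log marginal density of the stacked pseudo-data with the link integrated
# out, by dense (Mn)-dimensional Gaussian algebra.
brute_logmarg <- function(inst, beta = inst$beta, alpha = inst$alpha,
                          gamma = inst$gamma) {
  C <- build_kernel(inst$X, beta, gamma, jitter = 0)
  H <- kronecker(rep(1, inst$M), diag(inst$n))
  st <- collapse_pseudo_data(inst$y, alpha, inst$e, inst$sigma, inst$taus)
  D <- diag(as.numeric(2 * inst$sigma * inst$e))
  log_dmvnorm(as.numeric(st$z), rep(0, inst$n * inst$M),
              H %*% C %*% t(H) + D)
}

# The (beta, alpha, gamma)-free constant separating log A from the full log
# marginal.
brute_const <- function(inst) {
  with(inst, 0.5 * sum(log(2 * pi * 2 * sigma * e)))
}

# Conditional of the link given the pseudo-data by brute-force conditioning
# in the joint Gaussian over (eta, z).
brute_eta_conditional <- function(inst, jitter = 1e-10) {
  with(inst, {
    C <- build_kernel(X, beta, gamma, jitter = jitter)
    H <- kronecker(rep(1, M), diag(n))
    st <- collapse_pseudo_data(y, alpha, e, sigma, taus)
    D <- diag(as.numeric(2 * sigma * e))
    S_zz <- H %*% C %*% t(H) + D
    S_ez <- C %*% t(H)
    list(mean = as.numeric(S_ez %*% solve(S_zz, as.numeric(st$z))),
         cov = C - S_ez %*% solve(S_zz, t(S_ez)))
  })
}

# Unnormalized GIG(1/2, chi, psi) density and its quadrature moments.
gig_moment <- function(k, chi, psi) {
  f <- function(x) x^(-0.5) * exp(-(chi / x + psi * x) / 2)
  Z <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
  integrate(function(x) x^k * f(x), 0, Inf, rel.tol = 1e-10)$value / Z
}

gig_moment_rho <- function(k, rho, chi, psi) {
  f <- function(x) x^(rho - 1) * exp(-(chi / x + psi * x) / 2)
  Z <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
  integrate(function(x) x^k * f(x), 0, Inf, rel.tol = 1e-10)$value / Z
}

batch_se <- function(x, nb = 50) {
  bs <- floor(length(x) / nb)
  bm <- colMeans(matrix(x[1:(bs * nb)], bs, nb))
  sd(bm) / sqrt(nb)
}
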