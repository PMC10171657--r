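// Core numerics for Bayesian composite quantile single-index regression.
//
// The model keeps one response copy per quantile level internally (an n x M
// matrix Y); the public fitting path replicates the observed n-vector across
// columns, while the Geweke joint simulator generates the columns as data.
// All randomness goes through R's RNG so set.seed() governs every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double JITTER_MAX_REL = 1e-2;  // escalation cap, relative to gamma

// ---------------------------------------------------------------- kernel ----

// Reformulated squared-exponential kernel on projected indices: the bandwidth
// of the original kernel is absorbed by leaving ||beta|| free, so
// C(i,j) = gamma * exp{ -(x_i'beta - x_j'beta)^2 }.
static mat kernel_build(const vec& proj, double gamma) {
  const uword n = proj.n_elem;
  mat C(n, n);
  for (uword j = 0; j < n; ++j) {
    C(j, j) = gamma;
    for (uword i = j + 1; i < n; ++i) {
      const double d = proj[i] - proj[j];
      const double v = gamma * std::exp(-d * d);
      C(i, j) = v;
      C(j, i) = v;
    }
  }
  return C;
}

// Upper-triangular Cholesky of (A + j*I), escalating j tenfold from j0 up to
// jmax. A factor whose diagonal has collapsed (relative to its largest
// entry) would make later triangular solves singular, so it counts as a
// failure too. Returns false when even jmax fails.
static bool chol_jitter(mat& R, const mat& A, double j0, double jmax) {
  double j = j0;
  for (;;) {
    mat Aj = A;
    if (j > 0) Aj.diag() += j;
    if (chol(R, Aj) && R.diag().min() > 1e-7 * R.diag().max()) return true;
    if (j <= 0) j = (jmax > 0 ? jmax * 1e-6 : 1e-12);
    else j *= 10.0;
    if (j > jmax || !(jmax > 0)) return false;
  }
}

// ------------------------------------------------------- pseudo-data ----

// z_im = y_im - alpha_m - (1 - 2 tau_m) e_im, pseudo-variance v_im = 2 sigma
// e_im; combined per-observation precision-sum quantities feeding Eq. for the
// link's full conditional:
//   etilde_i = (sum_m v_im^{-1})^{-1},  F_i = sum_m z_im / v_im,
//   q = sum_im z_im^2 / v_im.
static void pseudo_stats(const mat& Y, const vec& alpha, const mat& e,
                         double sigma, const vec& taus,
                         mat& z, vec& et, vec& Fv, double& q) {
  const uword n = Y.n_rows, M = Y.n_cols;
  z.set_size(n, M);
  vec prec(n, fill::zeros);
  Fv.zeros(n);
  q = 0.0;
  for (uword m = 0; m < M; ++m) {
    const double shift = 1.0 - 2.0 * taus[m];
    const double a = alpha[m];
    for (uword i = 0; i < n; ++i) {
      const double v = 2.0 * sigma * e(i, m);
      const double zim = Y(i, m) - a - shift * e(i, m);
      z(i, m) = zim;
      prec[i] += 1.0 / v;
      Fv[i] += zim / v;
      q += zim * zim / v;
    }
  }
  et = 1.0 / prec;
}

struct CollapseOut {
  mat C;    // kernel (no jitter on diagonal beyond gamma itself)
  mat R;    // chol of C + E (+ jitter)
  vec et;   // etilde
  vec Fv;   // F
  mat z;    // pseudo-data
};

// log A(beta, alpha, e, gamma, sigma) up to a (beta, alpha, gamma)-free
// constant: the log marginal of the stacked pseudo-observations with the link
// integrated out,
//   log A = 1/2 log|E| - 1/2 log|C+E| - q/2 + F' Sigma F / 2,
// computed through one Cholesky of (C + E).
static double logA_core(const mat& X, const mat& Y, const vec& beta,
                        const vec& alpha, const mat& e, double gamma,
                        double sigma, const vec& taus, double jitter_rel,
                        CollapseOut* out = nullptr) {
  vec proj = X * beta;
  if (!proj.is_finite())
    Rcpp::stop("non-finite projections x'beta in kernel construction");
  mat C = kernel_build(proj, gamma);
  mat z;
  vec et, Fv;
  double q;
  pseudo_stats(Y, alpha, e, sigma, taus, z, et, Fv, q);
  mat A = C + diagmat(et);
  mat R;
  if (!chol_jitter(R, A, jitter_rel * gamma, JITTER_MAX_REL * gamma))
    Rcpp::stop("Cholesky of C + E failed after jitter escalation");
  const vec EF = et % Fv;
  const vec w = solve(trimatl(R.t()), EF, solve_opts::fast);
  const double logA = 0.5 * accu(log(et)) - accu(log(R.diag()))
      - 0.5 * q + 0.5 * (dot(EF, Fv) - dot(w, w));
  if (out) {
    out->C = std::move(C);
    out->R = std::move(R);
    out->et = std::move(et);
    out->Fv = std::move(Fv);
    out->z = std::move(z);
  }
  return logA;
}

// Sigma = C (C+E)^{-1} E, computed from the numerically stable side as
// E - E (C+E)^{-1} E (the subtracted term is small exactly when the kernel
// dominates the pseudo-noise, avoiding catastrophic cancellation at large
// amplitudes); mu = Sigma F.
static void eta_conditional_core(const mat& R, const vec& et, const vec& Fv,
                                 vec& mu, mat& Sigma) {
  mat Ed = diagmat(et);
  mat W = solve(trimatu(R), solve(trimatl(R.t()), Ed, solve_opts::fast),
                solve_opts::fast);
  Sigma = Ed - Ed * W;
  Sigma = 0.5 * (Sigma + Sigma.t());
  mu = Sigma * Fv;
}

// Gaussian draw with a rank-tolerant factorization: Cholesky with small
// jitter first, symmetric-eigendecomposition fallback with negative
// eigenvalues clipped at zero.
static vec draw_gauss(const vec& mu, const mat& Sigma) {
  const uword n = mu.n_elem;
  const double dmax = Sigma.diag().max();
  if (!(dmax > 0)) return mu;  // degenerate conditional: point mass at mu
  vec zr(n);
  for (uword i = 0; i < n; ++i) zr[i] = norm_rand();
  mat R;
  if (chol_jitter(R, Sigma, dmax * 1e-12, dmax * 1e-6))
    return mu + R.t() * zr;
  vec d;
  mat V;
  if (!eig_sym(d, V, Sigma))
    Rcpp::stop("factorization of the link conditional covariance failed");
  d.transform([](double x) { return x > 0 ? std::sqrt(x) : 0.0; });
  return mu + V * (d % zr);
}

// ------------------------------------------------------------ GIG draws ----

// Inverse Gaussian (mean mu, shape lambda), Michael-Schucany-Haas. The
// textbook formula for the smaller quadratic root cancels catastrophically
// when mu >> lambda, so it is computed as mu over the (stable) larger root:
// with t = mu y / lambda, the roots are mu (1 + t/2 -+ sqrt(t + t^2/4)) and
// multiply to mu^2.
static double rinvgauss1(double mu, double lambda) {
  const double nu = norm_rand();
  const double y = nu * nu;
  const double t = mu * y / lambda;
  const double big = 1.0 + 0.5 * t + std::sqrt(t + 0.25 * t * t);
  const double x1 = mu / big;
  if (unif_rand() * (big + 1.0) <= big) return x1;
  return mu * big;
}

// GIG with order 1/2 in the x^{rho-1} exp{-(chi/x + psi x)/2} convention.
// Reciprocal of an inverse Gaussian: 1/X ~ IG(sqrt(psi/chi), psi).
// chi -> 0 degenerates to Gamma(1/2, rate psi/2).
static double rgig_half(double chi, double psi) {
  if (!(psi > 0) || !std::isfinite(psi) || !std::isfinite(chi))
    Rcpp::stop("rgig_half: invalid (chi, psi) = (%g, %g)", chi, psi);
  if (!(chi > psi * 1e-60))  // exact zero or numerically indistinguishable
    return R::rgamma(0.5, 2.0 / psi);
  const double y = rinvgauss1(std::sqrt(psi / chi), psi);
  double x = 1.0 / y;
  if (!std::isfinite(x) || x <= 0.0) x = std::numeric_limits<double>::min();
  return x;
}

// ----------------------------------------------------------- exports -------

// [[Rcpp::export]]
arma::mat kernel_cpp(const arma::mat& X, const arma::vec& beta, double gamma,
                     double jitter) {
  vec proj = X * beta;
  if (!proj.is_finite()) Rcpp::stop("non-finite projections x'beta");
  mat C = kernel_build(proj, gamma);
  if (jitter > 0) C.diag() += jitter;
  return C;
}

// [[Rcpp::export]]
Rcpp::List collapse_cpp(const arma::mat& Y, const arma::vec& alpha,
                        const arma::mat& e, double sigma,
                        const arma::vec& taus) {
  mat z;
  vec et, Fv;
  double q;
  pseudo_stats(Y, alpha, e, sigma, taus, z, et, Fv, q);
  return Rcpp::List::create(Rcpp::Named("z") = z, Rcpp::Named("etilde") = et,
                            Rcpp::Named("F") = Fv, Rcpp::Named("q") = q);
}

// [[Rcpp::export]]
double logA_cpp(const arma::mat& X, const arma::mat& Y, const arma::vec& beta,
                const arma::vec& alpha, const arma::mat& e, double gamma,
                double sigma, const arma::vec& taus, double jitter_rel) {
  return logA_core(X, Y, beta, alpha, e, gamma, sigma, taus, jitter_rel);
}

// [[Rcpp::export]]
Rcpp::List eta_cond_cpp(const arma::mat& K, const arma::vec& etilde,
                        const arma::vec& Fv) {
  mat A = K + diagmat(etilde);
  mat R;
  const double scale = K.diag().max();
  if (!chol_jitter(R, A, 0.0, JITTER_MAX_REL * std::max(scale, 1e-300)))
    Rcpp::stop("Cholesky of C + E failed after jitter escalation");
  vec mu;
  mat Sigma;
  eta_conditional_core(R, etilde, Fv, mu, Sigma);
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("cov") = Sigma);
}

// [[Rcpp::export]]
arma::vec sample_eta_cpp(const arma::vec& mu, const arma::mat& Sigma) {
  return draw_gauss(mu, Sigma);
}

// [[Rcpp::export]]
arma::mat sample_e_cpp(const arma::mat& U, double sigma) {
  const uword n = U.n_rows, M = U.n_cols;
  const double psi = 1.0 / (2.0 * sigma);
  mat e(n, M);
  for (uword m = 0; m < M; ++m)
    for (uword i = 0; i < n; ++i)
      e(i, m) = rgig_half(U(i, m) * U(i, m) / (2.0 * sigma), psi);
  return e;
}

// [[Rcpp::export]]
arma::vec rgig_half_cpp(int nr, double chi, double psi) {
  vec out(nr);
  for (int i = 0; i < nr; ++i) out[i] = rgig_half(chi, psi);
  return out;
}

// ------------------------------------------------------------ the sweep ----

struct Pars {
  mat X;
  vec taus;
  double a_sigma, b_sigma, a_gamma, b_gamma;
  double alpha_prior_var;  // Inf = flat
  bool gaussian;           // Gaussian-likelihood baseline (e fixed at 1/2)
  double jitter_rel;
  bool per_m_alpha;
  bool update_gamma;
};

struct State {
  vec beta, alpha, eta;
  mat e;
  double sigma, gamma;
  mat Y;
  double curA;
};

struct Acc {
  double b = 0, a = 0, g = 0;
};

static double alpha_logprior(const vec& a, double v) {
  if (!std::isfinite(v)) return 0.0;
  return -0.5 * dot(a, a) / v;
}

// One full iteration of the partially collapsed scheme. Block order matters:
// the index, intercepts and amplitude are updated against targets with the
// link integrated out; the link is redrawn only afterwards, then the latent
// scales and the ALD scale. Optionally redraws the data (Geweke simulator).
static void sweep(State& s, const Pars& P, double sc_b, double sc_a,
                  double sc_g, Acc& acc, bool redraw_y) {
  const uword n = s.Y.n_rows, M = s.Y.n_cols, p = s.beta.n_elem;

  // current-state collapse, kept in step with the Metropolis blocks so the
  // link draw below can reuse the accepted state's factorization
  CollapseOut cur;
  s.curA = logA_core(P.X, s.Y, s.beta, s.alpha, s.e, s.gamma, s.sigma, P.taus,
                     P.jitter_rel, &cur);

  // ---- index vector: random-walk Metropolis against log A - b'b/(2 sigma)
  {
    vec bp = s.beta;
    for (uword j = 0; j < p; ++j) bp[j] += sc_b * norm_rand();
    CollapseOut co;
    const double Ap = logA_core(P.X, s.Y, bp, s.alpha, s.e, s.gamma, s.sigma,
                                P.taus, P.jitter_rel, &co);
    const double lr = (Ap - 0.5 * dot(bp, bp) / s.sigma)
        - (s.curA - 0.5 * dot(s.beta, s.beta) / s.sigma);
    if (std::log(unif_rand()) < lr) {
      s.beta = bp;
      s.curA = Ap;
      cur = std::move(co);
      acc.b += 1.0;
    }
  }

  // ---- intercepts: joint or one-at-a-time random walk against log A
  if (P.per_m_alpha) {
    double hits = 0.0;
    for (uword m = 0; m < M; ++m) {
      vec ap = s.alpha;
      ap[m] += sc_a * norm_rand();
      CollapseOut co;
      const double Aa = logA_core(P.X, s.Y, s.beta, ap, s.e, s.gamma, s.sigma,
                                  P.taus, P.jitter_rel, &co);
      const double lr = (Aa + alpha_logprior(ap, P.alpha_prior_var))
          - (s.curA + alpha_logprior(s.alpha, P.alpha_prior_var));
      if (std::log(unif_rand()) < lr) {
        s.alpha = ap;
        s.curA = Aa;
        cur = std::move(co);
        hits += 1.0;
      }
    }
    acc.a += hits / static_cast<double>(M);
  } else {
    vec ap = s.alpha;
    for (uword m = 0; m < M; ++m) ap[m] += sc_a * norm_rand();
    CollapseOut co;
    const double Aa = logA_core(P.X, s.Y, s.beta, ap, s.e, s.gamma, s.sigma,
                                P.taus, P.jitter_rel, &co);
    const double lr = (Aa + alpha_logprior(ap, P.alpha_prior_var))
        - (s.curA + alpha_logprior(s.alpha, P.alpha_prior_var));
    if (std::log(unif_rand()) < lr) {
      s.alpha = ap;
      s.curA = Aa;
      cur = std::move(co);
      acc.a += 1.0;
    }
  }

  // ---- amplitude: random walk on log gamma, IG(a_gamma, b_gamma) prior,
  //      log-scale Jacobian included in the ratio
  if (P.update_gamma) {
    const double lg = std::log(s.gamma);
    const double lgp = lg + sc_g * norm_rand();
    const double gp = std::exp(lgp);
    CollapseOut co;
    const double Ag = logA_core(P.X, s.Y, s.beta, s.alpha, s.e, gp, s.sigma,
                                P.taus, P.jitter_rel, &co);
    const double lr =
        (Ag - (P.a_gamma + 1.0) * lgp - P.b_gamma / gp + lgp)
        - (s.curA - (P.a_gamma + 1.0) * lg - P.b_gamma / s.gamma + lg);
    if (std::log(unif_rand()) < lr) {
      s.gamma = gp;
      s.curA = Ag;
      cur = std::move(co);
      acc.g += 1.0;
    }
  }

  // ---- link values: exact Gaussian full-conditional draw via Matheron's
  // rule written from the stable side: with A = C + E and draws
  // f ~ N(0, C), eps ~ N(0, E), the variate
  //   mu + eps - E A^{-1} (f + eps),   mu = E F - E A^{-1} E F,
  // has exactly the conditional law N(C A^{-1} E F, C A^{-1} E). The
  // subtracted terms stay small when the kernel dominates the pseudo-noise
  // (large amplitudes), so no catastrophic cancellation, and the
  // rank-deficient conditional covariance is never factorized.
  {
    const mat& R = cur.R;  // chol of C + E (+ jitter)
    const vec EF = cur.et % cur.Fv;
    const vec mu = EF - cur.et %
        solve(trimatu(R), solve(trimatl(R.t()), EF, solve_opts::fast),
              solve_opts::fast);
    mat Rc;
    if (!chol_jitter(Rc, cur.C, P.jitter_rel * s.gamma,
                     JITTER_MAX_REL * s.gamma))
      Rcpp::stop("Cholesky of the kernel failed after jitter escalation");
    vec z1(n), z2(n);
    for (uword i = 0; i < n; ++i) z1[i] = norm_rand();
    for (uword i = 0; i < n; ++i) z2[i] = norm_rand();
    const vec f = Rc.t() * z1;
    const vec eps = sqrt(cur.et) % z2;
    const vec h = f + eps;
    s.eta = mu + eps - cur.et %
        solve(trimatu(R), solve(trimatl(R.t()), h, solve_opts::fast),
              solve_opts::fast);
  }

  // ---- latent ALD scales: GIG(1/2, (y-alpha-eta)^2/(2 sigma), 1/(2 sigma))
  if (!P.gaussian) {
    const double psi = 1.0 / (2.0 * s.sigma);
    for (uword m = 0; m < M; ++m)
      for (uword i = 0; i < n; ++i) {
        const double u = s.Y(i, m) - s.alpha[m] - s.eta[i];
        s.e(i, m) = rgig_half(u * u / (2.0 * s.sigma), psi);
      }
  }

  // ---- ALD scale sigma: inverse gamma
  {
    double rate = 0.5 * dot(s.beta, s.beta) + P.b_sigma;
    for (uword m = 0; m < M; ++m) {
      const double shift = 1.0 - 2.0 * P.taus[m];
      const double tt = P.taus[m] * (1.0 - P.taus[m]);
      for (uword i = 0; i < n; ++i) {
        const double zim = s.Y(i, m) - s.alpha[m] - shift * s.e(i, m);
        const double r = zim - s.eta[i];
        rate += r * r / (4.0 * s.e(i, m));
        if (!P.gaussian) rate += tt * s.e(i, m);
      }
    }
    // likelihood contributes Mn/2, the latent-scale prior's sigma^{-Mn}
    // normalization contributes Mn, the index prior p/2 (absent terms drop
    // under the Gaussian baseline where e is fixed, not latent)
    const double shape = (P.gaussian ? 0.5 : 1.5) * (double)(n * M)
        + 0.5 * (double)p + P.a_sigma;
    if (!std::isfinite(rate))
      Rcpp::stop("non-finite rate in the sigma conditional: sigma=%g gamma=%g max|eta|=%g min_e=%g max_e=%g",
                 s.sigma, s.gamma, abs(s.eta).max(), s.e.min(), s.e.max());
    s.sigma = 1.0 / R::rgamma(shape, 1.0 / rate);
  }

  if (redraw_y) {
    for (uword m = 0; m < M; ++m) {
      const double shift = 1.0 - 2.0 * P.taus[m];
      for (uword i = 0; i < n; ++i) {
        const double sd = std::sqrt(2.0 * s.sigma * s.e(i, m));
        s.Y(i, m) = s.alpha[m] + s.eta[i] + shift * s.e(i, m) + sd * norm_rand();
      }
    }
  }
}

// Robbins-Monro log-scale adaptation step (burn-in only).
static double adapt_step(double scale, bool accepted, int t, double target) {
  const double step = 1.0 / std::pow(static_cast<double>(t), 0.6);
  return scale * std::exp(step * ((accepted ? 1.0 : 0.0) - target));
}

// [[Rcpp::export]]
Rcpp::List run_mcmc_cpp(const arma::mat& X, const arma::mat& Y,
                        const arma::vec& taus, double a_sigma, double b_sigma,
                        double a_gamma, double b_gamma,
                        double alpha_prior_var, bool gaussian, int n_iter,
                        int n_burnin, int thin, double ps_beta,
                        double ps_alpha, double ps_gamma, bool adapt,
                        double accept_target, const arma::vec& beta0,
                        const arma::vec& alpha0, const arma::mat& e0,
                        double sigma0, double gamma0, double jitter_rel,
                        bool per_m_alpha, bool update_gamma) {
  const uword n = Y.n_rows, M = Y.n_cols, p = X.n_cols;
  Pars P{X,       taus,     a_sigma,    b_sigma,     a_gamma, b_gamma,
         alpha_prior_var, gaussian, jitter_rel, per_m_alpha, update_gamma};

  State s;
  s.beta = beta0;
  s.alpha = alpha0;
  s.e = e0;
  s.sigma = sigma0;
  s.gamma = gamma0;
  s.eta = zeros<vec>(n);
  s.Y = Y;

  {
    const double A0 = logA_core(X, Y, s.beta, s.alpha, s.e, s.gamma, s.sigma,
                                taus, jitter_rel);
    if (!std::isfinite(A0)) {
      Rcpp::Rcout << "initial state: sigma=" << s.sigma
                  << " gamma=" << s.gamma << " beta=" << s.beta.t();
      Rcpp::stop("non-finite log target at initialization");
    }
  }

  double sc_b = ps_beta, sc_a = ps_alpha, sc_g = ps_gamma;
  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  mat beta_d(n_keep, p), alpha_d(n_keep, M), eta_d(n_keep, n);
  vec sigma_d(n_keep), gamma_d(n_keep);

  Acc post;          // post-burn-in acceptance
  int post_iters = 0;
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    Acc a1;
    sweep(s, P, sc_b, sc_a, sc_g, a1, false);
    if (t <= n_burnin) {
      if (adapt) {
        sc_b = adapt_step(sc_b, a1.b > 0.5, t, accept_target);
        sc_a = adapt_step(sc_a, a1.a > 0.5, t, accept_target);
        if (update_gamma) sc_g = adapt_step(sc_g, a1.g > 0.5, t, accept_target);
      }
    } else {
      post.b += a1.b;
      post.a += a1.a;
      post.g += a1.g;
      ++post_iters;
      if ((t - n_burnin - 1) % thin == 0 && kept < n_keep) {
        beta_d.row(kept) = s.beta.t();
        alpha_d.row(kept) = s.alpha.t();
        eta_d.row(kept) = s.eta.t();
        sigma_d[kept] = s.sigma;
        gamma_d[kept] = s.gamma;
        ++kept;
      }
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  const double denom = std::max(post_iters, 1);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_d.rows(0, kept - 1),
      Rcpp::Named("alpha") = alpha_d.rows(0, kept - 1),
      Rcpp::Named("sigma") = sigma_d.subvec(0, kept - 1),
      Rcpp::Named("gamma") = gamma_d.subvec(0, kept - 1),
      Rcpp::Named("eta") = eta_d.rows(0, kept - 1),
      Rcpp::Named("accept") = Rcpp::NumericVector::create(
          Rcpp::Named("beta") = post.b / denom,
          Rcpp::Named("alpha") = post.a / denom,
          Rcpp::Named("gamma") = post.g / denom),
      Rcpp::Named("scales") = Rcpp::NumericVector::create(
          Rcpp::Named("beta") = sc_b, Rcpp::Named("alpha") = sc_a,
          Rcpp::Named("gamma") = sc_g));
}

// Successive-conditional simulator for the getting-it-right check: the same
// sweep with the data matrix redrawn from the mixture representation after
// every parameter pass. Records (sigma, gamma, beta_1) per sweep.
// [[Rcpp::export]]
arma::mat geweke_cpp(const arma::mat& X, const arma::vec& taus, double a_sigma,
                     double b_sigma, double a_gamma, double b_gamma,
                     double alpha_prior_var, int n_sweep, double ps_beta,
                     double ps_alpha, double ps_gamma, const arma::vec& beta0,
                     const arma::vec& alpha0, const arma::mat& e0,
                     double sigma0, double gamma0, const arma::mat& Y0,
                     double jitter_rel) {
  Pars P{X,       taus,  a_sigma,    b_sigma, a_gamma, b_gamma,
         alpha_prior_var, false, jitter_rel, false,   true};
  State s;
  s.beta = beta0;
  s.alpha = alpha0;
  s.e = e0;
  s.sigma = sigma0;
  s.gamma = gamma0;
  s.eta = zeros<vec>(Y0.n_rows);
  s.Y = Y0;

  mat rec(n_sweep, 3);
  for (int t = 1; t <= n_sweep; ++t) {
    Acc a1;
    sweep(s, P, ps_beta, ps_alpha, ps_gamma, a1, true);
    rec(t - 1, 0) = s.sigma;
    rec(t - 1, 1) = s.gamma;
    rec(t - 1, 2) = s.beta[0];
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return rec;
}

// GP conditional mean of the link at new projection points, per stored draw.
// grid: either fixed index values (grid_is_projection = true) or rows of a
// new design matrix projected through each draw's beta.
// [[Rcpp::export]]
arma::mat link_cond_cpp(const arma::mat& X, const arma::mat& beta_draws,
                        const arma::vec& gamma_draws,
                        const arma::mat& eta_draws, const arma::mat& Xnew,
                        bool grid_is_projection, double jitter_rel) {
  const uword S = beta_draws.n_rows;
  const uword G = grid_is_projection ? Xnew.n_elem : Xnew.n_rows;
  mat out(S, G);
  for (uword sdx = 0; sdx < S; ++sdx) {
    const vec beta = beta_draws.row(sdx).t();
    const double gamma = gamma_draws[sdx];
    const vec proj = X * beta;
    vec pnew;
    if (grid_is_projection)
      pnew = vectorise(Xnew);
    else
      pnew = Xnew * beta;
    mat C = kernel_build(proj, gamma);
    mat R;
    if (!chol_jitter(R, C, std::max(jitter_rel, 1e-8) * gamma,
                     JITTER_MAX_REL * gamma))
      Rcpp::stop("Cholesky of the training kernel failed");
    const vec eta = eta_draws.row(sdx).t();
    const vec w = solve(trimatu(R), solve(trimatl(R.t()), eta, solve_opts::fast), solve_opts::fast);
    for (uword g = 0; g < G; ++g) {
      double acc = 0.0;
      for (uword i = 0; i < proj.n_elem; ++i) {
        const double d = pnew[g] - proj[i];
        acc += gamma * std::exp(-d * d) * w[i];
      }
      out(sdx, g) = acc;
    }
    if (sdx % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
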