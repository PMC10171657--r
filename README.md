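# bcqr — Bayesian composite quantile regression for single-index models

`bcqr` fits the single-index model

    y = η(xᵀβ) + ε

when neither the link function η nor the index vector β is known, by
**Bayesian composite quantile regression (BCQR)**: the check losses
ρ_τ(t) = t(τ − I(t<0)) of an equispaced grid of quantile levels
τ_m = m/(M+1) are pooled into one objective with a shared index and link
and level-specific intercepts α_m. The objective is exponentiated into an
asymmetric-Laplace working likelihood, whose normal–exponential mixture
representation, combined with a Gaussian-process prior on η evaluated at
the projected indices (kernel C(x_i, x_j) = γ·exp{−(x_iᵀβ − x_jᵀβ)²};
the free norm of β absorbs the bandwidth), turns posterior simulation into
a partially collapsed Metropolis-within-Gibbs sampler: β, α and log γ are
updated against targets with η analytically integrated out, then η, the
latent ALD scales (generalized inverse Gaussian) and the ALD scale σ
(inverse gamma) are redrawn exactly.

Pooling quantile levels keeps the index estimate efficient under
heavy-tailed, skewed or bimodal errors, where mean regression loses
accuracy and a single quantile loses efficiency. The intended users are
statisticians and epidemiologists fitting semiparametric index models on
small-to-medium tabular data (tens to a few hundred observations).

The package provides:

* `bcqr()`, `bqr()`, `blr()` — composite, single-quantile (M = 1,
  τ = 0.5, same code path) and Gaussian-likelihood baselines, all on the
  same GP single-index hierarchy, with burn-in proposal adaptation to a
  10–30% acceptance band;
* `normalize_beta()` — identifiability normalization (unit norm, positive
  first component) with equal-tailed credible intervals and CI lengths;
* `estimate_link()`, `predict()`, `mape()` — posterior link curve with
  pointwise credible bands, out-of-sample prediction, prediction error;
* `sim_design()`, `generate_example()`, `run_study()` — the three
  synthetic single-index designs with four error laws and the replicated
  bias/SD comparison engine;
* `read_dataset()`, `write_chain()`, plus a command-line wrapper
  (`inst/cli/bcqr.R`) with `fit`, `simulate` and `predict` subcommands;
* low-level building blocks (`check_loss`, `dald`, `rgig`,
  `collapsed_logdensity`, `eta_full_conditional`, …) for scrutiny and
  testing.

The numerical core is RcppArmadillo; one 100-observation, M = 9 chain runs
at roughly 0.7 ms per iteration on a single CPU.

## Worked example

```r
library(bcqr)

# one replication of simulation example 2: eta(t) = t^2 exp(t),
# beta = (1,2)/sqrt(5), x uniform on [-1,1]^2, noise 0.2 * N(0,1)
d <- generate_example(sim_design(example = 2, n = 100, reps = 1,
                                 base_seed = 301), 1)
fit <- bcqr(d$X, d$y, M = 5,
            control = sampler_control(n_iter = 8000, n_burnin = 4000,
                                      seed = 302))
summary(fit)
```

```
BCQR5: normalized index estimates (unit norm, first component positive)
   estimate ci_lower ci_upper ci_length
x1   0.4476   0.4043   0.4900    0.0857
x2   0.8943   0.8717   0.9146    0.0429
posterior median sigma 0.07661, gamma 1.749e+06
```

The `estimate` column is the posterior-mean index after normalization —
the truth here is (0.4472, 0.8944), inside both intervals; `ci_length` is
the efficiency measure used to compare methods (shorter is better at the
same coverage). The very large kernel amplitude γ is not pathological: the
free norm of β trades off against γ, and every identified quantity
(normalized index, fitted curve, predictions) is stable. Acceptance rates
after adaptation sit inside the 10–30% band:

```r
fit$accept
#>    beta   alpha   gamma
#> 0.22425 0.17725 0.20450
```

From the shell, the same machinery:

```sh
Rscript inst/cli/bcqr.R fit --data data.csv --response y \
    --covariates x1,x2 --model bcqr --M 5 --seed 1 --out fit_out
Rscript inst/cli/bcqr.R predict --fit-dir fit_out --newdata new.csv \
    --response y --out pred.csv
```

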