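# mimstd — marginal treatment effects by multiple imputation marginalization

`mimstd` estimates **marginal treatment effects in a target covariate
distribution** from patient-level data of a comparative "index" study
(covariates `x`, binary treatment `t`, binary outcome `y`) plus a
covariate-only dataset describing the target population. This is the
standardization problem of transportability analyses and
population-adjusted indirect treatment comparisons: because the (log)
odds ratio is non-collapsible, the treatment coefficient of a
covariate-adjusted outcome model is a *conditional* effect, and the
population-level *marginal* effect must be obtained by averaging the
fitted model over the target covariate distribution.

The package implements two routes:

* **Multiple imputation marginalization (MIM)** — the core method. Target
  outcomes are treated as missing data. Stage 1 (*synthesis*): a Bayesian
  first-stage regression
  `g(mu) = beta0 + x*beta1 + (beta_t + x*beta2)*1(t=1)` is fitted to the
  index study; the target covariates are stacked twice (once under each
  treatment, `N* = 2*N_tar` rows) and `M` complete outcome vectors are
  drawn from the posterior predictive distribution, one per retained
  posterior draw. Stage 2 (*analysis*): each synthesis is analysed with
  the marginal model `g(eta) = alpha + delta*t`, and the `M` estimates
  are pooled with the combining rules for fully synthetic data,

  ```
  estimate  = mean(delta_m)
  variance  = (1 + 1/M) * b - v_bar     # b = between, v_bar = within
  intervals : t distribution with nu_f = (M-1) * (1 + v_bar/((1+1/M)*b))^2
  ```

  (note the within variance is *subtracted*, unlike Rubin's rules),
  or by posterior simulation of the marginal effect's posterior.
* **Standard model-based standardization** — maximum-likelihood
  G-computation with ordinary non-parametric bootstrap inference
  (percentile intervals), the usual comparator.

A data-generating-process simulator (correlated Gaussian covariates,
logistic outcomes, a `kappa` overlap parameter shifting the target
distribution) and a benchmark harness (bias / ESE / MSE / coverage with
Monte Carlo standard errors over replicated simulations) round out the
package.

## Worked example

```r
library(mimstd)

cfg    <- dgp_config(n_index = 1000, kappa = 1, seed = 42)
trial  <- simulate_index_trial(cfg)        # index RCT: x, t, y
target <- simulate_target_covariates(cfg)  # external target: x only

mim <- mim_estimate(trial, target, outcome_model_spec(), seed = 3)
mim
#> Pooled marginal treatment effect (MIM)
#>   estimate -0.8850, variance 0.01812 (combining_rules, M = 1000)
#>   95% interval (-1.1490, -0.6209), dof 1426.6

gc <- bootstrap_gcomp(trial, target, n_boot = 1000, seed = 3)
gc
#> Marginal treatment effect (ML G-computation + bootstrap)
#>   estimate -0.8888 (original-sample -0.8844), SE 0.1402
#>   95% percentile interval (-1.1682, -0.6142), 1000 resamples

simulate_true_estimand(cfg, cohort_size = 2e6)$marginal_log_or
#> [1] -0.8101
```

Both estimators target the marginal log odds ratio in the target
population (true value about −0.81 under full overlap: the conditional
log odds ratio of −1.5 is attenuated by non-collapsibility). On this
replicate both land near −0.89 with almost identical uncertainty — one
draw from a sampling distribution whose spread (ESE ≈ 0.14 at
N = 1000) the benchmark harness quantifies.

A command-line wrapper is installed at
`system.file("cli", "mim.R", package = "mimstd")` with subcommands
`simulate`, `run`, `gcomp`, `benchmark` and `truth` operating on CSV
files (`x1..xK[, trt, y]`) and emitting JSON.

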