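# Shared fixtures and independent oracles for the test suite.

# Independent multivariate-normal sampler (Cholesky by hand), used as an
# oracle so tests of the package's covariate generator do not depend on it.
oracle_mvn <- function(n, means, sds, corr) {
  K <- length(means)
  R <- matrix(corr, K, K); diag(R) <- 1
  Sigma <- diag(sds, K) %*% R %*% diag(sds, K)
  Z <- matrix(rnorm(n * K), n, K)
  sweep(Z %*% chol(Sigma), 2, means, "+")
}

# Brute-force arm-wise event rate under the true logistic model for a
# given covariate distribution (averages plogis over a large draw).
oracle_event_rate <- function(cfg, treated, n = 1e6,
                              means = cfg$cov_means, sds = cfg$cov_sds) {
  x <- oracle_mvn(n, means, sds, cfg$cov_corr)
  eta <- cfg$beta0 + drop(x %*% cfg$beta1)
  if (treated) eta <- eta + cfg$beta_t + drop(x %*% cfg$beta2)
  mean(plogis(eta))
}

# Small complete trial fixture with exact cell counts per arm:
# treated n1 with e1 events, control n0 with e0 events.
fixture_two_by_two <- function(n1, e1, n0, e0) {
  list(
    outcomes = c(rep(1L, e1), rep(0L, n1 - e1),
                 rep(1L, e0), rep(0L, n0 - e0)),
    treatment = rep(c(1L, 0L), c(n1, n0))
  )
}

# Point-mass "posterior": every draw equals beta (used to isolate the
# posterior-predictive sampling step from the MCMC fit).
fixture_point_posterior <- function(beta, L, spec = outcome_model_spec()) {
  structure(
    list(draws = matrix(beta, L, length(beta), byrow = TRUE),
         diagnostics = list(), spec = spec, warnings = character(0),
         L = L),
    class = "mim_posterior"
  )
}

scaled_model_spec <- function(m = 100, ...) {
  outcome_model_spec(post_warmup_iters_per_chain = 2L * m,
                     warmup_iters = 2L * m, thin = 4, ...)
}
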