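#' Marginal second-stage regression on one synthesis
#'
#' Fits the marginal ("analysis") model `g(eta_j) = alpha + delta * t_j` to
#' one synthetic dataset by maximum likelihood and returns the treatment
#' coefficient and its estimated sampling variance. The model deliberately
#' contains treatment and intercept only: congeniality with the
#' first-stage regression holds because treatment already appears there.
#'
#' For the logit link the MLE has the 2x2-table closed form
#' `delta = logit(pbar1) - logit(pbar0)` with variance equal to the sum of
#' reciprocal cell counts, which is used directly (it is the exact MLE);
#' identity and log links are fitted iteratively via [stats::glm()].
#'
#' @param outcomes Length-N* outcome vector (0/1 for the logit link).
#' @param treatment Length-N* 0/1 treatment vector.
#' @param link Link function.
#' @return A list with `delta_hat` and `v_hat`.
#' @export
fit_second_stage <- function(outcomes, treatment,
                             link = c("logit", "identity", "log")) {
  link <- match.arg(link)
  if (length(outcomes) != length(treatment)) {
    stop_mim("mim_input_error", "outcomes and treatment lengths disagree")
  }
  if (!all(treatment %in% c(0, 1)) || !any(treatment == 1) ||
      !any(treatment == 0)) {
    stop_mim("mim_input_error", "both treatment arms must be non-empty")
  }
  if (link == "logit") {
    if (!all(outcomes %in% c(0, 1))) {
      stop_mim("mim_input_error", "outcomes must be binary for logit link")
    }
    n1 <- sum(treatment == 1)
    n0 <- sum(treatment == 0)
    e1 <- sum(outcomes[treatment == 1])
    e0 <- sum(outcomes[treatment == 0])
    cells <- c(e1, n1 - e1, e0, n0 - e0)
    if (any(cells == 0)) {
      stop_mim("mim_separation_error",
               "empty 2x2 cell: second-stage logistic fit is separated",
               cells = cells)
    }
    delta <- log(e1 / (n1 - e1)) - log(e0 / (n0 - e0))
    v <- sum(1 / cells)
    return(list(delta_hat = delta, v_hat = v))
  }
  fam <- switch(link,
    identity = stats::gaussian(),
    log = stats::poisson(link = "log")
  )
  fit <- stats::glm(outcomes ~ treatment, family = fam)
  if (!fit$converged) {
    stop_mim("mim_separation_error", "second-stage fit did not converge")
  }
  list(delta_hat = unname(stats::coef(fit)["treatment"]),
       v_hat = unname(stats::vcov(fit)["treatment", "treatment"]))
}

# Vectorized logit-link second stage across all M syntheses; returns a
# data.frame with one row per synthesis and a `separated` flag.
second_stage_all <- function(outcomes, treatment) {
  t1 <- treatment == 1
  n1 <- sum(t1)
  n0 <- sum(!t1)
  e1 <- rowSums(outcomes[, t1, drop = FALSE])
  e0 <- rowSums(outcomes[, !t1, drop = FALSE])
  separated <- e1 == 0 | e1 == n1 | e0 == 0 | e0 == n0
  delta <- log(e1 / (n1 - e1)) - log(e0 / (n0 - e0))
  v <- 1 / e1 + 1 / (n1 - e1) + 1 / e0 + 1 / (n0 - e0)
  data.frame(delta_hat = delta, v_hat = v, separated = separated)
}

#' Pooling quantities across syntheses
#'
#' Computes the three summaries that drive all pooling: the mean
#' `delta_bar` of the per-synthesis effect estimates, the mean `v_bar` of
#' their estimated variances (the "within" variance), and the sample
#' variance `b` of the estimates (the "between" variance, divisor M - 1).
#'
#' @param estimates Either a list of `fit_second_stage()` results or a
#'   data.frame with columns `delta_hat` and `v_hat`.
#' @return An object of class `mim_pooling_summary` with `delta_bar`,
#'   `v_bar`, `b` and `M`.
#' @export
pool_quantities <- function(estimates) {
  if (is.data.frame(estimates)) {
    d <- estimates$delta_hat
    v <- estimates$v_hat
  } else {
    d <- vapply(estimates, `[[`, numeric(1), "delta_hat")
    v <- vapply(estimates, `[[`, numeric(1), "v_hat")
  }
  M <- length(d)
  if (M < 2) {
    stop_mim("mim_input_error",
             "at least 2 syntheses are required (between variance undefined)")
  }
  structure(
    list(delta_bar = mean(d), v_bar = mean(v), b = stats::var(d),
         M = as.integer(M)),
    class = "mim_pooling_summary"
  )
}

#' Pool synthesis estimates via combining rules
#'
#' Closed-form pooling for fully synthetic data: the point estimate is the
#' mean of the per-synthesis estimates and its variance is
#' `(1 + 1/M) * b - v_bar`. Note the within variance is *subtracted* —
#' unlike Rubin's rules for conventional multiple imputation — because
#' every analysed outcome is synthesized. Interval estimates use a
#' t-distribution with
#' `nu_f = (M - 1) * (1 + v_bar / ((1 + 1/M) * b))^2` degrees of freedom.
#'
#' The variance formula is a method-of-moments expression and can go
#' negative when `(1 + 1/M) * b < v_bar`; this is an error by default
#' (remedy: increase M and/or the synthesis size). With
#' `on_negative_variance = "fallback"` the variance is widened to
#' `(1 + 1/M) * b` and a warning recorded instead.
#'
#' @param summary An `mim_pooling_summary` from [pool_quantities()].
#' @param level Interval level (default 0.95).
#' @param on_negative_variance `"error"` (default) or `"fallback"`.
#' @return An object of class `mim_pooled_effect`.
#' @export
pool_combining_rules <- function(summary, level = 0.95,
                                 on_negative_variance = c("error",
                                                          "fallback")) {
  stopifnot(inherits(summary, "mim_pooling_summary"),
            level > 0, level < 1)
  on_negative_variance <- match.arg(on_negative_variance)
  M <- summary$M
  b <- summary$b
  v_bar <- summary$v_bar
  estimate <- summary$delta_bar
  variance <- (1 + 1 / M) * b - v_bar
  warnings <- character(0)
  if (variance <= 0) {
    if (on_negative_variance == "error") {
      stop_mim("mim_negative_variance_error", sprintf(
        paste("combining-rule variance is non-positive (%.3g);",
              "increase M and/or the synthesis size"), variance),
        variance = variance)
    }
    warnings <- c(warnings, sprintf(
      "non-positive combining-rule variance (%.3g); widened to (1+1/M)*b",
      variance))
    warning(warnings[length(warnings)], call. = FALSE)
    variance <- (1 + 1 / M) * b
  }
  dof <- (M - 1) * (1 + v_bar / ((1 + 1 / M) * b))^2
  half <- stats::qt((1 + level) / 2, df = dof) * sqrt(variance)
  structure(
    list(estimate = estimate, variance = variance, dof = dof,
         interval = c(lower = estimate - half, upper = estimate + half),
         level = level, method = "combining_rules", M = M,
         pooling_summary = summary, draws = NULL, warnings = warnings),
    class = "mim_pooled_effect"
  )
}

#' Pool synthesis estimates via posterior simulation
#'
#' Monte Carlo approximation of the posterior of the marginal effect given
#' the syntheses. Per draw: `mu ~ Normal(delta_bar, v_bar / M)`;
#' `chi ~ chi-squared(M - 1)` defines `sigma2 = (M - 1) * b / chi - v_bar`;
#' then `Delta ~ t_{M-1}(mu, (1 + 1/M) * sigma2)` (location-scale, scale
#' squared given). Draws with `sigma2 < 0` cannot be completed and are
#' flagged and dropped; if their fraction exceeds `flag_threshold` a
#' negative-variance-prone warning is attached.
#'
#' @param summary An `mim_pooling_summary`.
#' @param n_draws Number of posterior draws (>= 1e4 recommended).
#' @param seed Integer seed.
#' @param level Interval level; interval endpoints are empirical
#'   quantiles of the draws.
#' @param flag_threshold Maximum tolerated fraction of negative-variance
#'   draws before a warning is raised (default 0.01).
#' @return An object of class `mim_pooled_effect` with the retained
#'   posterior draws in `$draws`.
#' @export
pool_posterior_simulation <- function(summary, n_draws = 1e4, seed = 1,
                                      level = 0.95, flag_threshold = 0.01) {
  stopifnot(inherits(summary, "mim_pooling_summary"),
            n_draws >= 2, level > 0, level < 1)
  M <- summary$M
  set.seed(seed)
  mu <- stats::rnorm(n_draws, summary$delta_bar, sqrt(summary$v_bar / M))
  chi <- stats::rchisq(n_draws, df = M - 1)
  sigma2 <- (M - 1) * summary$b / chi - summary$v_bar
  flagged <- sigma2 < 0
  warnings <- character(0)
  if (mean(flagged) > flag_threshold) {
    warnings <- c(warnings, sprintf(
      "negative-variance-prone pooling: %.1f%% of draws flagged",
      100 * mean(flagged)))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  keep <- !flagged
  delta <- mu[keep] +
    stats::rt(sum(keep), df = M - 1) * sqrt((1 + 1 / M) * sigma2[keep])
  qs <- stats::quantile(delta, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  structure(
    list(estimate = mean(delta), variance = stats::var(delta),
         dof = M - 1,
         interval = c(lower = qs[1], upper = qs[2]),
         level = level, method = "posterior_simulation", M = M,
         pooling_summary = summary, draws = delta,
         n_flagged = sum(flagged), warnings = warnings),
    class = "mim_pooled_effect"
  )
}

#' Multiple imputation marginalization, end to end
#'
#' Runs the full MIM pipeline: Bayesian first-stage fit on the index
#' study, augmentation of the target covariates, posterior predictive
#' synthesis of M outcome datasets, marginal second-stage fit on each
#' synthesis, and pooling. Syntheses whose second-stage fit is separated
#' (an empty 2x2 cell) are skipped and counted; more than
#' `max_skip_fraction` skipped is a hard error since pooling would be
#' unreliable.
#'
#' @param data An `mim_trial` index-study dataset.
#' @param target An `mim_target` covariate set with the same K covariates.
#' @param spec An [outcome_model_spec()].
#' @param pooling `"combining_rules"` (default) or
#'   `"posterior_simulation"`.
#' @param seed Integer seed; MCMC and synthesis use independent
#'   substreams.
#' @param level Interval level.
#' @param n_draws Posterior draws for the posterior-simulation pooling
#'   route.
#' @param max_skip_fraction Hard-error threshold on the fraction of
#'   separation-skipped syntheses (default 0.05).
#' @param on_negative_variance Passed to [pool_combining_rules()].
#' @return An `mim_pooled_effect` with extra fields `n_skipped`,
#'   `diagnostics` (first-stage) and accumulated `warnings`.
#' @examples
#' \donttest{
#' cfg <- dgp_config(n_index = 500, kappa = 1, seed = 7)
#' trial <- simulate_index_trial(cfg)
#' target <- simulate_target_covariates(cfg)
#' spec <- outcome_model_spec(post_warmup_iters_per_chain = 200,
#'                            warmup_iters = 200)
#' mim_estimate(trial, target, spec, seed = 7)
#' }
#' @export
mim_estimate <- function(data, target, spec = outcome_model_spec(),
                         pooling = c("combining_rules",
                                     "posterior_simulation"),
                         seed = 1, level = 0.95, n_draws = 1e4,
                         max_skip_fraction = 0.05,
                         on_negative_variance = c("error", "fallback")) {
  pooling <- match.arg(pooling)
  if (ncol(data$covariates) != ncol(target$covariates)) {
    stop_mim("mim_input_error",
             "index and target must share the same covariates")
  }
  posterior <- fit_first_stage(data, spec, seed = seed_stream(seed, "mcmc"))
  design <- augment_target(target)
  syn <- draw_synthetic_outcomes(posterior, design, spec,
                                 seed = seed_stream(seed, "synthesis"))
  ests <- second_stage_all(syn$outcomes, design$treatment)
  n_skipped <- sum(ests$separated)
  if (n_skipped > max_skip_fraction * nrow(ests)) {
    stop_mim("mim_separation_error", sprintf(
      "%d of %d syntheses separated (> %.0f%%): pooling unreliable",
      n_skipped, nrow(ests), 100 * max_skip_fraction))
  }
  summary <- pool_quantities(ests[!ests$separated, , drop = FALSE])
  pooled <- switch(pooling,
    combining_rules = pool_combining_rules(
      summary, level = level,
      on_negative_variance = match.arg(on_negative_variance)),
    posterior_simulation = pool_posterior_simulation(
      summary, n_draws = n_draws, seed = seed_stream(seed, "pooling"),
      level = level)
  )
  pooled$n_skipped <- n_skipped
  pooled$diagnostics <- posterior$diagnostics
  pooled$warnings <- c(posterior$warnings, pooled$warnings)
  pooled$seed <- seed
  pooled
}

#' @export
print.mim_pooled_effect <- function(x, ...) {
  cat("Pooled marginal treatment effect (MIM)\n")
  cat(sprintf("  estimate %.4f, variance %.5f (%s, M = %d)\n",
              x$estimate, x$variance, x$method, x$M))
  cat(sprintf("  %.0f%% interval (%.4f, %.4f), dof %.1f\n",
              100 * x$level, x$interval[1], x$interval[2], x$dof))
  if (!is.null(x$n_skipped) && x$n_skipped > 0) {
    cat(sprintf("  %d syntheses skipped for separation\n", x$n_skipped))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
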