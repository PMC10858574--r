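#' Specify one simulation scenario
#'
#' A scenario is one cell of the benchmark's factorial design: an index
#' trial size, an overlap level, a replicate count and estimator settings.
#' The full-fidelity design crosses `n_index` in {500, 1000, 2000} with
#' `kappa` in {0.5, 1} at `n_sim = 1000`, `m_syntheses = 1000` and
#' `n_boot = 1000`; scaled-down profiles reduce those three counts and
#' widen tolerances through the reported Monte Carlo standard errors.
#'
#' @param n_index Index trial size.
#' @param kappa Overlap proxy in (0, 1].
#' @param n_sim Number of simulation replicates.
#' @param estimators Subset of `c("mim", "gcomp")`.
#' @param base_seed Integer seed; replicate r uses a substream keyed by
#'   `(base_seed, r)`, so reruns are reproducible and both estimators see
#'   identical replicate datasets.
#' @param m_syntheses Number of MIM syntheses M (chains = 2, thin = 4;
#'   post-warmup iterations per chain are set to `2 * m_syntheses`).
#' @param n_boot Bootstrap resamples for the G-computation comparator.
#' @param level Interval level.
#' @param dgp Named list of [dgp_config()] overrides.
#' @param redraw_target Redraw the target covariate set each replicate
#'   (default `FALSE`: one draw per scenario, held fixed, since inference
#'   treats the target covariates as fixed).
#' @param truth_cohort Cohort size for the true-estimand simulation.
#' @return An object of class `mim_scenario`.
#' @export
scenario_spec <- function(n_index = 1000, kappa = 1, n_sim = 1000,
                          estimators = c("mim", "gcomp"), base_seed = 1,
                          m_syntheses = 1000, n_boot = 1000, level = 0.95,
                          dgp = list(), redraw_target = FALSE,
                          truth_cohort = 2e6) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (n_sim < 2) stop_mim("mim_config_error", "n_sim must be >= 2")
  structure(
    list(n_index = as.integer(n_index), kappa = kappa,
         n_sim = as.integer(n_sim), estimators = estimators,
         base_seed = as.integer(base_seed),
         m_syntheses = as.integer(m_syntheses),
         n_boot = as.integer(n_boot), level = level, dgp = dgp,
         redraw_target = isTRUE(redraw_target),
         truth_cohort = truth_cohort),
    class = "mim_scenario"
  )
}

#' Run one benchmark scenario
#'
#' Computes the true marginal estimand once per scenario by large-cohort
#' simulation, draws one fixed target covariate set (unless
#' `redraw_target`), then for each replicate simulates a fresh index
#' trial and applies every requested estimator to the identical data
#' (paired comparison). Replicates on which an estimator fails are
#' excluded from that scenario and counted in `n_sim_effective`.
#'
#' @param spec An [scenario_spec()] object.
#' @param verbose Print per-replicate progress.
#' @return An object of class `mim_performance`: `summary` (one row per
#'   estimator with bias/ESE/MSE/coverage and their MCSEs), `replicates`
#'   (long-format per-replicate results), `truth`, `n_failed`.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "mim_scenario"))
  cfg_args <- utils::modifyList(
    list(n_index = spec$n_index, kappa = spec$kappa,
         seed = seed_stream(spec$base_seed, "scenario")),
    spec$dgp)
  base_cfg <- do.call(dgp_config, cfg_args)
  truth <- simulate_true_estimand(base_cfg, cohort_size = spec$truth_cohort)

  model_spec <- outcome_model_spec(
    chains = 2,
    post_warmup_iters_per_chain = 2L * spec$m_syntheses,
    warmup_iters = 2L * spec$m_syntheses,
    thin = 4)

  target <- simulate_target_covariates(base_cfg)
  rows <- list()
  n_failed <- stats::setNames(integer(length(spec$estimators)),
                              spec$estimators)
  for (r in seq_len(spec$n_sim)) {
    cfg <- base_cfg
    cfg$seed <- seed_stream(spec$base_seed, "replicate", r)
    trial <- simulate_index_trial(cfg)
    if (spec$redraw_target) {
      target <- simulate_target_covariates(cfg)
    }
    for (est in spec$estimators) {
      res <- tryCatch({
        if (est == "mim") {
          fit <- suppressWarnings(
            mim_estimate(trial, target, model_spec,
                         seed = seed_stream(spec$base_seed, "mim", r),
                         level = spec$level))
          data.frame(replicate = r, estimator = "mim",
                     estimate = fit$estimate, se = sqrt(fit$variance),
                     lower = fit$interval[1], upper = fit$interval[2])
        } else {
          fit <- bootstrap_gcomp(trial, target, n_boot = spec$n_boot,
                                 seed = seed_stream(spec$base_seed,
                                                    "gcomp", r),
                                 level = spec$level)
          data.frame(replicate = r, estimator = "gcomp",
                     estimate = fit$estimate, se = fit$se,
                     lower = fit$interval[1], upper = fit$interval[2])
        }
      }, mim_error = function(e) NULL)
      if (is.null(res)) {
        n_failed[est] <- n_failed[est] + 1L
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
    if (verbose && r %% 10 == 0) {
      message(sprintf("replicate %d / %d", r, spec$n_sim))
    }
  }
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  summary <- do.call(rbind, lapply(spec$estimators, function(est) {
    d <- replicates[replicates$estimator == est, , drop = FALSE]
    cbind(data.frame(estimator = est),
          compute_metrics(d$estimate, d$lower, d$upper,
                          truth$marginal_log_or))
  }))
  structure(
    list(spec = spec, truth = truth$marginal_log_or,
         truth_detail = truth, summary = summary,
         replicates = replicates, n_failed = n_failed),
    class = "mim_performance"
  )
}

#' Performance metrics with Monte Carlo standard errors
#'
#' Aggregates per-replicate estimates and interval endpoints into the four
#' benchmark metrics: bias (mean estimate minus truth), empirical standard
#' error (standard deviation of estimates, divisor n - 1), mean square
#' error (plain mean of squared errors) and empirical coverage of the
#' intervals. Each metric is paired with its Monte Carlo standard error:
#' `MCSE(bias) = ESE / sqrt(n)`, `MCSE(ESE) = ESE / sqrt(2 (n - 1))`,
#' `MCSE(MSE) = sd((est - truth)^2) / sqrt(n)` and
#' `MCSE(coverage) = sqrt(coverage (1 - coverage) / n)`.
#'
#' @param estimates Per-replicate point estimates.
#' @param lower,upper Per-replicate interval endpoints.
#' @param truth True value of the estimand.
#' @return A one-row data.frame with the metrics, their MCSEs, `truth`
#'   and `n_sim_effective`.
#' @export
compute_metrics <- function(estimates, lower, upper, truth) {
  n <- length(estimates)
  if (n < 2) stop_mim("mim_input_error", "need >= 2 replicates")
  err <- estimates - truth
  ese <- stats::sd(estimates)
  mse <- mean(err^2)
  coverage <- mean(lower <= truth & truth <= upper)
  data.frame(
    bias = mean(err), bias_mcse = ese / sqrt(n),
    ese = ese, ese_mcse = ese / sqrt(2 * (n - 1)),
    mse = mse, mse_mcse = stats::sd(err^2) / sqrt(n),
    coverage = coverage,
    coverage_mcse = sqrt(coverage * (1 - coverage) / n),
    truth = truth, n_sim_effective = n
  )
}

#' Monte Carlo acceptance region for empirical coverage
#'
#' The empirical coverage over `n_sim` replicates is, under a correct
#' method, binomial around the nominal level; its 95 percent acceptance
#' region is `nominal +/- 1.96 * sqrt(nominal (1 - nominal) / n_sim)`.
#' Coverage outside this region differs significantly from nominal.
#'
#' @param nominal Nominal coverage in (0, 1).
#' @param n_sim Number of simulation replicates.
#' @return Named vector `c(lower, upper)`.
#' @export
coverage_acceptance_region <- function(nominal, n_sim) {
  stopifnot(nominal > 0, nominal < 1, n_sim >= 1)
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n_sim)
  c(lower = nominal - half, upper = nominal + half)
}

#' @export
print.mim_performance <- function(x, ...) {
  cat(sprintf(
    "Scenario N = %d, kappa = %.2f, n_sim = %d; truth = %.4f\n",
    x$spec$n_index, x$spec$kappa, x$spec$n_sim, x$truth))
  df <- x$summary
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-6s bias %+.4f (%.4f)  ESE %.4f (%.4f)  MSE %.4f (%.4f)  cover %.3f (%.3f)\n",
      df$estimator[i], df$bias[i], df$bias_mcse[i], df$ese[i],
      df$ese_mcse[i], df$mse[i], df$mse_mcse[i], df$coverage[i],
      df$coverage_mcse[i]))
  }
  if (any(x$n_failed > 0)) {
    cat("  failed replicates:",
        paste(names(x$n_failed), x$n_failed, collapse = ", "), "\n")
  }
  invisible(x)
}
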