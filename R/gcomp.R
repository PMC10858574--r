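#' Maximum-likelihood G-computation point estimate
#'
#' Standard parametric model-based standardization: fit the conditional
#' outcome model (main effects plus treatment-covariate interactions) to
#' the index study by maximum likelihood, predict conditional outcome
#' means for every target row under treatment 1 and under treatment 0,
#' average the predictions within each arm over the target covariate
#' dataset, transform the two marginal means to the link scale, and
#' contrast (active minus control).
#'
#' @param data An `mim_trial` index-study dataset.
#' @param target An `mim_target` covariate set.
#' @param link Link function for the contrast scale (and outcome model).
#' @param coefficients Optional coefficient vector overriding the ML fit
#'   (test hook; order `(beta0, beta1, beta2, beta_t)`).
#' @return The marginal treatment effect estimate on the link scale.
#' @export
gcomp_point_estimate <- function(data, target,
                                 link = c("logit", "identity", "log"),
                                 coefficients = NULL) {
  link <- match.arg(link)
  spec <- outcome_model_spec(link = "logit")
  if (is.null(coefficients)) {
    coefficients <- gcomp_ml_coefficients(data, spec)
  }
  x_tar <- as.matrix(target$covariates)
  n <- nrow(x_tar)
  d1 <- build_design_matrix(x_tar, rep(1L, n), spec)
  d0 <- build_design_matrix(x_tar, rep(0L, n), spec)
  p1 <- mean(expit(drop(d1 %*% coefficients)))
  p0 <- mean(expit(drop(d0 %*% coefficients)))
  apply_link(p1, link) - apply_link(p0, link)
}

# ML fit of the first-stage model; errors on non-convergence/separation.
gcomp_ml_coefficients <- function(data, spec, start = NULL) {
  y <- data$outcomes
  if (length(unique(y)) < 2) {
    stop_mim("mim_estimation_error",
             "constant outcome: outcome model is not identifiable")
  }
  D <- build_design_matrix(data$covariates, data$treatment, spec)
  fit <- suppressWarnings(
    stats::glm.fit(D, y, family = stats::binomial(), start = start)
  )
  if (!fit$converged || fit$boundary || any(abs(fit$coefficients) > 50) ||
      anyNA(fit$coefficients)) {
    stop_mim("mim_estimation_error",
             "maximum-likelihood outcome model failed to converge (separation?)")
  }
  fit$coefficients
}

#' G-computation with non-parametric bootstrap inference
#'
#' Resamples the index-study rows with replacement (the target covariates
#' are held fixed), refits the outcome model and re-standardizes on each
#' resample. The reported estimate is the mean of the resample estimates
#' (the original-sample estimate is also stored), the standard error is
#' their standard deviation, and the interval uses the percentile method:
#' with `B` resamples at level 0.95 the endpoints are the
#' `ceiling(0.025 B)`-th smallest and `ceiling(0.025 B)`-th largest
#' resample estimates (for B = 1000, the 25th and 976th order
#' statistics).
#'
#' A resample on which the model cannot be fitted (e.g. separation) is
#' redrawn, up to `10 * n_boot` total attempts.
#'
#' @param data An `mim_trial` index-study dataset.
#' @param target An `mim_target` covariate set.
#' @param link Link function.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @return An object of class `mim_gcomp`: `estimate`, `se`, `interval`,
#'   `original_estimate`, `n_bootstrap`, `bootstrap_estimates`,
#'   `n_redrawn`.
#' @export
bootstrap_gcomp <- function(data, target,
                            link = c("logit", "identity", "log"),
                            n_boot = 1000, seed = 1, level = 0.95) {
  link <- match.arg(link)
  if (n_boot < 2) stop_mim("mim_config_error", "n_boot must be >= 2")
  spec <- outcome_model_spec(link = "logit")
  coef0 <- gcomp_ml_coefficients(data, spec)
  original <- gcomp_point_estimate(data, target, link,
                                   coefficients = coef0)

  x_tar <- as.matrix(target$covariates)
  n_tar <- nrow(x_tar)
  d1 <- build_design_matrix(x_tar, rep(1L, n_tar), spec)
  d0 <- build_design_matrix(x_tar, rep(0L, n_tar), spec)
  N <- length(data$outcomes)

  set.seed(seed_stream(seed, "bootstrap"))
  est <- numeric(n_boot)
  attempts <- 0L
  redrawn <- 0L
  b <- 1L
  while (b <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > 10L * n_boot) {
      stop_mim("mim_estimation_error",
               "bootstrap retry cap exceeded: too many unfittable resamples")
    }
    idx <- sample.int(N, N, replace = TRUE)
    co <- tryCatch(
      gcomp_ml_coefficients(
        list(covariates = data$covariates[idx, , drop = FALSE],
             treatment = data$treatment[idx],
             outcomes = data$outcomes[idx]),
        spec, start = coef0),
      mim_estimation_error = function(e) NULL
    )
    if (is.null(co)) {
      redrawn <- redrawn + 1L
      next
    }
    p1 <- mean(expit(drop(d1 %*% co)))
    p0 <- mean(expit(drop(d0 %*% co)))
    est[b] <- apply_link(p1, link) - apply_link(p0, link)
    b <- b + 1L
  }

  sorted <- sort(est)
  # guard against floating-point noise pushing ceiling() up one rank
  k <- as.integer(ceiling((1 - level) / 2 * n_boot - 1e-9))
  structure(
    list(estimate = mean(est), se = stats::sd(est),
         interval = c(lower = sorted[k], upper = sorted[n_boot + 1 - k]),
         level = level, original_estimate = original,
         n_bootstrap = n_boot, bootstrap_estimates = est,
         n_redrawn = redrawn),
    class = "mim_gcomp"
  )
}

#' @export
print.mim_gcomp <- function(x, ...) {
  cat("Marginal treatment effect (ML G-computation + bootstrap)\n")
  cat(sprintf("  estimate %.4f (original-sample %.4f), SE %.4f\n",
              x$estimate, x$original_estimate, x$se))
  cat(sprintf("  %.0f%% percentile interval (%.4f, %.4f), %d resamples\n",
              100 * x$level, x$interval[1], x$interval[2], x$n_bootstrap))
  invisible(x)
}
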