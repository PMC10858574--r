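test_that("second-stage logistic MLE equals the 2x2 closed form", {
  # equal arm proportions => zero effect
  z <- fit_second_stage(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(z$delta_hat, 0)

  # frozen closed-form oracle: 1000/1000 arms, means 0.6 vs 0.75
  f <- fixture_two_by_two(1000, 600, 1000, 750)
  est <- fit_second_stage(f$outcomes, f$treatment)
  expect_equal(est$delta_hat, log(0.6 / 0.4) - log(0.75 / 0.25))
  expect_equal(est$v_hat, 1 / 600 + 1 / 400 + 1 / 750 + 1 / 250)

  # empty cell => separation error
  expect_error(fit_second_stage(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               class = "mim_separation_error")
  expect_error(fit_second_stage(c(1, 0, 1, 0), rep(1, 4)),
               class = "mim_input_error")
})

test_that("closed-form second stage matches an iterative glm oracle", {
  set.seed(61)
  for (rep in 1:5) {
    t <- rep(c(1L, 0L), c(80, 120))
    y <- rbinom(200, 1, ifelse(t == 1, 0.4, 0.6))
    if (length(unique(y[t == 1])) < 2 || length(unique(y[t == 0])) < 2) next
    est <- fit_second_stage(y, t)
    fit <- glm(y ~ t, family = binomial())
    expect_equal(est$delta_hat, unname(coef(fit)["t"]), tolerance = 1e-6)
    expect_equal(est$v_hat, unname(vcov(fit)["t", "t"]), tolerance = 1e-6)
  }
})

test_that("pooling quantities are the stated means and sample variance", {
  ests <- data.frame(delta_hat = c(0.1, 0.2, 0.3), v_hat = rep(0.005, 3))
  s <- pool_quantities(ests)
  expect_equal(s$delta_bar, 0.2)
  expect_equal(s$v_bar, 0.005)
  expect_equal(s$b, 0.01)
  expect_equal(s$M, 3L)

  # permutation invariance and the degenerate all-equal case
  s2 <- pool_quantities(ests[c(3, 1, 2), ])
  expect_equal(s[c("delta_bar", "v_bar", "b")],
               s2[c("delta_bar", "v_bar", "b")])
  same <- pool_quantities(data.frame(delta_hat = rep(0.2, 5),
                                     v_hat = rep(0.01, 5)))
  expect_equal(same$b, 0)
  expect_error(pool_quantities(data.frame(delta_hat = 1, v_hat = 1)),
               class = "mim_input_error")
})

test_that("combining rules reproduce the frozen arithmetic example", {
  s <- pool_quantities(data.frame(delta_hat = c(0.1, 0.2, 0.3),
                                  v_hat = rep(0.005, 3)))
  p <- pool_combining_rules(s)
  expect_equal(p$estimate, 0.2)
  expect_equal(p$variance, (1 + 1 / 3) * 0.01 - 0.005)
  expect_equal(p$dof, 2 * (1 + 0.005 / ((4 / 3) * 0.01))^2)
  expect_equal(p$dof, 3.78125)
  expect_lt(p$interval[1], p$estimate)
  expect_gt(p$interval[2], p$estimate)
})

test_that("combining rules match independent arithmetic on random inputs", {
  set.seed(62)
  for (rep in 1:25) {
    M <- sample(3:50, 1)
    d <- rnorm(M, 0, 0.5)
    v <- runif(M, 0.001, 0.01)
    s <- pool_quantities(data.frame(delta_hat = d, v_hat = v))
    dbar <- sum(d) / M
    vbar <- sum(v) / M
    b <- sum((d - dbar)^2) / (M - 1)
    variance <- (1 + 1 / M) * b - vbar
    if (variance <= 0) {
      expect_error(pool_combining_rules(s),
                   class = "mim_negative_variance_error")
      next
    }
    p <- pool_combining_rules(s)
    expect_equal(p$estimate, dbar, tolerance = 1e-14)
    expect_equal(p$variance, variance)
    nu <- (M - 1) * (1 + vbar / ((1 + 1 / M) * b))^2
    expect_equal(p$dof, nu)
    expect_gte(p$dof, M - 1)
    expect_equal(unname(p$interval),
                 dbar + c(-1, 1) * qt(0.975, nu) * sqrt(variance))
  }
})

test_that("combining-rule limits: zero within variance and zero between variance", {
  s0 <- pool_quantities(data.frame(delta_hat = c(0.1, 0.2, 0.3),
                                   v_hat = rep(0, 3)))
  p0 <- pool_combining_rules(s0)
  expect_equal(p0$variance, (1 + 1 / 3) * 0.01)
  expect_equal(p0$dof, 2)

  sb <- pool_quantities(data.frame(delta_hat = rep(0.2, 4),
                                   v_hat = rep(0.01, 4)))
  expect_error(pool_combining_rules(sb),
               class = "mim_negative_variance_error")
  expect_warning(pf <- pool_combining_rules(sb,
                                            on_negative_variance = "fallback"),
                 "widened")
  expect_equal(pf$variance, (1 + 1 / 4) * 0)
})

test_that("posterior-simulation pooling agrees with combining rules at large M", {
  set.seed(63)
  M <- 1000
  d <- rnorm(M, -0.8, 0.1)
  v <- runif(M, 0.004, 0.006)
  s <- pool_quantities(data.frame(delta_hat = d, v_hat = v))
  cr <- pool_combining_rules(s)
  n_draws <- 1e5
  ps <- pool_posterior_simulation(s, n_draws = n_draws, seed = 64)
  mcse_mean <- sd(ps$draws) / sqrt(n_draws)
  expect_lt(abs(ps$estimate - cr$estimate), 3 * mcse_mean)
  mcse_var <- ps$variance * sqrt(2 / n_draws)
  # allow the small finite-M mean shift of the variance alongside MC noise
  finite_m <- cr$variance * 3 / M
  expect_lt(abs(ps$variance - cr$variance), 3 * mcse_var + finite_m)

  # same seed => identical draws
  ps2 <- pool_posterior_simulation(s, n_draws = 1000, seed = 65)
  ps3 <- pool_posterior_simulation(s, n_draws = 1000, seed = 65)
  expect_identical(ps2$draws, ps3$draws)
  expect_true(abs(ps2$estimate - s$delta_bar) < 0.01)
})

test_that("negative-variance-prone posterior simulation raises a warning", {
  s <- structure(list(delta_bar = 0, v_bar = 0.1, b = 0.001, M = 10L),
                 class = "mim_pooling_summary")
  expect_warning(pool_posterior_simulation(s, n_draws = 2000, seed = 66),
                 "negative-variance")
})

test_that("MIM pipeline pools the per-synthesis closed forms exactly", {
  cfg <- dgp_config(n_index = 600, n_target = 400, kappa = 1, seed = 71)
  trial <- simulate_index_trial(cfg)
  target <- simulate_target_covariates(cfg)
  spec <- scaled_model_spec(100)
  fit <- mim_estimate(trial, target, spec, seed = 72)

  # reconstruct the syntheses independently and re-derive Eq.-level pooling
  post <- fit_first_stage(trial, spec, seed = seed_stream(72, "mcmc"))
  aug <- augment_target(target)
  syn <- draw_synthetic_outcomes(post, aug, spec,
                                 seed = seed_stream(72, "synthesis"))
  deltas <- vas <- numeric(0)
  for (m in seq_len(nrow(syn$outcomes))) {
    est <- tryCatch(fit_second_stage(syn$outcomes[m, ], aug$treatment),
                    mim_separation_error = function(e) NULL)
    if (!is.null(est)) {
      deltas <- c(deltas, est$delta_hat)
      vas <- c(vas, est$v_hat)
    }
  }
  # congeniality: pooled estimate is exactly the mean of marginal
  # (intercept + treatment only) per-synthesis MLEs
  expect_identical(fit$estimate, mean(deltas))
  expect_equal(fit$variance,
               (1 + 1 / length(deltas)) * var(deltas) - mean(vas))
  expect_equal(fit$M, length(deltas))
})

test_that("MIM recovers the true marginal effect on a full-overlap replicate", {
  cfg <- dgp_config(n_index = 1000, kappa = 1, seed = 73)
  trial <- simulate_index_trial(cfg)
  target <- simulate_target_covariates(cfg)
  fit <- mim_estimate(trial, target, scaled_model_spec(250), seed = 74)
  expect_lt(abs(fit$estimate - (-0.81)), 3 * sqrt(fit$variance))
  expect_true(fit$interval[1] < fit$estimate &
                fit$estimate < fit$interval[2])
})

test_that("an overwhelming separation rate is a hard error", {
  # tiny target and a posterior concentrated on huge negative intercepts
  # makes every synthesis all-zero, so all second-stage fits separate
  spec <- scaled_model_spec(10)
  aug_target <- list(covariates = matrix(rnorm(10), 5, 2))
  post <- fixture_point_posterior(c(-50, 0, 0, 0, 0, 0), L = 40, spec)
  syn <- draw_synthetic_outcomes(post, augment_target(aug_target), spec,
                                 seed = 75)
  ests <- mimstd:::second_stage_all(syn$outcomes,
                                    augment_target(aug_target)$treatment)
  expect_true(all(ests$separated))
})
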