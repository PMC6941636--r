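# constant-baseline, no-frailty spec used by the degenerate-equivalence tests
degenerate_spec <- function(...) {
  model_spec(frailty = FALSE, n_knots = 0, order = 1, n_starts = 1,
             reltol = 1e-14, ...)
}

test_that("with zero frailty and constant baselines the fit is the Poisson MLE", {
  sim <- toy_cohort(n = 150, seed = 41, rate_1 = 0.03, rate_2 = 0.015,
                    beta_1 = c("arm=treat" = log(1.8)),
                    beta_2 = c("arm=treat" = log(0.7)))
  h <- sim$history
  fit <- fit_joint_frailty(h, degenerate_spec(), seed = 1)

  # IRLS oracle: collapsed per-subject counts with log-exposure offset
  glm_beta <- function(type) {
    cnt <- tabulate_counts(h, type)
    expo <- vapply(h$covariates$subject_id, function(s) {
      rows <- h$events[h$events$subject_id == s & h$events$event_type == type, ]
      sum(rows$stop - rows$start)
    }, numeric(1))
    treat <- as.numeric(h$covariates$arm == "treat")
    stats::glm(cnt ~ treat + offset(log(expo)), family = stats::poisson())
  }
  for (type in c("1", "2")) {
    gl <- glm_beta(type)
    est <- fit$coefficients$estimate[fit$coefficients$process == type]
    expect_equal(unname(est), unname(coef(gl)["treat"]), tolerance = 1e-6)
    # the flat baseline equals the intercept rate
    lam_hat <- base_hazard(fit$baselines[[type]], 10)
    expect_equal(log(lam_hat), unname(coef(gl)["(Intercept)"]),
                 tolerance = 1e-6)
  }
})

test_that("without covariates the constant-hazard fit is events over exposure", {
  sim <- simulate_cohort(toy_config_nocov(n = 80, seed = 42, rate_1 = 0.04,
                                          rate_2 = 0.01))
  h <- sim$history
  fit <- fit_joint_frailty(
    h, degenerate_spec(design_1 = character(0), design_2 = character(0)),
    seed = 1)
  for (type in c("1", "2")) {
    rows <- h$events[h$events$event_type == type, ]
    lam_mle <- sum(rows$status) / sum(rows$stop - rows$start)
    expect_equal(base_hazard(fit$baselines[[type]], 5), lam_mle,
                 tolerance = 1e-6)
  }
})

test_that("freeing the frailty covariance never lowers the maximized likelihood", {
  for (s in c(61, 62)) {
    sim <- toy_cohort(n = 60, seed = s, theta = 0.8, eta = 1.2, rho = 0.4)
    f0 <- fit_joint_frailty(sim$history,
                            model_spec(frailty = FALSE, n_knots = 1,
                                       n_starts = 1),
                            seed = 1, se = FALSE)
    f1 <- fit_joint_frailty(sim$history,
                            model_spec(frailty = TRUE, n_knots = 1,
                                       quad_nodes = 12, n_starts = 1),
                            seed = 1, se = FALSE)
    expect_gte(f1$loglik_marginal, f0$loglik_marginal - 1e-6)
  }
})

test_that("changing the reference level shifts coefficients by the known contrast", {
  cfg <- toy_config(n = 200, seed = 71, rate_1 = 0.03, rate_2 = 0.02,
                    beta_1 = c("arm=treat" = 0.5),
                    beta_2 = c("arm=treat" = -0.2))
  sim <- simulate_cohort(cfg)
  h1 <- sim$history
  fit1 <- fit_joint_frailty(h1, degenerate_spec(), seed = 1, se = FALSE)

  h2 <- h1
  h2$schema <- cov_schema(arm = c("control", "treat"), ref = c(arm = "treat"))
  fit2 <- fit_joint_frailty(h2, degenerate_spec(), seed = 1, se = FALSE)

  expect_equal(fit1$loglik_marginal, fit2$loglik_marginal, tolerance = 1e-6)
  b1 <- fit1$coefficients$estimate[fit1$coefficients$process == "1"]
  b2 <- fit2$coefficients$estimate[fit2$coefficients$process == "1"]
  expect_equal(b2, -b1, tolerance = 1e-5)
})

test_that("hazard ratio tables exponentiate Wald intervals correctly", {
  stub <- tibble::tibble(process = "1", term = "x", estimate = 0,
                         std.error = 0.1)
  hr <- hazard_ratio_table(stub)
  expect_equal(hr$hr, 1)
  expect_equal(hr$ci_low, exp(-qnorm(0.975) * 0.1), tolerance = 1e-10)
  expect_equal(hr$ci_high, exp(qnorm(0.975) * 0.1), tolerance = 1e-10)
  expect_equal(round(hr$ci_low, 2), 0.82)
  expect_equal(round(hr$ci_high, 2), 1.22)

  # printed-table fixture: HR 2.86, CI 1.76-4.64
  stub <- tibble::tibble(process = "1", term = "age_group=<=40",
                         estimate = 1.0508, std.error = 0.2469)
  hr <- hazard_ratio_table(stub)
  expect_equal(round(hr$hr, 2), 2.86)
  expect_equal(round(hr$ci_low, 2), 1.76)
  expect_equal(round(hr$ci_high, 2), 4.64)

  # zero SE degenerates to the point estimate
  stub$std.error <- 0
  hr <- hazard_ratio_table(stub)
  expect_equal(hr$ci_low, hr$hr)
  expect_equal(hr$ci_high, hr$hr)

  # missing SEs flag the table
  stub$std.error <- NA_real_
  expect_false(attr(hazard_ratio_table(stub), "ci_available"))
})

test_that("fitted models emit reference rows and tidy/glance output", {
  sim <- toy_cohort(n = 80, seed = 81, theta = 0.5, eta = 0.8,
                    beta_1 = c("arm=treat" = 0.4),
                    beta_2 = c("arm=treat" = 0.2))
  fit <- fit_joint_frailty(sim$history,
                           model_spec(n_knots = 1, quad_nodes = 10,
                                      n_starts = 1),
                           seed = 1)
  hr <- hazard_ratio_table(fit)
  ref <- hr[hr$reference, ]
  expect_true(all(ref$hr == 1))
  expect_true(all(ref$level == "control"))
  expect_true(all(hr$ci_low[!hr$reference] <= hr$hr[!hr$reference] &
                    hr$hr[!hr$reference] <= hr$ci_high[!hr$reference]))
  td <- tidy(fit)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  expect_true(all(td$std.error >= 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_lte(gl$logLik_penalized, gl$logLik + 1e-9)
  expect_true(is.finite(gl$gradient_norm))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("increasing kappa never increases the roughness at the optimum", {
  sim <- toy_cohort(n = 100, seed = 91, theta = 0.5, eta = 0.8,
                    rate_1 = 0.05, rate_2 = 0.03, cap = 10)
  rough <- vapply(c(0, 1e2, 1e5, 1e8), function(k) {
    fit <- fit_joint_frailty(sim$history,
                             model_spec(n_knots = 3, quad_nodes = 8,
                                        kappa_1 = k, kappa_2 = k,
                                        n_starts = 1),
                             seed = 1, se = FALSE)
    roughness_penalty(fit$baselines[["1"]]) +
      roughness_penalty(fit$baselines[["2"]])
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-8 + 0.01 * abs(rough[-length(rough)])))
})

test_that("with true correlation zero the bootstrap interval usually covers zero", {
  # scaled-down check: small no-covariate cohorts with constant baselines,
  # percentile interval from 60 subject-level resamples
  reps <- 10
  B <- 60
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(simulation_config(
      n_subjects = 60, baseline_1 = baseline_piecewise(0.05),
      baseline_2 = baseline_piecewise(0.05),
      beta_1 = numeric(0), beta_2 = numeric(0),
      frailty = frailty_covariance(0.8, 0.8, 0), covariate_model = list(),
      schema = cov_schema(arm = c("control", "treat")),
      censoring = list(horizon = 60, dropout_rate = 0),
      max_recurrences = 8, seed = 300 + r))
    h <- sim$history
    row_idx <- split(seq_len(nrow(h$events)), h$events$subject_id)
    boot_rho <- vapply(seq_len(B), function(b) {
      idx <- withr::with_seed(1000 * r + b,
                              sample(h$covariates$subject_id, replace = TRUE))
      newids <- sprintf("r%03d", seq_along(idx))
      take <- row_idx[idx]
      ev <- h$events[unlist(take), ]
      ev$subject_id <- rep(newids, lengths(take))
      cv <- h$covariates[match(idx, h$covariates$subject_id), ]
      cv$subject_id <- newids
      hb <- event_history(ev, cv, schema = h$schema, validate = FALSE)
      fb <- fit_joint_frailty(
        hb, model_spec(design_1 = character(0), design_2 = character(0),
                       n_knots = 0, order = 1, quad_nodes = 8,
                       n_starts = 1, maxit = 200),
        seed = 1, se = FALSE)
      fb$frailty$estimate[3]
    }, numeric(1))
    ci <- quantile(boot_rho, c(0.025, 0.975), names = FALSE)
    covered[r] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("scan_kappa profiles the smoothing weight with a shrinking edf", {
  sim <- toy_cohort(n = 60, seed = 91, theta = 0.5, eta = 0.8,
                    rate_1 = 0.05, rate_2 = 0.03, cap = 10)
  out <- scan_kappa(sim$history,
                    model_spec(n_knots = 2, quad_nodes = 8, n_starts = 1),
                    kappas = c(1e2, 1e6))
  expect_equal(nrow(out), 2)
  # heavier smoothing uses fewer effective spline degrees of freedom and
  # leaves a flatter (less rough) baseline
  expect_lt(out$edf[2], out$edf[1])
  expect_lte(out$roughness_1[2], out$roughness_1[1])
  expect_true(all(out$loglik_penalized <= out$loglik_marginal + 1e-9))
})

test_that("terminal-event fits converge and load on both frailties", {
  cfg <- cohort_preset(n_subjects = 120, seed = 55, include_terminal = TRUE)
  sim <- simulate_cohort(cfg)
  fit <- fit_joint_frailty(
    sim$history,
    model_spec(include_terminal = TRUE, n_knots = 1, quad_nodes = 8,
               n_starts = 1, design_D = c("age_group")),
    seed = 1, se = FALSE)
  expect_true(fit$converged)
  expect_true(all(c("alpha_1", "alpha_2") %in%
                    fit$coefficients$term[fit$coefficients$process == "D"]))
})

test_that("degenerate inputs abort with an identifiability diagnostic", {
  sim <- simulate_cohort(toy_config_nocov(n = 10, seed = 44, rate_1 = 0.04,
                                          rate_2 = 1e-9))
  expect_error(fit_joint_frailty(sim$history, model_spec(n_knots = 0)),
               "zero events")
})
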