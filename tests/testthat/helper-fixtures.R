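# shared fixtures, all generated in code

# minimal hand-written history: one subject, a type-1 event at 12,
# censored at 30, type-2 censored at 30
tiny_history <- function() {
  events <- tibble::tribble(
    ~subject_id, ~event_type, ~start, ~stop, ~status,
    "s1", "1", 0, 12, 1L,
    "s1", "1", 12, 30, 0L,
    "s1", "2", 0, 30, 0L
  )
  covariates <- tibble::tibble(subject_id = "s1", grade = "II")
  event_history(events, covariates,
                schema = cov_schema(grade = c("I", "II", "III")))
}

# small two-process cohort with constant baselines and a single binary
# covariate; cheap enough for repeated fitting in tests
toy_config <- function(n = 40, seed = 1, theta = 0, eta = 0, rho = 0,
                       rate_1 = 0.02, rate_2 = 0.01,
                       beta_1 = c("arm=treat" = 0), beta_2 = c("arm=treat" = 0),
                       horizon = 60, dropout = 0, cap = 6) {
  simulation_config(
    n_subjects = n,
    baseline_1 = baseline_piecewise(rate_1),
    baseline_2 = baseline_piecewise(rate_2),
    beta_1 = beta_1, beta_2 = beta_2,
    frailty = frailty_covariance(theta, eta, rho),
    covariate_model = list(arm = c(control = 0.5, treat = 0.5)),
    schema = cov_schema(arm = c("control", "treat")),
    censoring = list(horizon = horizon, dropout_rate = dropout),
    max_recurrences = cap,
    seed = seed
  )
}

toy_cohort <- function(...) simulate_cohort(toy_config(...))

# no-covariate variant (empty designs)
toy_config_nocov <- function(n = 40, seed = 1, theta = 0, eta = 0, rho = 0,
                             rate_1 = 0.02, rate_2 = 0.01, horizon = 60,
                             cap = 6) {
  simulation_config(
    n_subjects = n,
    baseline_1 = baseline_piecewise(rate_1),
    baseline_2 = baseline_piecewise(rate_2),
    beta_1 = numeric(0), beta_2 = numeric(0),
    frailty = frailty_covariance(theta, eta, rho),
    covariate_model = list(),
    schema = cov_schema(dummy = c("a", "b")),
    censoring = list(horizon = horizon, dropout_rate = 0),
    max_recurrences = cap,
    seed = seed
  )
}

# parameters matching a toy cohort's generating model, with a chosen
# frailty covariance
toy_params <- function(sim, theta = 0, eta = 0, rho = 0) {
  joint_params(
    beta_1 = sim$truth$beta_1, beta_2 = sim$truth$beta_2,
    baseline_1 = sim$truth$baseline_1, baseline_2 = sim$truth$baseline_2,
    frailty = frailty_covariance(theta, eta, rho)
  )
}

# per-subject event count of one type (zeros included)
tabulate_counts <- function(history, type) {
  ev <- dplyr::filter(history$events, .data$event_type == type,
                      .data$status == 1L)
  subjects <- history$covariates$subject_id
  cnt <- table(factor(ev$subject_id, levels = subjects))
  as.numeric(cnt)
}

expect_tibble_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
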