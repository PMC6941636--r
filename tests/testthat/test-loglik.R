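# one subject, constant baselines lambda / lambda2, one type-1 event at t,
# follow-up tau
one_subject_history <- function(t = 10, tau = 25) {
  events <- tibble::tribble(
    ~subject_id, ~event_type, ~start, ~stop, ~status,
    "s1", "1", 0, t, 1L,
    "s1", "1", t, tau, 0L,
    "s1", "2", 0, tau, 0L
  )
  cv <- tibble::tibble(subject_id = "s1", arm = "control")
  event_history(events, cv, schema = cov_schema(arm = c("control", "treat")))
}

const_params <- function(lam1, lam2, theta = 0, eta = 0, rho = 0,
                         beta_1 = numeric(0), beta_2 = numeric(0)) {
  joint_params(beta_1 = beta_1, beta_2 = beta_2,
               baseline_1 = baseline_piecewise(lam1),
               baseline_2 = baseline_piecewise(lam2),
               frailty = frailty_covariance(theta, eta, rho))
}

test_that("the conditional log-likelihood reduces to Poisson closed forms", {
  lam <- 0.07; lam2 <- 0.012; t <- 10; tau <- 25
  h <- one_subject_history(t, tau)
  ll <- conditional_loglik_subject(h, const_params(lam, lam2), c(0, 0))
  expect_equal(ll, log(lam) - lam * tau - lam2 * tau, tolerance = 1e-12)

  # a zero coefficient changes nothing
  ll0 <- conditional_loglik_subject(
    h, const_params(lam, lam2, beta_1 = c("arm=treat" = 0)), c(0, 0))
  expect_equal(ll0, ll)

  # frailty enters additively on the log scale
  llu <- conditional_loglik_subject(h, const_params(lam, lam2), c(0.4, -0.2))
  expect_equal(llu, (log(lam) + 0.4) - lam * exp(0.4) * tau -
                 lam2 * exp(-0.2) * tau, tolerance = 1e-12)
})

test_that("a piecewise-constant toy matches a hand-computed cell likelihood", {
  # rates 0.2 on [0, 5), 0.05 after; events at 3 and 8, follow-up to 12
  events <- tibble::tribble(
    ~subject_id, ~event_type, ~start, ~stop, ~status,
    "s1", "1", 0, 3, 1L,
    "s1", "1", 3, 8, 1L,
    "s1", "1", 8, 12, 0L,
    "s1", "2", 0, 12, 0L
  )
  cv <- tibble::tibble(subject_id = "s1", arm = "control")
  h <- event_history(events, cv, schema = cov_schema(arm = c("control")))
  p <- joint_params(numeric(0), numeric(0),
                    baseline_piecewise(c(0.2, 0.05), 5),
                    baseline_piecewise(0.01),
                    frailty = frailty_covariance(0, 0))
  hand <- log(0.2) + log(0.05) -
    (0.2 * 5 + 0.05 * 7) -   # type-1 exposure over both rate cells
    0.01 * 12                # event-free type-2 process
  expect_equal(conditional_loglik_subject(h, p, c(0, 0)), hand,
               tolerance = 1e-12)
})

test_that("zero frailty variances collapse the marginal to the conditional", {
  sim <- toy_cohort(n = 8, seed = 14, theta = 0.6, eta = 1.1, rho = 0.2)
  p <- toy_params(sim, theta = 0, eta = 0)
  subs <- unique(sim$history$covariates$subject_id)
  cond <- sum(vapply(subs, function(s) {
    conditional_loglik_subject(sim$history, p, c(0, 0), subject = s)
  }, numeric(1)))
  expect_equal(marginal_loglik(sim$history, p), cond, tolerance = 1e-12)
  expect_equal(oracle_marginal_loglik(sim$history, p), cond, tolerance = 1e-12)
})

test_that("quadrature agrees with the dense-grid oracle on a 3-subject toy", {
  sim <- toy_cohort(n = 3, seed = 23)
  p <- toy_params(sim, theta = 1, eta = 1, rho = 0.3)
  gh <- marginal_loglik(sim$history, p, quad_nodes = 32)
  grid <- oracle_marginal_loglik(sim$history, p, grid_points = 800)
  expect_equal(gh, grid, tolerance = 1e-4)
})

test_that("the quadrature value is stable in the number of nodes", {
  sim <- toy_cohort(n = 5, seed = 24, rate_1 = 0.004, rate_2 = 0.004,
                    cap = 2)
  p <- toy_params(sim, theta = 0.4, eta = 0.6, rho = 0.3)
  v20 <- marginal_loglik(sim$history, p, quad_nodes = 20)
  v40 <- marginal_loglik(sim$history, p, quad_nodes = 40)
  expect_lt(abs(v20 - v40), 1e-8)
})

test_that("the oracle converges under grid refinement", {
  sim <- toy_cohort(n = 3, seed = 25)
  p <- toy_params(sim, theta = 0.8, eta = 1.2, rho = 0.4)
  a <- oracle_marginal_loglik(sim$history, p, grid_points = 1000)
  b <- oracle_marginal_loglik(sim$history, p, grid_points = 2000)
  expect_lt(abs(a - b), 1e-6)
})

test_that("a single zero variance integrates over one dimension only", {
  sim <- toy_cohort(n = 4, seed = 26)
  p <- toy_params(sim, theta = 0, eta = 1.5)
  expect_equal(p$frailty$rho, 0)
  gh <- marginal_loglik(sim$history, p, quad_nodes = 40)
  grid <- oracle_marginal_loglik(sim$history, p, grid_points = 2000)
  expect_equal(gh, grid, tolerance = 1e-6)
})

test_that("an invalid covariance is rejected", {
  sim <- toy_cohort(n = 2, seed = 27)
  p <- toy_params(sim)
  p$frailty <- structure(list(theta = -1, eta = 1, rho = 0),
                         class = "frailty_covariance")
  expect_error(marginal_loglik(sim$history, p), "covariance")
})

test_that("the analytic gradient matches central finite differences", {
  sim <- toy_cohort(n = 12, seed = 33, theta = 0.7, eta = 1.4, rho = 0.3)
  h <- sim$history
  spec <- model_spec(quad_nodes = 12, n_knots = 2, kappa_1 = 1e4,
                     kappa_2 = 1e4, n_starts = 1)
  obj <- penalized_objective(h, spec)
  withr::with_seed(44, {
    for (rep in 1:3) {
      par <- obj$par0 + rnorm(length(obj$par0), 0, 0.25)
      g_an <- obj$gradient(par)
      g_fd <- vapply(seq_along(par), function(j) {
        hh <- 1e-6 * (1 + abs(par[j]))
        pp <- par; pp[j] <- pp[j] + hh
        pm <- par; pm[j] <- pm[j] - hh
        (obj$value(pp) - obj$value(pm)) / (2 * hh)
      }, numeric(1))
      expect_lt(max(abs(g_an - g_fd) / (1 + abs(g_fd))), 1e-5)
    }
  })
})

test_that("the terminal-event gradient is also exact", {
  cfg <- cohort_preset(n_subjects = 25, seed = 51, include_terminal = TRUE)
  sim <- simulate_cohort(cfg)
  spec <- model_spec(quad_nodes = 8, n_knots = 1, n_starts = 1,
                     include_terminal = TRUE)
  obj <- penalized_objective(sim$history, spec)
  withr::with_seed(45, {
    par <- obj$par0 + rnorm(length(obj$par0), 0, 0.2)
    g_an <- obj$gradient(par)
    g_fd <- vapply(seq_along(par), function(j) {
      hh <- 1e-6 * (1 + abs(par[j]))
      pp <- par; pp[j] <- pp[j] + hh
      pm <- par; pm[j] <- pm[j] - hh
      (obj$value(pp) - obj$value(pm)) / (2 * hh)
    }, numeric(1))
    expect_lt(max(abs(g_an - g_fd) / (1 + abs(g_fd))), 1e-5)
  })
})
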