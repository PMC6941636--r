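test_that("frailty draws have the configured covariance and are reproducible", {
  z <- draw_frailties(50, frailty_covariance(0, 0), seed = 1)
  expect_true(all(z$u == 0) && all(z$v == 0))

  a <- draw_frailties(100, frailty_covariance(1, 2, 0.4), seed = 7)
  b <- draw_frailties(100, frailty_covariance(1, 2, 0.4), seed = 7)
  expect_identical(a, b)

  # Monte-Carlo moments at the reported frailty variances
  n <- 1e5
  z <- draw_frailties(n, frailty_covariance(1.10, 7.39, 0.5), seed = 123)
  se_var <- function(s2) sqrt(2 / (n - 1)) * s2
  expect_lt(abs(var(z$u) - 1.10), 3 * se_var(1.10))
  expect_lt(abs(var(z$v) - 7.39), 3 * se_var(7.39))
  expect_lt(abs(cor(z$u, z$v) - 0.5), 3 * (1 - 0.5^2) / sqrt(n))

  expect_error(frailty_covariance(-1, 1), "nonnegative")
  expect_error(frailty_covariance(1, 1, 1), "rho")
  # rho is ignored when a variance is zero
  expect_equal(frailty_covariance(0, 2, 0.7)$rho, 0)
})

test_that("gap times from a constant baseline are exponential", {
  cfg <- toy_config_nocov(n = 400, seed = 21, rate_1 = 0.05, rate_2 = 0.001,
                          horizon = 1e5, cap = 3)
  sim <- simulate_cohort(cfg)
  ev <- dplyr::filter(sim$history$events, event_type == "1", status == 1)
  gaps <- ev$stop - ev$start
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("a vanishing horizon yields a single censored interval per type", {
  cfg <- toy_config_nocov(n = 5, seed = 3, rate_1 = 1e-6, rate_2 = 1e-6,
                          horizon = 0.001)
  sim <- simulate_cohort(cfg)
  ev <- sim$history$events
  expect_equal(nrow(ev), 10)          # 5 subjects x 2 types
  expect_true(all(ev$status == 0L))
  expect_true(all(ev$stop == 0.001))
})

test_that("a log(2) coefficient doubles the event rate of the indexed stratum", {
  cfg <- toy_config(n = 3000, seed = 17, rate_1 = 0.01,
                    beta_1 = c("arm=treat" = log(2)), horizon = 50, cap = 50)
  sim <- simulate_cohort(cfg)
  counts <- dplyr::count(
    dplyr::filter(sim$history$events, event_type == "1", status == 1),
    subject_id)
  cv <- dplyr::left_join(sim$history$covariates, counts, by = "subject_id")
  cv$n[is.na(cv$n)] <- 0
  m_treat <- mean(cv$n[cv$arm == "treat"])
  m_ctrl <- mean(cv$n[cv$arm == "control"])
  se_ratio <- (m_treat / m_ctrl) *
    sqrt(var(cv$n[cv$arm == "treat"]) / sum(cv$arm == "treat") / m_treat^2 +
           var(cv$n[cv$arm == "control"]) / sum(cv$arm == "control") / m_ctrl^2)
  expect_lt(abs(m_treat / m_ctrl - 2), 3 * se_ratio)
})

test_that("cohort event counts match Poisson and log-normal frailty expectations", {
  # no frailty: mean events per subject ~ lambda * tau
  lam <- 0.03; tau <- 40
  sim <- simulate_cohort(toy_config_nocov(n = 2000, seed = 5, rate_1 = lam,
                                          rate_2 = 1e-4, horizon = tau,
                                          cap = 50))
  counts <- tabulate_counts(sim$history, "1")
  expect_lt(abs(mean(counts) - lam * tau),
            3 * sd(counts) / sqrt(length(counts)))

  # log-normal frailty multiplies the marginal mean by exp(theta / 2)
  th <- 1
  sim <- simulate_cohort(toy_config_nocov(n = 2000, seed = 6, rate_1 = lam,
                                          rate_2 = 1e-4, horizon = tau,
                                          theta = th, cap = 500))
  counts <- tabulate_counts(sim$history, "1")
  expect_lt(abs(mean(counts) - lam * tau * exp(th / 2)),
            3 * sd(counts) / sqrt(length(counts)))
})

test_that("identical seeds reproduce the cohort and subjects are stream-independent", {
  a <- simulate_cohort(toy_config(n = 25, seed = 11, theta = 0.5, eta = 1,
                                  rho = 0.3))
  b <- simulate_cohort(toy_config(n = 25, seed = 11, theta = 0.5, eta = 1,
                                  rho = 0.3))
  expect_identical(a$history$events, b$history$events)
  expect_identical(a$truth$frailties, b$truth$frailties)

  # enlarging the cohort leaves earlier subjects' records unchanged
  big <- simulate_cohort(toy_config(n = 50, seed = 11, theta = 0.5, eta = 1,
                                    rho = 0.3))
  first25 <- dplyr::semi_join(big$history$events,
                              a$history$events["subject_id"],
                              by = "subject_id")
  expect_identical(as.data.frame(first25), as.data.frame(a$history$events))
})

test_that("raising theta does not decrease the spread of type-1 counts", {
  v_at <- function(th) {
    sims <- lapply(1:4, function(s) {
      simulate_cohort(toy_config_nocov(n = 300, seed = 30 + s, rate_1 = 0.02,
                                       rate_2 = 1e-4, horizon = 50,
                                       theta = th, cap = 50))
    })
    mean(vapply(sims, function(s) var(tabulate_counts(s$history, "1")),
                numeric(1)))
  }
  expect_lte(v_at(0), v_at(0.5))
  expect_lte(v_at(0.5), v_at(1.5))
})

test_that("terminal events stop the recurrent processes", {
  cfg <- cohort_preset(n_subjects = 60, seed = 13, include_terminal = TRUE)
  sim <- simulate_cohort(cfg)
  ev <- sim$history$events
  expect_true("D" %in% ev$event_type)
  expect_identical(nrow(validate_counting_process(sim$history)), 0L)
  term <- dplyr::filter(ev, event_type == "D")
  rec <- dplyr::filter(ev, event_type != "D")
  stops <- setNames(term$stop, term$subject_id)
  expect_true(all(rec$stop <= stops[rec$subject_id] + 1e-9))
})
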