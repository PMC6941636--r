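#' Specify a joint frailty model fit
#'
#' @param design_1,design_2 Character vectors of covariate names entering
#'   the linear predictor of each recurrent process (default: all schema
#'   covariates at fit time). Use `character(0)` for no covariates.
#' @param design_D Covariates for the terminal submodel.
#' @param include_terminal Fit the terminal-event submodel (default
#'   `FALSE`); requires `"D"` records in the data.
#' @param frailty Estimate the bivariate frailty covariance (default
#'   `TRUE`); `FALSE` fixes both variances at zero (no random effects).
#' @param quad_nodes Gauss-Hermite nodes per frailty dimension (>= 5).
#' @param kappa_1,kappa_2,kappa_D Nonnegative smoothing weights on the
#'   curvature penalty \eqn{\kappa \int h_0''^2} of each baseline; 0 (the
#'   default) fits by plain maximum marginal likelihood.
#' @param n_knots Interior knots per baseline (default 7).
#' @param order Spline order (default 4, cubic; order 1 with
#'   `n_knots = 0` gives a constant baseline hazard).
#' @param n_starts Number of seeded optimizer starts (default 3); ties are
#'   broken by highest penalized likelihood, then smallest gradient norm.
#' @param maxit,reltol Quasi-Newton (BFGS) iteration cap and relative
#'   tolerance.
#' @return A `model_spec` object.
#' @export
model_spec <- function(design_1 = NULL, design_2 = NULL, design_D = NULL,
                       include_terminal = FALSE, frailty = TRUE,
                       quad_nodes = 20L,
                       kappa_1 = 0, kappa_2 = 0, kappa_D = 0,
                       n_knots = 7L, order = 4L,
                       n_starts = 3L, maxit = 500L, reltol = 1e-10) {
  if (quad_nodes < 5) abort("quad_nodes must be at least 5")
  if (min(kappa_1, kappa_2, kappa_D) < 0) abort("kappas must be nonnegative")
  if (order < 3 && max(kappa_1, kappa_2, kappa_D) > 0) {
    abort("a curvature penalty requires spline order >= 3")
  }
  structure(
    list(design_1 = design_1, design_2 = design_2, design_D = design_D,
         include_terminal = include_terminal, frailty = frailty,
         quad_nodes = as.integer(quad_nodes),
         kappa_1 = kappa_1, kappa_2 = kappa_2, kappa_D = kappa_D,
         n_knots = as.integer(n_knots), order = as.integer(order),
         n_starts = as.integer(n_starts), maxit = as.integer(maxit),
         reltol = reltol),
    class = "model_spec"
  )
}

design_terms <- function(history, covariate_names) {
  zx <- covariate_dummies(history$covariates, history$schema,
                          covariate_names = covariate_names)
  zx
}

#' Fit the joint frailty model by penalized marginal likelihood
#'
#' Maximizes the Gauss-Hermite-integrated marginal log-likelihood minus
#' the curvature penalties over regression coefficients, log spline
#' coefficients, log frailty variances and the atanh-transformed
#' correlation, using quasi-Newton (BFGS) steps with an analytic gradient
#' and `n_starts` seeded starts. Standard errors come from the inverse of
#' the numerically differentiated observed information of the *marginal,
#' unpenalized* log-likelihood in the regression/frailty block (spline
#' coefficients held at their estimates); frailty-scale SEs are mapped by
#' the delta method.
#'
#' @param history A validated [event_history()] with at least one event of
#'   each recurrent type.
#' @param spec A [model_spec()].
#' @param init Optional named list overriding initial values (`beta_1`,
#'   `beta_2`, `theta`, `eta`, `rho`, `c1`, `c2`, ...).
#' @param seed Integer seed for the multi-start jitter.
#' @param se Compute standard errors (default `TRUE`); `FALSE` skips the
#'   observed-information step, useful inside bootstrap loops.
#' @return A `joint_frailty_fit` object; see [tidy()], [glance()],
#'   [hazard_ratio_table()] and [autoplot()] methods.
#' @export
fit_joint_frailty <- function(history, spec = model_spec(), init = NULL,
                              seed = 1L, se = TRUE) {
  prob <- build_fit_problem(history, spec, init)
  fit_from_problem(prob, history, spec, seed, se)
}

# assemble data structures, parameter layout, starting values and the
# penalized-objective closure for one model specification
build_fit_problem <- function(history, spec, init = NULL) {
  viol <- validate_counting_process(history)
  if (nrow(viol)) abort("history fails validate_counting_process()")
  ev <- history$events
  for (k in 1:2) {
    nev <- sum(ev$event_type == as.character(k) & ev$status == 1L)
    if (nev == 0) {
      abort(paste0(
        "process ", k, " has zero events: the model is not identifiable ",
        "unless its frailty variance is fixed at 0 and its baseline fixed; ",
        "drop the process or supply data with events"))
    }
  }
  if (spec$include_terminal && !any(ev$event_type == "D")) {
    abort("include_terminal = TRUE but the history has no terminal records")
  }

  all_covs <- schema_covariates(history$schema)
  d1 <- spec$design_1 %||% all_covs
  d2 <- spec$design_2 %||% all_covs
  dD <- spec$design_D %||% all_covs
  Z1 <- design_terms(history, d1)
  Z2 <- design_terms(history, d2)

  Tmax <- max(ev$stop)
  basis_for <- function(type) {
    evt <- ev$stop[ev$event_type == type & ev$status == 1L]
    mspline_basis(evt, n_knots = spec$n_knots, order = spec$order,
                  boundary = c(0, Tmax))
  }
  b1 <- basis_for("1")
  b2 <- basis_for("2")
  bD <- if (spec$include_terminal) basis_for("D") else NULL

  beta1_names <- colnames(Z1)
  beta2_names <- colnames(Z2)
  betaD_names <- if (spec$include_terminal) colnames(design_terms(history, dD))
  else character(0)

  skel <- joint_params(
    beta_1 = setNames(numeric(length(beta1_names)), beta1_names),
    beta_2 = setNames(numeric(length(beta2_names)), beta2_names),
    baseline_1 = b1, baseline_2 = b2,
    frailty = frailty_covariance(if (spec$frailty) 0.3 else 0,
                                 if (spec$frailty) 0.3 else 0, 0),
    beta_D = setNames(numeric(length(betaD_names)), betaD_names),
    baseline_D = bD, alpha = c(0, 0)
  )
  pd <- prepare_joint_data(history, skel)

  P1 <- if (spec$kappa_1 > 0) penalty_matrix(b1) else NULL
  P2 <- if (spec$kappa_2 > 0) penalty_matrix(b2) else NULL
  PD <- if (spec$include_terminal && spec$kappa_D > 0) penalty_matrix(bD) else NULL

  layout <- par_layout(length(beta1_names), length(beta2_names),
                       b1$nbasis, b2$nbasis, spec$frailty,
                       spec$include_terminal, length(betaD_names),
                       if (spec$include_terminal) bD$nbasis else 0L)

  # crude event-rate initial values: flat hazard spread over the basis
  init_rate <- function(type, nb) {
    recs <- ev[ev$event_type == type, ]
    rate <- sum(recs$status) / sum(recs$stop - recs$start)
    rep(log(rate * Tmax / nb), nb)
  }
  # moment-based variance starting values: for a mixed Poisson count with
  # log-normal frailty, E[N(N-1)] / E[N]^2 (exposure-adjusted) = exp(sigma^2)
  init_sigma2 <- function(type) {
    cnt <- rowsum_vec(as.numeric(ev$status[ev$event_type == type]),
                      match(ev$subject_id[ev$event_type == type],
                            sort(unique(ev$subject_id))),
                      length(unique(ev$subject_id)))
    fu <- rowsum_vec((ev$stop - ev$start)[ev$event_type == type],
                     match(ev$subject_id[ev$event_type == type],
                           sort(unique(ev$subject_id))),
                     length(unique(ev$subject_id)))
    ratio <- sum(cnt * (cnt - 1)) * sum(fu)^2 / (sum(cnt)^2 * sum(fu^2))
    log(min(max(ratio, 1.1), 20))
  }
  par0 <- numeric(layout$n_par)
  par0[layout$c1] <- init_rate("1", b1$nbasis)
  par0[layout$c2] <- init_rate("2", b2$nbasis)
  if (spec$frailty) {
    par0[layout$sig] <- c(init_sigma2("1"), init_sigma2("2"), 0)
  }
  if (spec$include_terminal) {
    par0[layout$cD] <- init_rate("D", bD$nbasis)
  }
  if (!is.null(init)) {
    if (!is.null(init$beta_1)) par0[layout$beta_1] <- init$beta_1
    if (!is.null(init$beta_2)) par0[layout$beta_2] <- init$beta_2
    if (!is.null(init$c1)) par0[layout$c1] <- log(init$c1)
    if (!is.null(init$c2)) par0[layout$c2] <- log(init$c2)
    if (spec$frailty) {
      if (!is.null(init$theta)) par0[layout$sig][1] <- log(init$theta)
      if (!is.null(init$eta)) par0[layout$sig][2] <- log(init$eta)
      if (!is.null(init$rho)) par0[layout$sig][3] <- atanh(init$rho)
    }
  }

  objective <- function(par, want_grad = TRUE, penalized = TRUE) {
    up <- unpack_par(par, layout, skel)
    eng <- marginal_engine(pd, up$params, quad_nodes = spec$quad_nodes,
                           want_grad = want_grad,
                           c1 = up$c1, c2 = up$c2, cD = up$cD)
    val <- eng$value
    if (penalized) {
      if (!is.null(P1)) val <- val - spec$kappa_1 * drop(crossprod(up$c1, P1 %*% up$c1))
      if (!is.null(P2)) val <- val - spec$kappa_2 * drop(crossprod(up$c2, P2 %*% up$c2))
      if (!is.null(PD)) val <- val - spec$kappa_D * drop(crossprod(up$cD, PD %*% up$cD))
    }
    if (!want_grad) return(list(value = val))
    g <- pack_grad(eng$grad, layout, up, spec$frailty)
    if (penalized) {
      if (!is.null(P1)) g[layout$c1] <- g[layout$c1] -
          2 * spec$kappa_1 * drop(P1 %*% up$c1) * up$c1
      if (!is.null(P2)) g[layout$c2] <- g[layout$c2] -
          2 * spec$kappa_2 * drop(P2 %*% up$c2) * up$c2
      if (!is.null(PD)) g[layout$cD] <- g[layout$cD] -
          2 * spec$kappa_D * drop(PD %*% up$cD) * up$cD
    }
    list(value = val, gradient = g)
  }

  list(objective = objective, par0 = par0, layout = layout, skel = skel,
       pd = pd, b1 = b1, b2 = b2, bD = bD,
       beta1_names = beta1_names, beta2_names = beta2_names,
       betaD_names = betaD_names)
}

#' Penalized-objective closure for diagnostics
#'
#' Exposes the penalized marginal log-likelihood that
#' [fit_joint_frailty()] maximizes, as functions of the packed
#' unconstrained parameter vector (regression coefficients, log spline
#' coefficients, log variances, atanh correlation). Useful for gradient
#' checks and profiling.
#'
#' @inheritParams fit_joint_frailty
#' @return A list with `par0` (the default starting vector), `value(par)`,
#'   `gradient(par)` (analytic), and the parameter `layout`.
#' @export
penalized_objective <- function(history, spec = model_spec(), init = NULL) {
  prob <- build_fit_problem(history, spec, init)
  list(
    par0 = prob$par0,
    value = function(par) prob$objective(par, want_grad = FALSE)$value,
    gradient = function(par) prob$objective(par)$gradient,
    layout = prob$layout
  )
}

fit_from_problem <- function(prob, history, spec, seed, se) {
  objective <- prob$objective
  par0 <- prob$par0
  layout <- prob$layout
  skel <- prob$skel
  pd <- prob$pd
  b1 <- prob$b1; b2 <- prob$b2; bD <- prob$bD
  beta1_names <- prob$beta1_names
  beta2_names <- prob$beta2_names
  betaD_names <- prob$betaD_names

  fn <- function(par) -objective(par, want_grad = FALSE)$value
  gr <- function(par) -objective(par)$gradient

  runs <- vector("list", spec$n_starts)
  for (s in seq_len(spec$n_starts)) {
    par_s <- if (s == 1) par0 else {
      withr::with_seed(as.integer(seed) + s, {
        jit <- rnorm(length(par0), 0, 0.3)
        # wider spread on the variance block, where the surface is flattest
        jit[layout$sig] <- rnorm(length(layout$sig), 0, 0.8)
        par0 + jit
      })
    }
    opt <- tryCatch(
      optim(par_s, fn, gr, method = "BFGS",
            control = list(maxit = spec$maxit, reltol = spec$reltol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    gn <- sqrt(sum(gr(opt$par)^2))
    runs[[s]] <- list(opt = opt, gn = gn)
  }
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) abort("all optimizer starts failed")
  vals <- vapply(runs, function(r) -r$opt$value, numeric(1))
  gns <- vapply(runs, function(r) r$gn, numeric(1))
  best <- order(-vals, gns)[1]
  opt <- runs[[best]]$opt
  grad_norm <- runs[[best]]$gn

  up <- unpack_par(opt$par, layout, skel)
  loglik_pen <- -opt$value
  loglik_marg <- objective(opt$par, want_grad = FALSE, penalized = FALSE)$value

  ses <- if (se) {
    fit_standard_errors(opt$par, layout, skel, pd, spec)
  } else {
    list(se = rep(NA_real_, layout$n_par), ok = FALSE, vcov = NULL,
         index = integer(0))
  }

  b1f <- set_coefficients(b1, up$c1)
  b2f <- set_coefficients(b2, up$c2)
  bDf <- if (spec$include_terminal) set_coefficients(bD, up$cD) else NULL

  coefs <- bind_rows(
    coef_tibble("1", beta1_names, up$params$beta_1, ses$se[layout$beta_1]),
    coef_tibble("2", beta2_names, up$params$beta_2, ses$se[layout$beta_2]),
    if (spec$include_terminal) bind_rows(
      coef_tibble("D", betaD_names, up$params$beta_D, ses$se[layout$beta_D]),
      coef_tibble("D", c("alpha_1", "alpha_2"), up$params$alpha,
                  ses$se[layout$alpha])
    )
  )

  fr <- up$params$frailty
  if (spec$frailty) {
    se_sig <- ses$se[layout$sig]
    frailty_tbl <- tibble(
      parameter = c("theta", "eta", "rho"),
      estimate = c(fr$theta, fr$eta, fr$rho),
      std.error = c(fr$theta * se_sig[1], fr$eta * se_sig[2],
                    (1 - fr$rho^2) * se_sig[3])
    )
  } else {
    frailty_tbl <- tibble(parameter = c("theta", "eta", "rho"),
                          estimate = c(0, 0, 0), std.error = NA_real_)
  }

  structure(
    list(coefficients = coefs, frailty = frailty_tbl, frailty_cov = fr,
         baselines = list(`1` = b1f, `2` = b2f, D = bDf),
         loglik_marginal = loglik_marg, loglik_penalized = loglik_pen,
         converged = opt$convergence == 0, n_iter = unname(opt$counts[2]),
         gradient_norm = grad_norm,
         se_ok = ses$ok, vcov = ses$vcov, vcov_index = ses$index,
         spec = spec, schema = history$schema, layout = layout,
         n = pd$n, par = opt$par),
    class = "joint_frailty_fit"
  )
}

coef_tibble <- function(process, terms, est, se) {
  if (!length(terms)) {
    return(tibble(process = character(), term = character(),
                  estimate = numeric(), std.error = numeric()))
  }
  tibble(process = process, term = terms, estimate = unname(est),
         std.error = unname(se))
}

par_layout <- function(p1, p2, nb1, nb2, frailty, terminal, pD, nbD) {
  idx <- 0L
  take <- function(k) {
    out <- if (k > 0) idx + seq_len(k) else integer(0)
    idx <<- idx + k
    out
  }
  l <- list(
    beta_1 = take(p1), beta_2 = take(p2),
    c1 = take(nb1), c2 = take(nb2),
    sig = if (frailty) take(3L) else integer(0),
    beta_D = if (terminal) take(pD) else integer(0),
    alpha = if (terminal) take(2L) else integer(0),
    cD = if (terminal) take(nbD) else integer(0)
  )
  l$n_par <- idx
  l
}

unpack_par <- function(par, layout, skel) {
  params <- skel
  params$beta_1[] <- par[layout$beta_1]
  params$beta_2[] <- par[layout$beta_2]
  c1 <- exp(pmin(par[layout$c1], 300))
  c2 <- exp(pmin(par[layout$c2], 300))
  cD <- NULL
  if (length(layout$sig)) {
    s <- pmin(pmax(par[layout$sig], -30), 30)
    # keep |rho| away from 1 so the Cholesky factor stays finite during
    # line searches
    rho <- tanh(pmin(pmax(s[3], -12), 12))
    params$frailty <- frailty_covariance(exp(s[1]), exp(s[2]), rho)
  } else {
    params$frailty <- frailty_covariance(0, 0, 0)
  }
  if (length(layout$alpha)) {
    params$beta_D[] <- par[layout$beta_D]
    params$alpha <- par[layout$alpha]
    cD <- exp(pmin(par[layout$cD], 300))
  }
  list(params = params, c1 = c1, c2 = c2, cD = cD)
}

pack_grad <- function(g, layout, up, frailty) {
  out <- numeric(layout$n_par)
  out[layout$beta_1] <- g$beta_1
  out[layout$beta_2] <- g$beta_2
  out[layout$c1] <- g$c1 * up$c1          # chain rule to the log scale
  out[layout$c2] <- g$c2 * up$c2
  if (frailty && !is.null(g$dL)) {
    fr <- up$params$frailty
    s1 <- sqrt(fr$theta); s2 <- sqrt(fr$eta); rho <- fr$rho
    dL_dlth <- matrix(c(s1 / 2, 0, 0, 0), 2, 2)
    dL_dlet <- matrix(c(0, rho * s2 / 2, 0, s2 * sqrt(1 - rho^2) / 2), 2, 2)
    dL_drho <- matrix(c(0, s2, 0, -s2 * rho / sqrt(1 - rho^2)), 2, 2)
    dL <- g$dL
    out[layout$sig] <- c(sum(dL * dL_dlth), sum(dL * dL_dlet),
                         sum(dL * dL_drho) * (1 - rho^2))
  } else if (frailty) {
    out[layout$sig] <- 0
  }
  if (length(layout$alpha)) {
    out[layout$beta_D] <- g$beta_D
    out[layout$alpha] <- g$alpha %||% c(0, 0)
    out[layout$cD] <- g$cD * up$cD
  }
  out
}

# observed-information SEs for the beta / Sigma (/ terminal) block from
# central finite differences of the analytic gradient of the marginal,
# unpenalized log-likelihood; spline coefficients held fixed
fit_standard_errors <- function(par_hat, layout, skel, pd, spec) {
  index <- c(layout$beta_1, layout$beta_2, layout$sig,
             layout$beta_D, layout$alpha)
  se <- rep(NA_real_, layout$n_par)
  if (!length(index)) return(list(se = se, ok = TRUE, vcov = NULL, index = index))
  grad_at <- function(par) {
    up <- unpack_par(par, layout, skel)
    eng <- marginal_engine(pd, up$params, quad_nodes = spec$quad_nodes,
                           want_grad = TRUE, c1 = up$c1, c2 = up$c2,
                           cD = up$cD)
    pack_grad(eng$grad, layout, up, spec$frailty)[index]
  }
  m <- length(index)
  H <- matrix(0, m, m)
  for (j in seq_len(m)) {
    h <- 1e-4 * (1 + abs(par_hat[index[j]]))
    pp <- par_hat; pp[index[j]] <- pp[index[j]] + h
    pm <- par_hat; pm[index[j]] <- pm[index[j]] - h
    H[, j] <- (grad_at(pp) - grad_at(pm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(-H), error = function(e) NULL)
  ok <- !is.null(V) && all(diag(V) > 0)
  if (ok) se[index] <- sqrt(diag(V))
  list(se = se, ok = ok, vcov = V, index = index)
}

#' @export
print.joint_frailty_fit <- function(x, ...) {
  cat("<joint_frailty_fit> n =", x$n,
      "| marginal logLik =", format(x$loglik_marginal, digits = 8),
      "| converged:", x$converged, "\n")
  print(hazard_ratio_table(x), n = Inf)
  fr <- x$frailty
  cat(sprintf("theta = %.3f (SE %.3f), eta = %.3f (SE %.3f), rho = %.3f\n",
              fr$estimate[1], fr$std.error[1], fr$estimate[2],
              fr$std.error[2], fr$estimate[3]))
  invisible(x)
}

#' @method tidy joint_frailty_fit
#' @export
tidy.joint_frailty_fit <- function(x, exponentiate = FALSE,
                                   conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- x$coefficients |>
    mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      conf.low = .data$estimate - z * .data$std.error,
      conf.high = .data$estimate + z * .data$std.error
    )
  if (exponentiate) {
    out <- out |>
      mutate(estimate = exp(.data$estimate),
             conf.low = exp(.data$conf.low),
             conf.high = exp(.data$conf.high))
  }
  out
}

#' @method glance joint_frailty_fit
#' @export
glance.joint_frailty_fit <- function(x, ...) {
  tibble(
    n = x$n,
    logLik = x$loglik_marginal,
    logLik_penalized = x$loglik_penalized,
    theta = x$frailty$estimate[1], eta = x$frailty$estimate[2],
    rho = x$frailty$estimate[3],
    converged = x$converged, n_iter = x$n_iter,
    gradient_norm = x$gradient_norm
  )
}

#' Hazard-ratio table with Wald confidence intervals
#'
#' Exponentiates each regression coefficient into a hazard ratio with a
#' Wald interval \eqn{\exp(\hat\beta \pm z \cdot SE)}. For a fitted model,
#' reference levels of categorical covariates are emitted as rows with
#' `hr = 1` and no interval. When standard errors are unavailable the
#' interval columns are `NA` and the result carries attribute
#' `ci_available = FALSE`.
#'
#' @param fit A `joint_frailty_fit`, or a data frame with columns
#'   `process`, `term`, `estimate`, `std.error`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `process`, `covariate`, `level`, `hr`,
#'   `ci_low`, `ci_high`, `reference`.
#' @export
hazard_ratio_table <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  coefs <- if (inherits(fit, "joint_frailty_fit")) fit$coefficients else
    as_tibble(fit)
  schema <- if (inherits(fit, "joint_frailty_fit")) fit$schema else NULL
  coefs <- coefs |> filter(!.data$term %in% c("alpha_1", "alpha_2"))
  split_term <- function(term) {
    parts <- strsplit(term, "=", fixed = TRUE)
    tibble(covariate = vapply(parts, `[[`, "", 1),
           level = vapply(parts, function(p) {
             if (length(p) > 1) paste(p[-1], collapse = "=") else NA_character_
           }, ""))
  }
  rows <- dplyr::bind_cols(coefs, split_term(coefs$term)) |>
    mutate(
      hr = exp(.data$estimate),
      ci_low = exp(.data$estimate - z * .data$std.error),
      ci_high = exp(.data$estimate + z * .data$std.error),
      reference = FALSE
    ) |>
    select("process", "covariate", "level", "hr", "ci_low", "ci_high",
           "reference")
  if (!is.null(schema)) {
    refs <- rows |>
      distinct(.data$process, .data$covariate) |>
      filter(.data$covariate %in% schema_covariates(schema)) |>
      filter(vapply(.data$covariate, function(nm) is_categorical(schema, nm),
                    logical(1))) |>
      mutate(level = vapply(.data$covariate, function(nm) schema[[nm]]$ref, ""),
             hr = 1, ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
    rows <- bind_rows(refs, rows) |>
      arrange(.data$process, .data$covariate, dplyr::desc(.data$reference))
  }
  attr(rows, "ci_available") <- !anyNA(coefs$std.error)
  rows
}

#' Plot fitted baseline hazards
#'
#' @param object A `joint_frailty_fit`.
#' @param n_points Curve resolution.
#' @param ... Unused.
#' @return A ggplot object with one curve per process.
#' @method autoplot joint_frailty_fit
#' @export
autoplot.joint_frailty_fit <- function(object, n_points = 200L, ...) {
  dfs <- purrr::imap(Filter(Negate(is.null), object$baselines),
                     function(b, nm) {
    t <- seq(b$boundary[1], b$boundary[2], length.out = n_points)
    tibble(process = nm, time = t, hazard = base_hazard(b, t))
  })
  ggplot2::ggplot(bind_rows(dfs),
                  ggplot2::aes(x = .data$time, y = .data$hazard,
                               colour = .data$process)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "baseline hazard", colour = "process")
}

#' Profile the smoothing weight kappa
#'
#' Refits the model over a grid of smoothing weights (applied to both
#' recurrent baselines) and reports the marginal log-likelihood, the
#' roughness of each fitted baseline, the effective degrees of freedom of
#' the spline blocks, and an AIC-style score
#' `logLik - edf` (larger is better). No kappa is selected automatically.
#'
#' @param history An [event_history()].
#' @param spec A [model_spec()]; its `kappa_1`/`kappa_2` are overridden by
#'   the grid.
#' @param kappas Numeric grid of smoothing weights (default
#'   `10^seq(0, 8, by = 2)`).
#' @param seed Passed to [fit_joint_frailty()].
#' @return A tibble with one row per kappa.
#' @export
scan_kappa <- function(history, spec = model_spec(), kappas = 10^seq(0, 8, 2),
                       seed = 1L) {
  rows <- purrr::map(kappas, function(k) {
    sp <- spec
    sp$kappa_1 <- k
    sp$kappa_2 <- k
    fit <- fit_joint_frailty(history, sp, seed = seed)
    edf <- tryCatch(spline_edf(fit, history, sp), error = function(e) NA_real_)
    tibble(
      kappa = k,
      loglik_marginal = fit$loglik_marginal,
      loglik_penalized = fit$loglik_penalized,
      roughness_1 = roughness_penalty(fit$baselines[["1"]]),
      roughness_2 = roughness_penalty(fit$baselines[["2"]]),
      edf = edf,
      score = fit$loglik_marginal - edf,
      converged = fit$converged
    )
  })
  bind_rows(rows)
}

# effective df of the two spline blocks: tr((H + Pen'')^{-1} H) with H the
# observed information of the marginal loglik restricted to log-coefficients
spline_edf <- function(fit, history, spec) {
  layout <- fit$layout
  skel <- unpack_par(fit$par, layout, joint_params(
    beta_1 = setNames(numeric(length(layout$beta_1)),
                      fit$coefficients$term[fit$coefficients$process == "1"]),
    beta_2 = setNames(numeric(length(layout$beta_2)),
                      fit$coefficients$term[fit$coefficients$process == "2"]),
    baseline_1 = fit$baselines[["1"]], baseline_2 = fit$baselines[["2"]],
    frailty = fit$frailty_cov))$params
  pd <- prepare_joint_data(history, joint_params(
    beta_1 = skel$beta_1, beta_2 = skel$beta_2,
    baseline_1 = fit$baselines[["1"]], baseline_2 = fit$baselines[["2"]],
    frailty = fit$frailty_cov))
  skel2 <- joint_params(beta_1 = skel$beta_1, beta_2 = skel$beta_2,
                        baseline_1 = fit$baselines[["1"]],
                        baseline_2 = fit$baselines[["2"]],
                        frailty = fit$frailty_cov)
  idx <- c(layout$c1, layout$c2)
  grad_at <- function(par) {
    up <- unpack_par(par, layout, skel2)
    eng <- marginal_engine(pd, up$params, quad_nodes = spec$quad_nodes,
                           want_grad = TRUE, c1 = up$c1, c2 = up$c2)
    pack_grad(eng$grad, layout, up, spec$frailty)[idx]
  }
  m <- length(idx)
  H <- matrix(0, m, m)
  for (j in seq_len(m)) {
    h <- 1e-4 * (1 + abs(fit$par[idx[j]]))
    pp <- fit$par; pp[idx[j]] <- pp[idx[j]] + h
    pm <- fit$par; pm[idx[j]] <- pm[idx[j]] - h
    H[, j] <- (grad_at(pp) - grad_at(pm)) / (2 * h)
  }
  H <- -(H + t(H)) / 2
  c1 <- fit$baselines[["1"]]$coefficients
  c2 <- fit$baselines[["2"]]$coefficients
  penhess_block <- function(P, k, cc) {
    if (k == 0) return(matrix(0, length(cc), length(cc)))
    k * (2 * diag(cc) %*% P %*% diag(cc) + 2 * diag(drop(P %*% cc) * cc))
  }
  Pen <- matrix(0, m, m)
  n1 <- length(c1)
  Pen[seq_len(n1), seq_len(n1)] <-
    penhess_block(penalty_matrix(fit$baselines[["1"]]), spec$kappa_1, c1)
  Pen[n1 + seq_along(c2), n1 + seq_along(c2)] <-
    penhess_block(penalty_matrix(fit$baselines[["2"]]), spec$kappa_2, c2)
  sum(diag(solve(H + Pen, H)))
}
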