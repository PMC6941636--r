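#' Bundle model parameters for likelihood evaluation
#'
#' A parameter set for the joint model: per-process regression
#' coefficients (named by dummy column, see [covariate_dummies()]),
#' baseline hazards (parametric [baseline_weibull()] /
#' [baseline_piecewise()] or fitted [mspline_basis()] objects), the
#' frailty covariance, and the optional terminal-event submodel whose
#' log-hazard is \eqn{\beta_D'Z + \alpha_1 u + \alpha_2 v}.
#'
#' @param beta_1,beta_2 Named numeric coefficient vectors (possibly empty).
#' @param baseline_1,baseline_2 Baseline hazard objects.
#' @param frailty A [frailty_covariance()].
#' @param beta_D,baseline_D,alpha Terminal-event parameters; a `NULL`
#'   `baseline_D` disables the terminal submodel.
#' @return A `joint_params` list.
#' @export
joint_params <- function(beta_1, beta_2, baseline_1, baseline_2,
                         frailty = frailty_covariance(0, 0),
                         beta_D = numeric(0), baseline_D = NULL,
                         alpha = c(0, 0)) {
  structure(
    list(beta_1 = beta_1, beta_2 = beta_2,
         baseline_1 = baseline_1, baseline_2 = baseline_2,
         frailty = frailty, beta_D = beta_D, baseline_D = baseline_D,
         alpha = alpha),
    class = "joint_params"
  )
}

subject_lp <- function(covrow, schema, beta) {
  if (!length(beta)) return(0)
  zx <- covariate_dummies(covrow, schema)
  miss <- setdiff(names(beta), colnames(zx))
  if (length(miss)) abort(paste0("beta names not in design: ",
                                 paste(miss, collapse = ", ")))
  sum(beta * zx[1, names(beta)])
}

#' Conditional log-likelihood of one subject given its frailties
#'
#' The counting-process log-likelihood conditional on the subject's
#' log-frailty pair \eqn{(u, v)}: for each recurrent process `k`, each
#' observed event contributes \eqn{\log h_{0k}(t) + \beta_k'Z + b_k} and
#' each at-risk interval contributes
#' \eqn{-e^{\beta_k'Z + b_k}[\Lambda_{0k}(stop) - \Lambda_{0k}(start)]},
#' with \eqn{b_1 = u}, \eqn{b_2 = v}; the terminal record (when modelled)
#' contributes the analogous terms with linear predictor
#' \eqn{\beta_D'Z + \alpha_1 u + \alpha_2 v}.
#'
#' @param history An [event_history()].
#' @param params A [joint_params()].
#' @param frailty Numeric `c(u, v)`.
#' @param subject Subject id; may be omitted when the history holds a
#'   single subject.
#' @return A single log-likelihood value.
#' @export
conditional_loglik_subject <- function(history, params, frailty,
                                       subject = NULL) {
  subs <- unique(history$covariates$subject_id)
  if (is.null(subject)) {
    if (length(subs) != 1) abort("specify `subject` for a multi-subject history")
    subject <- subs
  }
  ev <- history$events |> filter(.data$subject_id == subject)
  covrow <- history$covariates |> filter(.data$subject_id == subject)
  if (!nrow(ev)) abort(paste0("no records for subject ", subject))

  ll <- 0
  for (k in 1:2) {
    recs <- ev |> filter(.data$event_type == as.character(k))
    if (!nrow(recs)) next
    bl <- params[[paste0("baseline_", k)]]
    lp <- subject_lp(covrow, history$schema, params[[paste0("beta_", k)]]) +
      frailty[k]
    evt <- recs$stop[recs$status == 1L]
    if (length(evt)) ll <- ll + sum(log(base_hazard(bl, evt)) + lp)
    ll <- ll - exp(lp) * sum(base_cumhaz(bl, recs$stop) -
                               base_cumhaz(bl, recs$start))
  }
  if (!is.null(params$baseline_D)) {
    recs <- ev |> filter(.data$event_type == "D")
    if (nrow(recs)) {
      lp <- subject_lp(covrow, history$schema, params$beta_D) +
        params$alpha[1] * frailty[1] + params$alpha[2] * frailty[2]
      if (recs$status[1] == 1L) {
        ll <- ll + log(base_hazard(params$baseline_D, recs$stop[1])) + lp
      }
      ll <- ll - exp(lp) * (base_cumhaz(params$baseline_D, recs$stop[1]) -
                              base_cumhaz(params$baseline_D, recs$start[1]))
    }
  }
  ll
}

# ---- sufficient statistics ------------------------------------------------

# Per-subject sufficient statistics for the joint likelihood.
# For a fixed-parameter baseline, A (sum of log h0 at event times) and
# C (total baseline exposure) are scalars; for spline baselines the event
# basis rows and exposure-integral rows are stored so A and C can be
# recomputed for any coefficient vector.
prepare_joint_data <- function(history, params) {
  cv <- history$covariates
  subjects <- cv$subject_id
  n <- length(subjects)
  sub_idx <- setNames(seq_len(n), subjects)
  zx_full <- covariate_dummies(cv, history$schema)
  ev <- history$events

  prep_process <- function(type, beta, bl) {
    recs <- ev |> filter(.data$event_type == type)
    i_rec <- sub_idx[recs$subject_id]
    n_ev <- as.numeric(tabulate(i_rec[recs$status == 1L], n))
    Z <- zx_full[, names(beta), drop = FALSE]
    out <- list(type = type, n_ev = n_ev, Z = Z, p = length(beta))
    if (inherits(bl, "mspline_basis")) {
      evt <- recs$stop[recs$status == 1L]
      out$ev_subject <- i_rec[recs$status == 1L]
      out$M_ev <- mspline_eval(bl, evt)
      D <- mspline_integral(bl, recs$stop) - mspline_integral(bl, recs$start)
      out$D <- rowsum_matrix(D, i_rec, n)
      out$basis <- bl
    } else {
      evt <- recs$stop[recs$status == 1L]
      A <- if (length(evt)) {
        as.numeric(rowsum_vec(log(base_hazard(bl, evt)),
                              i_rec[recs$status == 1L], n))
      } else numeric(n)
      C <- as.numeric(rowsum_vec(base_cumhaz(bl, recs$stop) -
                                   base_cumhaz(bl, recs$start), i_rec, n))
      out$A <- A
      out$C <- C
    }
    out
  }

  pd <- list(
    n = n, subjects = subjects,
    p1 = prep_process("1", params$beta_1, params$baseline_1),
    p2 = prep_process("2", params$beta_2, params$baseline_2)
  )
  if (!is.null(params$baseline_D)) {
    recs <- ev |> filter(.data$event_type == "D")
    i_rec <- sub_idx[recs$subject_id]
    delta <- numeric(n); delta[i_rec] <- recs$status
    TD <- numeric(n); TD[i_rec] <- recs$stop
    Z <- zx_full[, names(params$beta_D), drop = FALSE]
    term <- list(delta = delta, n_ev = delta, TD = TD, Z = Z,
                 p = length(params$beta_D))
    bl <- params$baseline_D
    if (inherits(bl, "mspline_basis")) {
      dead <- which(delta == 1)
      term$ev_subject <- dead
      term$M_ev <- mspline_eval(bl, TD[dead])
      term$D <- rowsum_matrix(mspline_integral(bl, TD), seq_len(n), n)
      term$basis <- bl
    } else {
      A <- numeric(n)
      A[delta == 1] <- log(base_hazard(bl, TD[delta == 1]))
      term$A <- A
      term$C <- base_cumhaz(bl, TD)
    }
    pd$term <- term
  }
  pd
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

rowsum_matrix <- function(X, idx, n) {
  out <- matrix(0, n, ncol(X))
  if (nrow(X)) {
    s <- rowsum(X, idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# A (event log-hazard sum), C (baseline exposure) and, for gradients, the
# per-subject event-weighted basis rows for one process at coefficients ck
process_stats <- function(pp, ck = NULL, want_grad = FALSE) {
  if (!is.null(pp$A)) {
    return(list(A = pp$A, C = pp$C, Mgrad = NULL))
  }
  h_ev <- drop(pp$M_ev %*% ck)
  A <- rowsum_vec(log(h_ev), pp$ev_subject, length(pp$n_ev))
  C <- drop(pp$D %*% ck)
  Mgrad <- NULL
  if (want_grad) {
    Mgrad <- rowsum_matrix(pp$M_ev / h_ev, pp$ev_subject, length(pp$n_ev))
  }
  list(A = A, C = C, Mgrad = Mgrad)
}

# Gauss-Hermite grid over the active frailty dimensions.
# Returns standardized node matrix X (nodes x K), log-weights (including
# the Gaussian normalisation), or NULL when no dimension is active.
gh_grid <- function(active, quad_nodes) {
  K <- sum(active)
  if (K == 0) return(NULL)
  gh <- gauss_hermite(quad_nodes)
  if (K == 1) {
    X <- matrix(gh$x, ncol = 1)
    logw <- log(gh$w) - 0.5 * log(pi)
  } else {
    X <- as.matrix(expand.grid(gh$x, gh$x))
    logw <- log(expand.grid(gh$w, gh$w)[, 1]) +
      log(expand.grid(gh$w, gh$w)[, 2]) - log(pi)
  }
  list(X = X, logw = as.numeric(logw))
}

#' Marginal log-likelihood of the joint frailty model
#'
#' Integrates the conditional likelihood over the bivariate normal
#' log-frailty pair by fixed Gauss-Hermite quadrature after standardising
#' the pair through the Cholesky factor of its covariance
#' (`quad_nodes` nodes per dimension, log-sum-exp for stability). A zero
#' frailty variance collapses the corresponding dimension to a point mass
#' at zero, so with `theta = eta = 0` the result equals the sum of
#' conditional log-likelihoods at \eqn{(0, 0)}.
#'
#' @param history An [event_history()].
#' @param params A [joint_params()].
#' @param quad_nodes Gauss-Hermite nodes per dimension (>= 5 for a
#'   meaningful approximation; default 20).
#' @return The marginal log-likelihood.
#' @export
marginal_loglik <- function(history, params, quad_nodes = 20L) {
  pd <- prepare_joint_data(history, params)
  eng <- marginal_engine(pd, params, quad_nodes = quad_nodes)
  eng$value
}

# core evaluator; returns value and (optionally) analytic gradient pieces
marginal_engine <- function(pd, params, quad_nodes = 20L, want_grad = FALSE,
                            c1 = NULL, c2 = NULL, cD = NULL) {
  n <- pd$n
  fr <- params$frailty
  if (fr$theta < 0 || fr$eta < 0 || abs(fr$rho) >= 1) {
    abort("invalid frailty covariance")
  }
  active <- c(fr$theta > 0, fr$eta > 0)
  c1 <- c1 %||% params$baseline_1$coefficients
  c2 <- c2 %||% params$baseline_2$coefficients
  cD <- cD %||% params$baseline_D$coefficients

  s1 <- process_stats(pd$p1, c1, want_grad)
  s2 <- process_stats(pd$p2, c2, want_grad)
  lp1 <- if (pd$p1$p) drop(pd$p1$Z %*% params$beta_1) else numeric(n)
  lp2 <- if (pd$p2$p) drop(pd$p2$Z %*% params$beta_2) else numeric(n)
  has_term <- !is.null(pd$term)
  if (has_term) {
    sD <- process_stats(pd$term, cD, want_grad)
    lpD <- if (pd$term$p) drop(pd$term$Z %*% params$beta_D) else numeric(n)
    delta <- pd$term$delta
  }

  const_i <- s1$A + pd$p1$n_ev * lp1 + s2$A + pd$p2$n_ev * lp2
  if (has_term) const_i <- const_i + delta * (sD$A + lpD)

  grid <- gh_grid(active, quad_nodes)
  if (is.null(grid)) {
    # degenerate point mass at (0, 0)
    val <- sum(const_i) - sum(s1$C * exp(lp1)) - sum(s2$C * exp(lp2))
    if (has_term) val <- val - sum(sD$C * exp(lpD))
    out <- list(value = val)
    if (want_grad) {
      out$grad <- degenerate_grad(pd, params, s1, s2,
                                  if (has_term) sD else NULL,
                                  lp1, lp2, if (has_term) lpD else NULL,
                                  c1, c2, cD)
    }
    return(out)
  }

  # map standardized nodes to the active frailty dimensions
  L <- frailty_chol(fr)
  Lact <- L[active, active, drop = FALSE]
  Bact <- sqrt(2) * grid$X %*% t(Lact)       # nodes x K_active
  nq <- nrow(Bact)
  b1 <- if (active[1]) Bact[, 1] else rep(0, nq)
  b2 <- if (active[2]) Bact[, sum(active)] else rep(0, nq)

  E1 <- s1$C * exp(lp1)
  E2 <- s2$C * exp(lp2)
  G <- tcrossprod(pd$p1$n_ev, b1) - tcrossprod(E1, exp(b1)) +
    tcrossprod(pd$p2$n_ev, b2) - tcrossprod(E2, exp(b2))
  if (has_term) {
    bD <- params$alpha[1] * b1 + params$alpha[2] * b2
    ED <- sD$C * exp(lpD)
    G <- G + tcrossprod(delta, bD) - tcrossprod(ED, exp(bD))
  }
  G <- G + const_i
  Gw <- sweep(G, 2, grid$logw, "+")
  m <- apply(Gw, 1, max)
  li <- m + log(rowSums(exp(Gw - m)))
  out <- list(value = sum(li))
  if (!want_grad) return(out)

  P <- exp(Gw - li)                    # n x nq posterior node weights
  Ew1 <- drop(P %*% exp(b1))
  Ew2 <- drop(P %*% exp(b2))
  g <- list()
  r1bar <- pd$p1$n_ev - E1 * Ew1
  r2bar <- pd$p2$n_ev - E2 * Ew2
  g$beta_1 <- if (pd$p1$p) drop(crossprod(pd$p1$Z, r1bar)) else numeric(0)
  g$beta_2 <- if (pd$p2$p) drop(crossprod(pd$p2$Z, r2bar)) else numeric(0)
  if (!is.null(s1$Mgrad)) {
    g$c1 <- colSums(s1$Mgrad) - drop(crossprod(pd$p1$D, exp(lp1) * Ew1))
  }
  if (!is.null(s2$Mgrad)) {
    g$c2 <- colSums(s2$Mgrad) - drop(crossprod(pd$p2$D, exp(lp2) * Ew2))
  }
  if (has_term) {
    EwD <- drop(P %*% exp(bD))
    rDbar <- delta - ED * EwD
    g$beta_D <- if (pd$term$p) drop(crossprod(pd$term$Z, rDbar)) else numeric(0)
    if (!is.null(sD$Mgrad)) {
      g$cD <- colSums(sD$Mgrad) - drop(crossprod(pd$term$D, exp(lpD) * EwD))
    }
    # node-wise posterior sums of the terminal score, for alpha and Sigma
    SD <- drop(crossprod(P, delta)) - exp(bD) * drop(crossprod(P, ED))
    g$alpha <- c(sum(SD * b1), sum(SD * b2))
  }
  # Sigma block: score wrt the Cholesky factor, chained to the variances
  S1 <- drop(crossprod(P, pd$p1$n_ev)) - exp(b1) * drop(crossprod(P, E1))
  S2 <- drop(crossprod(P, pd$p2$n_ev)) - exp(b2) * drop(crossprod(P, E2))
  if (has_term) {
    S1 <- S1 + params$alpha[1] * SD
    S2 <- S2 + params$alpha[2] * SD
  }
  Smat <- cbind(S1, S2)[, active, drop = FALSE]
  dL <- sqrt(2) * crossprod(Smat, grid$X)    # K_active x K_active
  g$dL <- dL
  g$active <- active
  out$grad <- g
  out
}

degenerate_grad <- function(pd, params, s1, s2, sD, lp1, lp2, lpD,
                            c1, c2, cD) {
  g <- list()
  r1 <- pd$p1$n_ev - s1$C * exp(lp1)
  r2 <- pd$p2$n_ev - s2$C * exp(lp2)
  g$beta_1 <- if (pd$p1$p) drop(crossprod(pd$p1$Z, r1)) else numeric(0)
  g$beta_2 <- if (pd$p2$p) drop(crossprod(pd$p2$Z, r2)) else numeric(0)
  if (!is.null(s1$Mgrad)) {
    g$c1 <- colSums(s1$Mgrad) - drop(crossprod(pd$p1$D, exp(lp1)))
  }
  if (!is.null(s2$Mgrad)) {
    g$c2 <- colSums(s2$Mgrad) - drop(crossprod(pd$p2$D, exp(lp2)))
  }
  if (!is.null(sD)) {
    rD <- pd$term$delta - sD$C * exp(lpD)
    g$beta_D <- if (pd$term$p) drop(crossprod(pd$term$Z, rD)) else numeric(0)
    if (!is.null(sD$Mgrad)) {
      g$cD <- colSums(sD$Mgrad) - drop(crossprod(pd$term$D, exp(lpD)))
    }
    g$alpha <- c(0, 0)
  }
  g$active <- c(FALSE, FALSE)
  g
}

#' Dense-grid oracle for the marginal log-likelihood
#'
#' Approximates the same frailty integral as [marginal_loglik()] by a
#' tensor-product trapezoid rule on a grid spanning
#' `grid_span` standard deviations in each active frailty dimension.
#' Intended as an independent cross-check on small datasets (cost grows
#' with `grid_points^2`); the integrand is assembled directly from the
#' subject records, independently of the quadrature path.
#'
#' @inheritParams marginal_loglik
#' @param grid_span Half-width of the grid in frailty standard deviations.
#' @param grid_points Number of grid points per dimension.
#' @return The log-likelihood approximation.
#' @export
oracle_marginal_loglik <- function(history, params, grid_span = 6,
                                   grid_points = 400L) {
  fr <- params$frailty
  subjects <- unique(history$covariates$subject_id)
  active <- c(fr$theta > 0, fr$eta > 0)
  if (!any(active)) {
    return(sum(vapply(subjects, function(s) {
      conditional_loglik_subject(history, params, c(0, 0), subject = s)
    }, numeric(1))))
  }

  # per-subject sufficient statistics, straight from the records
  stats_for <- function(s) {
    ev <- history$events |> filter(.data$subject_id == s)
    covrow <- history$covariates |> filter(.data$subject_id == s)
    st <- list()
    for (k in 1:2) {
      recs <- ev |> filter(.data$event_type == as.character(k))
      bl <- params[[paste0("baseline_", k)]]
      lp <- subject_lp(covrow, history$schema, params[[paste0("beta_", k)]])
      evt <- recs$stop[recs$status == 1L]
      st[[paste0("A", k)]] <- if (length(evt))
        sum(log(base_hazard(bl, evt))) + length(evt) * lp else 0
      st[[paste0("n", k)]] <- length(evt)
      st[[paste0("E", k)]] <- exp(lp) *
        sum(base_cumhaz(bl, recs$stop) - base_cumhaz(bl, recs$start))
    }
    if (!is.null(params$baseline_D)) {
      recs <- ev |> filter(.data$event_type == "D")
      lp <- subject_lp(covrow, history$schema, params$beta_D)
      st$dD <- if (nrow(recs)) recs$status[1] else 0L
      st$AD <- if (nrow(recs) && recs$status[1] == 1L)
        log(base_hazard(params$baseline_D, recs$stop[1])) + lp else 0
      st$ED <- if (nrow(recs)) exp(lp) *
        (base_cumhaz(params$baseline_D, recs$stop[1]) -
           base_cumhaz(params$baseline_D, recs$start[1])) else 0
    }
    st
  }

  np <- grid_points
  s1 <- sqrt(fr$theta); s2 <- sqrt(fr$eta)
  u <- if (active[1]) seq(-grid_span * s1, grid_span * s1, length.out = np) else 0
  v <- if (active[2]) seq(-grid_span * s2, grid_span * s2, length.out = np) else 0
  wu <- if (active[1]) trapezoid_weights(np) * diff(u)[1] else 1
  wv <- if (active[2]) trapezoid_weights(np) * diff(v)[1] else 1

  # log of the normal density over the grid
  if (all(active)) {
    Sig <- frailty_sigma(fr)
    Si <- solve(Sig)
    ld <- as.numeric(determinant(Sig)$modulus)
    lphi <- -0.5 * (outer(u^2 * Si[1, 1], v^2 * Si[2, 2], "+") +
                      2 * Si[1, 2] * outer(u, v)) - log(2 * pi) - 0.5 * ld
  } else if (active[1]) {
    lphi <- matrix(dnorm(u, sd = s1, log = TRUE), ncol = 1)
  } else {
    lphi <- matrix(dnorm(v, sd = s2, log = TRUE), nrow = 1)
  }
  lw <- lphi + log(outer(as.numeric(wu), as.numeric(wv)))

  total <- 0
  for (s in subjects) {
    st <- stats_for(s)
    gu <- st$A1 + st$n1 * u - st$E1 * exp(u)
    gv <- st$A2 + st$n2 * v - st$E2 * exp(v)
    G <- outer(gu, gv, "+")
    if (!is.null(params$baseline_D)) {
      bD <- outer(params$alpha[1] * u, params$alpha[2] * v, "+")
      G <- G + st$dD * (st$AD + bD) - st$ED * exp(bD)
    }
    lsum <- G + lw
    m <- max(lsum)
    total <- total + m + log(sum(exp(lsum - m)))
  }
  total
}

trapezoid_weights <- function(np) {
  w <- rep(1, np)
  w[c(1, np)] <- 0.5
  w
}
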