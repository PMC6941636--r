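#' M-spline basis for a nonnegative baseline hazard
#'
#' The baseline hazard is represented as \eqn{h_0(t) = \sum_j c_j M_j(t)}
#' where the \eqn{M_j} are M-splines (B-splines rescaled to integrate to
#' one over their support); any coefficient vector with \eqn{c_j \ge 0}
#' yields a nonnegative hazard. The cumulative hazard uses the exact
#' closed-form integrals \eqn{I_j} of the basis functions (I-splines), so
#' \eqn{\Lambda_0(t) = \sum_j c_j I_j(t)} is computed without numerical
#' quadrature.
#'
#' Boundary knots sit at 0 and the maximum follow-up time; interior knots
#' are placed at equispaced quantiles of the supplied (event) times.
#'
#' @param times Observed event times used to place interior knots; at
#'   least 2 distinct values.
#' @param n_knots Number of interior knots (default 7).
#' @param order Spline order (polynomial degree + 1); default 4 (cubic).
#'   Order 1 with 0 interior knots gives a constant hazard.
#' @param boundary Optional `c(lower, upper)` boundary knots; default
#'   `c(0, max(times))`.
#' @param coefficients Optional nonnegative coefficient vector (length
#'   `n_knots + order`).
#' @return An `mspline_basis` object.
#' @export
mspline_basis <- function(times, n_knots = 7L, order = 4L, boundary = NULL,
                          coefficients = NULL) {
  stopifnot(order >= 1, n_knots >= 0)
  tt <- sort(unique(as.numeric(times)))
  if (length(tt) < 2 && is.null(boundary)) {
    abort("at least 2 distinct times are needed to place boundary knots")
  }
  boundary <- boundary %||% c(0, max(tt))
  if (n_knots > 0 && length(tt) < n_knots) {
    abort(paste0("only ", length(tt), " distinct times for ", n_knots,
                 " interior knots; use fewer knots"))
  }
  interior <- if (n_knots > 0) {
    q <- quantile(tt, probs = seq_len(n_knots) / (n_knots + 1), names = FALSE,
                  type = 7)
    q <- pmin(pmax(q, boundary[1]), boundary[2])
    unique(q)
  } else numeric(0)
  if (length(interior) < n_knots) {
    abort("tied time quantiles collapse interior knots; use fewer knots")
  }
  knots_ext <- c(rep(boundary[1], order), interior, rep(boundary[2], order))
  nbasis <- length(knots_ext) - order
  b <- structure(
    list(order = as.integer(order), boundary = boundary, interior = interior,
         knots_ext = knots_ext, nbasis = nbasis, coefficients = NULL),
    class = "mspline_basis"
  )
  if (!is.null(coefficients)) b <- set_coefficients(b, coefficients)
  b
}

#' Set the coefficients of an M-spline basis
#' @param basis An [mspline_basis()].
#' @param coefficients Nonnegative numeric vector, one entry per basis
#'   function.
#' @return The basis with coefficients set.
#' @export
set_coefficients <- function(basis, coefficients) {
  if (length(coefficients) != basis$nbasis) {
    abort(paste0("expected ", basis$nbasis, " coefficients, got ",
                 length(coefficients)))
  }
  if (any(coefficients < 0)) abort("M-spline coefficients must be nonnegative")
  basis$coefficients <- as.numeric(coefficients)
  basis
}

#' @export
print.mspline_basis <- function(x, ...) {
  cat("<mspline_basis> order ", x$order, ", ", length(x$interior),
      " interior knots on [", x$boundary[1], ", ", x$boundary[2], "], ",
      x$nbasis, " basis functions",
      if (is.null(x$coefficients)) " (coefficients unset)" else "", "\n",
      sep = "")
  invisible(x)
}

check_support <- function(basis, t, tol = 1e-8) {
  if (any(t < basis$boundary[1] - tol) || any(t > basis$boundary[2] + tol)) {
    abort(paste0("time outside baseline support [", basis$boundary[1], ", ",
                 basis$boundary[2], "]"))
  }
  pmin(pmax(t, basis$boundary[1]), basis$boundary[2])
}

#' Evaluate M-spline basis functions
#'
#' @param basis An [mspline_basis()].
#' @param t Times inside the support.
#' @param deriv Derivative order (0, 1 or 2).
#' @return Matrix `length(t)` by `nbasis`.
#' @export
mspline_eval <- function(basis, t, deriv = 0L) {
  t <- check_support(basis, t)
  widths <- basis$knots_ext[seq_len(basis$nbasis) + basis$order] -
    basis$knots_ext[seq_len(basis$nbasis)]
  B <- splines::splineDesign(basis$knots_ext, t, ord = basis$order,
                             derivs = rep(as.integer(deriv), length(t)),
                             outer.ok = TRUE)
  sweep(B, 2, basis$order / widths, "*")
}

#' Exact integrals of M-spline basis functions (I-splines)
#'
#' \eqn{I_j(t) = \int_0^t M_j(s)\,ds}, computed in closed form from the
#' order-(k+1) B-spline recursion; each column is nondecreasing from 0
#' to 1.
#'
#' @inheritParams mspline_eval
#' @return Matrix `length(t)` by `nbasis`.
#' @export
mspline_integral <- function(basis, t) {
  t <- check_support(basis, t)
  nb <- basis$nbasis
  kts2 <- c(basis$boundary[1], basis$knots_ext, basis$boundary[2])
  B2 <- splines::splineDesign(kts2, t, ord = basis$order + 1L, outer.ok = TRUE)
  # I_j(t) = sum of order-(k+1) normalized B-splines with index > j
  rev_cs <- t(apply(B2[, (nb + 1):1, drop = FALSE], 1, cumsum))
  rev_cs[, nb:1, drop = FALSE]
}

#' Baseline hazard / cumulative hazard from a fitted basis
#' @export
#' @rdname base_hazard
base_hazard.mspline_basis <- function(b, t) {
  if (is.null(b$coefficients)) abort("basis coefficients are unset")
  drop(mspline_eval(b, t) %*% b$coefficients)
}

#' @export
#' @rdname base_hazard
base_cumhaz.mspline_basis <- function(b, t) {
  if (is.null(b$coefficients)) abort("basis coefficients are unset")
  drop(mspline_integral(b, t) %*% b$coefficients)
}

#' Curvature penalty matrix and roughness of a spline hazard
#'
#' The roughness of the baseline hazard is
#' \eqn{\int_0^T h_0''(t)^2 dt = c' P c} with
#' \eqn{P_{jl} = \int M_j'' M_l''}. Because second derivatives of an
#' order-`k` spline are piecewise polynomials of degree `k - 3`, the Gram
#' matrix is computed exactly by per-interval Gauss-Legendre quadrature
#' with enough nodes for the polynomial degree.
#'
#' @param basis An [mspline_basis()] with `order >= 3`.
#' @return `penalty_matrix()`: the `nbasis` by `nbasis` matrix `P`;
#'   `roughness_penalty()`: the scalar `c' P c` for the basis coefficients.
#' @export
penalty_matrix <- function(basis) {
  if (basis$order < 3) {
    abort("curvature penalty needs order >= 3 (piecewise-smooth second derivative)")
  }
  deg <- basis$order - 3L            # degree of h'' pieces
  ngauss <- max(1L, ceiling((2L * deg + 1L) / 2L))
  gl <- gauss_legendre(ngauss)
  dk <- unique(basis$knots_ext)
  P <- matrix(0, basis$nbasis, basis$nbasis)
  for (iv in seq_len(length(dk) - 1L)) {
    a <- dk[iv]; b2 <- dk[iv + 1L]
    h <- (b2 - a) / 2
    for (g in seq_along(gl$x)) {
      x <- (a + b2) / 2 + h * gl$x[g]
      m2 <- mspline_eval(basis, x, deriv = 2L)
      P <- P + h * gl$w[g] * crossprod(m2)
    }
  }
  P
}

#' @rdname penalty_matrix
#' @export
roughness_penalty <- function(basis) {
  if (is.null(basis$coefficients)) abort("basis coefficients are unset")
  P <- penalty_matrix(basis)
  drop(crossprod(basis$coefficients, P %*% basis$coefficients))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch)
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}
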