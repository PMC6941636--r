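#' Parametric baseline hazards for simulation
#'
#' Two closed-form families are supported so that event times can be drawn
#' by exact inversion of the cumulative hazard, with no root-finding:
#'
#' * `baseline_weibull(shape, scale)`: \eqn{\Lambda_0(t) = (t/scale)^{shape}}.
#' * `baseline_piecewise(rates, cuts)`: constant hazard `rates[j]` on the
#'   interval from `cuts[j-1]` to `cuts[j]` (with implicit 0 and Inf
#'   endpoints).
#'
#' @param shape,scale Weibull shape (> 0) and scale (> 0, time units).
#' @return A `baseline_hazard` object.
#' @export
baseline_weibull <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(family = "weibull", shape = shape, scale = scale),
            class = "baseline_hazard")
}

#' @rdname baseline_weibull
#' @param rates Positive hazard rates, one per piece.
#' @param cuts Ascending interior cut points (length `length(rates) - 1`).
#' @export
baseline_piecewise <- function(rates, cuts = numeric(0)) {
  stopifnot(all(rates > 0), length(cuts) == length(rates) - 1)
  if (length(cuts) && (any(diff(cuts) <= 0) || any(cuts <= 0))) {
    abort("cuts must be positive and strictly ascending")
  }
  structure(list(family = "piecewise", rates = as.numeric(rates),
                 cuts = as.numeric(cuts)),
            class = "baseline_hazard")
}

#' Evaluate a baseline hazard
#'
#' `base_hazard()` gives \eqn{h_0(t)}, `base_cumhaz()` gives
#' \eqn{\Lambda_0(t)} and `base_invcumhaz()` its exact inverse. Methods
#' exist for the parametric [baseline_weibull()] / [baseline_piecewise()]
#' families and (except inversion) for fitted [mspline_basis()] objects.
#'
#' @param b A baseline-hazard object.
#' @param t Nonnegative time(s).
#' @param H Nonnegative cumulative-hazard value(s).
#' @return Numeric vector.
#' @export
base_hazard <- function(b, t) UseMethod("base_hazard")

#' @rdname base_hazard
#' @export
base_cumhaz <- function(b, t) UseMethod("base_cumhaz")

#' @rdname base_hazard
#' @export
base_invcumhaz <- function(b, H) UseMethod("base_invcumhaz")

#' @export
base_hazard.baseline_hazard <- function(b, t) {
  switch(b$family,
    weibull = (b$shape / b$scale) * (pmax(t, 0) / b$scale)^(b$shape - 1),
    piecewise = {
      idx <- findInterval(t, b$cuts) + 1L
      b$rates[idx]
    }
  )
}

#' @export
base_cumhaz.baseline_hazard <- function(b, t) {
  t <- pmax(t, 0)
  switch(b$family,
    weibull = (t / b$scale)^b$shape,
    piecewise = {
      bounds <- c(0, b$cuts, Inf)
      out <- numeric(length(t))
      for (j in seq_along(b$rates)) {
        lo <- bounds[j]; hi <- bounds[j + 1]
        out <- out + b$rates[j] * pmax(pmin(t, hi) - lo, 0)
      }
      out
    }
  )
}

#' @export
base_invcumhaz.baseline_hazard <- function(b, H) {
  stopifnot(all(H >= 0))
  switch(b$family,
    weibull = b$scale * H^(1 / b$shape),
    piecewise = {
      bounds <- c(0, b$cuts)
      Hb <- base_cumhaz(b, c(b$cuts, Inf))  # cumulative at cut points (last Inf)
      Hlo <- c(0, head(Hb, -1))
      idx <- findInterval(H, Hlo, rightmost.closed = FALSE)
      bounds[idx] + (H - Hlo[idx]) / b$rates[idx]
    }
  )
}

#' @export
print.baseline_hazard <- function(x, ...) {
  if (x$family == "weibull") {
    cat("<baseline_hazard> Weibull(shape =", x$shape, ", scale =", x$scale, ")\n")
  } else {
    cat("<baseline_hazard> piecewise-constant; rates:",
        paste(signif(x$rates, 4), collapse = ", "),
        if (length(x$cuts)) paste0("cuts: ", paste(x$cuts, collapse = ", ")) else "",
        "\n")
  }
  invisible(x)
}
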