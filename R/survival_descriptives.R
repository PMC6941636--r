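#' Disease-free survival times per subject
#'
#' Disease-free survival is the time from the origin (surgery) to the
#' first recurrence of either recurrent type; subjects with no recurrence
#' are censored at their last follow-up stop (including any terminal
#' record).
#'
#' @param history An [event_history()].
#' @return A tibble with one row per subject: `subject_id`, `time`,
#'   `status` (1 = first recurrence observed at `time`, 0 = censored).
#' @export
disease_free_times <- function(history) {
  ev <- history$events
  subjects <- unique(history$covariates$subject_id)
  no_rec <- setdiff(subjects, unique(ev$subject_id))
  if (length(no_rec)) {
    abort(paste0("subject(s) with no event records: ",
                 paste(head(no_rec, 3), collapse = ", ")))
  }
  ev |>
    group_by(.data$subject_id) |>
    summarise(
      time = {
        rec <- .data$event_type != "D" & .data$status == 1L
        if (any(rec)) min(.data$stop[rec]) else max(.data$stop)
      },
      status = as.integer(any(.data$event_type != "D" & .data$status == 1L))
    ) |>
    ungroup()
}

#' Kaplan-Meier product-limit estimator with Greenwood standard errors
#'
#' At tied times, events are resolved before censorings (so censored
#' subjects at an event time are still in the risk set at that time). The
#' Greenwood standard error is
#' \eqn{\hat S(t)\sqrt{\sum_{t_j \le t} d_j / (n_j (n_j - d_j))}}.
#'
#' @param data Data frame with columns `time` (> 0) and `status`
#'   (1 = event, 0 = censored), one row per subject; extra columns are
#'   ignored.
#' @return A `km_estimate`: a tibble with one row per distinct observed
#'   time, columns `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `std_err`.
#' @export
kaplan_meier <- function(data) {
  if (!all(c("time", "status") %in% names(data))) {
    abort("`data` must have columns `time` and `status`")
  }
  if (nrow(data) == 0) abort("at least one (time, status) pair is required")
  time <- as.numeric(data$time)
  status <- as.integer(data$status)
  if (any(time <= 0)) abort("times must be strictly positive")
  tt <- sort(unique(time))
  n_event <- vapply(tt, function(t) sum(time == t & status == 1L), integer(1))
  n_censor <- vapply(tt, function(t) sum(time == t & status == 0L), integer(1))
  n_risk <- vapply(tt, function(t) sum(time >= t), integer(1))
  frac <- ifelse(n_risk > 0, 1 - n_event / n_risk, 1)
  survival <- cumprod(frac)
  gw_term <- ifelse(n_event > 0 & n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), 0)
  # where S drops to 0 the Greenwood variance is taken as 0 (S * sqrt(...) with S = 0)
  std_err <- survival * sqrt(cumsum(gw_term))
  out <- tibble(time = tt, n_risk = n_risk, n_event = n_event,
                n_censor = n_censor, survival = survival, std_err = std_err)
  class(out) <- c("km_estimate", class(out))
  out
}

#' Look up the survival curve at given times
#'
#' The product-limit curve is a right-continuous step function: before the
#' first observed time the survival is 1 with standard error 0; beyond the
#' last time the final value is carried forward.
#'
#' @param km A [kaplan_meier()] result.
#' @param t Nonnegative time(s).
#' @return A tibble with columns `time`, `survival`, `std_err`.
#' @export
survival_at <- function(km, t) {
  stopifnot(all(t >= 0))
  idx <- findInterval(t, km$time)
  tibble(
    time = t,
    survival = ifelse(idx == 0, 1, km$survival[pmax(idx, 1)]),
    std_err = ifelse(idx == 0, 0, km$std_err[pmax(idx, 1)])
  )
}

#' Median survival time
#'
#' The smallest observed time at which the product-limit curve reaches
#' 0.5 or below; `NA` when the curve never does.
#'
#' @param km A [kaplan_meier()] result.
#' @return A single time, or `NA_real_` when the median is undefined.
#' @export
median_survival <- function(km) {
  hit <- which(km$survival <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  km$time[hit[1]]
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("<km_estimate> ", sum(x$n_event), " events among ",
      x$n_risk[1], " subjects; median ", format(median_survival(x)), "\n", sep = "")
  NextMethod()
}

#' @method tidy km_estimate
#' @export
tidy.km_estimate <- function(x, ...) {
  tibble(time = x$time, n.risk = x$n_risk, n.event = x$n_event,
         n.censor = x$n_censor, estimate = x$survival, std.error = x$std_err)
}

#' @method glance km_estimate
#' @export
glance.km_estimate <- function(x, ...) {
  tibble(n = x$n_risk[1], events = sum(x$n_event),
         median = median_survival(x))
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A [kaplan_meier()] result.
#' @param conf Shade pointwise Greenwood +-1.96 SE bands (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, conf = TRUE, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival),
               std_err = c(0, object$std_err))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "disease-free survival")
  if (conf) {
    df <- df |>
      mutate(lo = pmax(.data$survival - 1.96 * .data$std_err, 0),
             hi = pmin(.data$survival + 1.96 * .data$std_err, 1))
    p <- p +
      ggplot2::geom_step(data = df, ggplot2::aes(y = .data$lo),
                         linetype = "dashed", colour = "grey50") +
      ggplot2::geom_step(data = df, ggplot2::aes(y = .data$hi),
                         linetype = "dashed", colour = "grey50")
  }
  p
}

# half-up decimal rounding (round() in R rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Frequency table of categorical covariates
#'
#' Counts and percentages per declared category, in declared order, with
#' percentages rounded half-up to one decimal (so a printed count of
#' 233 out of 342 yields 68.1).
#'
#' @param data Covariate data frame (one row per subject), or an
#'   [event_history()] whose covariate table is used.
#' @param variables Covariate names to tabulate (default: all categorical
#'   covariates in the schema).
#' @param schema A [cov_schema()]; taken from `data` when it is an
#'   `event_history`.
#' @return A `frequency_table`: a tibble with columns `variable`, `level`,
#'   `n`, `percent`, and attribute `total_n`.
#' @export
frequency_table <- function(data, variables = NULL, schema = NULL) {
  if (inherits(data, "event_history")) {
    schema <- schema %||% data$schema
    data <- data$covariates
  }
  if (is.null(schema)) {
    abort("a covariate schema is required (or pass an event_history)")
  }
  variables <- variables %||%
    Filter(function(nm) is_categorical(schema, nm), schema_covariates(schema))
  bad <- setdiff(variables, schema_covariates(schema))
  if (length(bad)) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")))
  }
  total_n <- nrow(data)
  rows <- purrr::map(variables, function(nm) {
    if (!nm %in% names(data)) abort(paste0("variable '", nm, "' not in data"))
    lv <- schema[[nm]]$levels
    v <- as.character(data[[nm]])
    cnt <- unname(vapply(lv, function(l) sum(v == l, na.rm = TRUE), integer(1)))
    tibble(variable = nm, level = lv, n = cnt,
           percent = round_half_up(100 * cnt / total_n, 1))
  })
  out <- bind_rows(rows)
  attr(out, "total_n") <- total_n
  class(out) <- c("frequency_table", class(out))
  out
}
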