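#' Build an event-history object from counting-process tables
#'
#' An `event_history` bundles the long-format counting-process event table
#' (one row per at-risk interval per event type per subject), the one-row-
#' per-subject covariate table, and the covariate schema. Event types are
#' `"1"` (first recurrent process, e.g. local recurrence), `"2"` (second
#' recurrent process, e.g. metastasis) and optionally `"D"` (terminal
#' event). Intervals are half-open `(start, stop]`; an event occurs at
#' `stop` when `status == 1`.
#'
#' @param events Data frame with columns `subject_id`, `event_type`,
#'   `start`, `stop`, `status`.
#' @param covariates Data frame with column `subject_id` plus covariate
#'   columns; exactly one row per subject.
#' @param schema A [cov_schema()]; defaults to the columns of `covariates`
#'   treated as categorical with observed levels (alphabetical reference).
#' @param time_unit Label for the time axis (default `"months"`).
#' @param validate Abort if [validate_counting_process()] reports
#'   violations (default `TRUE`).
#'
#' @return An `event_history` object (list with tibbles `events`,
#'   `covariates`, plus `schema` and `time_unit`); rows are normalised to
#'   (subject, type, start) order.
#' @export
event_history <- function(events, covariates, schema = NULL,
                          time_unit = "months", validate = TRUE) {
  req <- c("subject_id", "event_type", "start", "stop", "status")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    abort(paste0("events table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"subject_id" %in% names(covariates)) {
    abort("covariates table is missing column: subject_id")
  }
  events <- as_tibble(events) |>
    mutate(
      subject_id = as.character(.data$subject_id),
      event_type = as.character(.data$event_type),
      start = as.numeric(.data$start),
      stop = as.numeric(.data$stop),
      status = as.integer(.data$status)
    ) |>
    select(dplyr::all_of(req)) |>
    arrange(.data$subject_id, .data$event_type, .data$start)
  covariates <- as_tibble(covariates) |>
    mutate(subject_id = as.character(.data$subject_id)) |>
    arrange(.data$subject_id)
  if (is.null(schema)) {
    covs <- setdiff(names(covariates), "subject_id")
    args <- lapply(covs, function(nm) {
      v <- covariates[[nm]]
      if (is.numeric(v)) NULL else sort(unique(as.character(v)))
    })
    names(args) <- covs
    schema <- do.call(cov_schema, args)
  }
  h <- structure(
    list(events = events, covariates = covariates, schema = schema,
         time_unit = time_unit),
    class = "event_history"
  )
  if (validate) {
    v <- validate_counting_process(h)
    if (nrow(v)) {
      abort(paste0(
        "invalid counting-process data (", nrow(v), " violation(s)); first: ",
        v$rule[[1]], " [subject ", v$subject_id[[1]], ", type ",
        v$event_type[[1]], "]"
      ))
    }
  }
  h
}

#' @export
print.event_history <- function(x, ...) {
  cat("<event_history> ", n_subjects(x), " subjects, ",
      nrow(x$events), " at-risk intervals (time in ", x$time_unit, ")\n", sep = "")
  tab <- x$events |>
    group_by(.data$event_type) |>
    summarise(intervals = n(), events = sum(.data$status))
  print(tab)
  invisible(x)
}

#' Number of subjects in an event history
#' @param history An [event_history()].
#' @return Integer count.
#' @export
n_subjects <- function(history) length(unique(history$covariates$subject_id))

recurrent_types <- function(history) {
  setdiff(sort(unique(history$events$event_type)), "D")
}

#' Check the counting-process invariants of an event history
#'
#' Verifies, without raising, that every at-risk interval satisfies
#' `start < stop`, that intervals within a (subject, event type) pair do
#' not overlap, that each subject has at most one terminal record and no
#' recurrent interval extends past the terminal/censoring stop, that every
#' subject appears exactly once in the covariate table with no missing
#' values and only declared levels, and that every subject has at least one
#' record for each recurrent event type present in the data.
#'
#' @param history An [event_history()] (or a bare list with the same
#'   elements).
#' @return A tibble of violations with columns `subject_id`, `event_type`,
#'   `rule`, `detail`; zero rows when the history is valid.
#' @export
validate_counting_process <- function(history) {
  ev <- history$events
  cv <- history$covariates
  schema <- history$schema
  viol <- list()
  add <- function(subject, type, rule, detail = "") {
    viol[[length(viol) + 1]] <<- tibble(
      subject_id = as.character(subject), event_type = as.character(type),
      rule = rule, detail = detail
    )
  }

  bad_type <- !ev$event_type %in% c("1", "2", "D")
  for (i in which(bad_type)) {
    add(ev$subject_id[i], ev$event_type[i], "unknown event type")
  }
  bad_status <- !ev$status %in% c(0L, 1L)
  for (i in which(bad_status)) {
    add(ev$subject_id[i], ev$event_type[i], "status must be 0 or 1")
  }
  neg <- which(!is.na(ev$start) & ev$start < 0)
  for (i in neg) add(ev$subject_id[i], ev$event_type[i], "start must be >= 0")
  bad_ord <- which(!(ev$start < ev$stop))
  for (i in bad_ord) {
    add(ev$subject_id[i], ev$event_type[i], "start < stop",
        paste0("(", ev$start[i], ", ", ev$stop[i], "]"))
  }

  split_idx <- split(seq_len(nrow(ev)), paste(ev$subject_id, ev$event_type, sep = "\r"))
  for (idx in split_idx) {
    sub <- ev$subject_id[idx[1]]
    typ <- ev$event_type[idx[1]]
    if (typ == "D" && length(idx) > 1) {
      add(sub, "D", "at most one terminal record per subject")
    }
    if (length(idx) > 1) {
      o <- idx[order(ev$start[idx])]
      gaps <- ev$start[o][-1] - ev$stop[o][-length(o)]
      if (any(gaps < -1e-12)) add(sub, typ, "overlap", "risk intervals overlap")
    }
  }

  # recurrent intervals must not extend past the subject's terminal stop
  term <- ev |> filter(.data$event_type == "D")
  if (nrow(term)) {
    term_stop <- setNames(term$stop, term$subject_id)
    rec <- ev |> filter(.data$event_type != "D")
    over <- which(rec$subject_id %in% names(term_stop) &
                    rec$stop > term_stop[rec$subject_id] + 1e-9)
    for (i in over) {
      add(rec$subject_id[i], rec$event_type[i],
          "recurrent interval extends past terminal stop")
    }
  }

  ev_subj <- unique(ev$subject_id)
  dup <- cv$subject_id[duplicated(cv$subject_id)]
  for (s in unique(dup)) add(s, NA, "duplicate covariate row")
  for (s in setdiff(ev_subj, cv$subject_id)) add(s, NA, "subject missing from covariates")
  rtypes <- setdiff(unique(ev$event_type), "D")
  for (s in ev_subj) {
    have <- unique(ev$event_type[ev$subject_id == s])
    for (typ in setdiff(rtypes, have)) {
      add(s, typ, "no record for modeled event type")
    }
  }

  if (!is.null(schema)) {
    for (nm in intersect(schema_covariates(schema), names(cv))) {
      v <- cv[[nm]]
      miss <- which(is.na(v))
      for (i in miss) add(cv$subject_id[i], NA, "missing covariate value", nm)
      if (is_categorical(schema, nm)) {
        bad <- which(!is.na(v) & !as.character(v) %in% schema[[nm]]$levels)
        for (i in bad) {
          add(cv$subject_id[i], NA, "undeclared covariate level",
              paste0(nm, "=", v[i]))
        }
      }
    }
  }

  if (length(viol)) bind_rows(viol) else
    tibble(subject_id = character(), event_type = character(),
           rule = character(), detail = character())
}

#' Read an event history from CSV files
#'
#' Expects an events CSV with columns
#' `subject_id,event_type,start,stop,status` and a covariates CSV with
#' `subject_id` plus the covariates declared in `schema`. Files are UTF-8,
#' comma-separated, with a header row.
#'
#' @param events_path,covariates_path CSV file paths.
#' @param schema A [cov_schema()] (or path to a YAML schema file). `NULL`
#'   infers a schema from the data.
#' @return A validated [event_history()].
#' @export
read_event_history <- function(events_path, covariates_path, schema = NULL) {
  if (is.character(schema)) schema <- read_cov_schema(schema)
  if (!file.exists(events_path)) abort(paste0("file not found: ", events_path))
  if (!file.exists(covariates_path)) {
    abort(paste0("file not found: ", covariates_path))
  }
  # base strtod parsing is correctly rounded, so 17-significant-digit text
  # round-trips doubles exactly
  ev <- as_tibble(utils::read.csv(events_path, colClasses = "character",
                                  check.names = FALSE))
  missing_cols <- setdiff(c("subject_id", "event_type", "start", "stop", "status"),
                          names(ev))
  if (length(missing_cols)) {
    abort(paste0("events file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  parse_num <- function(col, nm) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad)) {
      abort(paste0("parse error in ", events_path, " at row ", bad[1],
                   ": cannot read '", col[bad[1]], "' as a number (column ",
                   nm, ")"))
    }
    x
  }
  ev$start <- parse_num(ev$start, "start")
  ev$stop <- parse_num(ev$stop, "stop")
  ev$status <- as.integer(parse_num(ev$status, "status"))
  cv <- as_tibble(utils::read.csv(covariates_path,
                                  colClasses = c(subject_id = "character"),
                                  check.names = FALSE))
  if (!is.null(schema)) {
    missing_cov <- setdiff(schema_covariates(schema), names(cv))
    if (length(missing_cov)) {
      abort(paste0("covariates file is missing column(s): ",
                   paste(missing_cov, collapse = ", ")))
    }
  }
  event_history(ev, cv, schema = schema)
}

#' Write an event history to CSV files
#'
#' Column and row order are deterministic (subject, type, start), so
#' writing, re-reading and writing again is byte-stable.
#'
#' @param history An [event_history()].
#' @param events_path,covariates_path Output CSV paths.
#' @return Invisibly, `c(events_path, covariates_path)`.
#' @export
write_event_history <- function(history, events_path, covariates_path) {
  ev <- history$events |>
    mutate(start = format_time(.data$start), stop = format_time(.data$stop))
  readr::write_csv(ev, events_path)
  cv <- history$covariates |>
    select("subject_id",
           dplyr::all_of(intersect(schema_covariates(history$schema),
                                   names(history$covariates))),
           dplyr::everything())
  num_cols <- names(cv)[vapply(cv, is.double, logical(1))]
  for (nm in num_cols) cv[[nm]] <- format_time(cv[[nm]])
  readr::write_csv(cv, covariates_path)
  invisible(c(events_path, covariates_path))
}

# 17 significant digits guarantee an exact double round trip through text
format_time <- function(x) {
  out <- sprintf("%.17g", x)
  # trim redundant trailing zeros without losing exactness
  ifelse(as.numeric(sprintf("%.15g", x)) == x, sprintf("%.15g", x), out)
}
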