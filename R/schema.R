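#' Declare the covariate dictionary for a cohort
#'
#' A covariate schema lists every covariate column expected in the covariate
#' table, its admissible categorical levels in display order, and the
#' reference level used when covariates are expanded to dummy columns.
#' Numeric covariates are declared with `NULL` instead of a level vector.
#'
#' @param ... Named arguments, one per covariate: either a character vector
#'   of levels (the first is the reference unless `ref` overrides it) or
#'   `NULL` for a numeric covariate.
#' @param ref Optional named character vector of reference levels, e.g.
#'   `c(grade = "I")`. Defaults to the first declared level.
#'
#' @return A `cov_schema` object: a named list with elements `levels` and
#'   `ref` per covariate.
#'
#' @examples
#' cov_schema(
#'   grade = c("I", "II", "III"),
#'   size  = c("<20", ">=20")
#' )
#' @export
cov_schema <- function(..., ref = NULL) {
  decl <- list(...)
  if (length(decl) == 0 || is.null(names(decl)) || any(names(decl) == "")) {
    abort("every covariate in a schema must be named")
  }
  out <- lapply(names(decl), function(nm) {
    lv <- decl[[nm]]
    if (is.null(lv)) {
      return(list(levels = NULL, ref = NULL))
    }
    lv <- as.character(lv)
    if (anyDuplicated(lv)) abort(paste0("duplicate levels for covariate '", nm, "'"))
    r <- if (!is.null(ref) && nm %in% names(ref)) ref[[nm]] else lv[[1]]
    if (!r %in% lv) abort(paste0("reference level '", r, "' not among levels of '", nm, "'"))
    list(levels = lv, ref = r)
  })
  names(out) <- names(decl)
  structure(out, class = "cov_schema")
}

#' Default breast-cancer covariate schema
#'
#' Age group, tumour grade, tumour size and HER2 status with the reference
#' levels used throughout: age > 60 years, grade I, size < 20 mm, HER2
#' negative.
#'
#' @return A [cov_schema()].
#' @export
default_schema <- function() {
  cov_schema(
    age_group = c(">60", "<=40", "40-60"),
    grade     = c("I", "II", "III"),
    size      = c("<20", ">=20"),
    her2      = c("negative", "positive")
  )
}

schema_covariates <- function(schema) names(schema)

is_categorical <- function(schema, nm) !is.null(schema[[nm]]$levels)

#' Read / write a covariate schema as YAML
#'
#' The on-disk form is a mapping from covariate name to either a list with
#' `levels` and `ref` keys, or `~` (null) for a numeric covariate.
#'
#' @param path File path.
#' @return `read_cov_schema()` returns a [cov_schema()];
#'   `write_cov_schema()` returns `path` invisibly.
#' @export
read_cov_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- lapply(raw, function(x) if (is.null(x)) NULL else as.character(x$levels))
  refs <- unlist(lapply(names(raw), function(nm) {
    if (is.null(raw[[nm]]) || is.null(raw[[nm]]$ref)) NULL else setNames(raw[[nm]]$ref, nm)
  }))
  do.call(cov_schema, c(args, list(ref = refs)))
}

#' @rdname read_cov_schema
#' @param schema A [cov_schema()].
#' @export
write_cov_schema <- function(schema, path) {
  raw <- lapply(schema, function(x) {
    if (is.null(x$levels)) NULL else list(levels = as.list(x$levels), ref = x$ref)
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.cov_schema <- function(x, ...) {
  cat("<cov_schema> with", length(x), "covariates\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]]$levels)) {
      cat(" ", nm, ": numeric\n")
    } else {
      cat(" ", nm, ": ", paste(x[[nm]]$levels, collapse = ", "),
          " (ref: ", x[[nm]]$ref, ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Expand covariates to reference-level dummy columns
#'
#' Categorical covariates become one indicator column per non-reference
#' level, named `"<covariate>=<level>"`; numeric covariates pass through
#' under their own name.
#'
#' @param covariates A data frame with one row per subject.
#' @param schema A [cov_schema()] declaring levels and reference levels.
#' @param covariate_names Which covariates to expand (default: all in the
#'   schema).
#' @return A numeric matrix with `nrow(covariates)` rows, plus attribute
#'   `terms`, a tibble mapping columns to (covariate, level).
#' @export
covariate_dummies <- function(covariates, schema, covariate_names = schema_covariates(schema)) {
  bad <- setdiff(covariate_names, names(covariates))
  if (length(bad)) abort(paste0("covariates not found: ", paste(bad, collapse = ", ")))
  cols <- list()
  terms <- list()
  for (nm in covariate_names) {
    v <- covariates[[nm]]
    if (is_categorical(schema, nm)) {
      lv <- schema[[nm]]$levels
      v <- as.character(v)
      unknown <- setdiff(unique(v), lv)
      if (length(unknown)) {
        abort(paste0("covariate '", nm, "' has undeclared levels: ",
                     paste(unknown, collapse = ", ")))
      }
      for (l in setdiff(lv, schema[[nm]]$ref)) {
        cn <- paste0(nm, "=", l)
        cols[[cn]] <- as.numeric(v == l)
        terms[[cn]] <- tibble(column = cn, covariate = nm, level = l)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
      terms[[nm]] <- tibble(column = nm, covariate = nm, level = NA_character_)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else matrix(0, nrow(covariates), 0)
  attr(m, "terms") <- if (length(terms)) bind_rows(terms) else
    tibble(column = character(), covariate = character(), level = character())
  m
}
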