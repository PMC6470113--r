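# Readers for the package's CSV interchange formats. All validate on entry:
# VAS scores must lie in [0,100] (missing allowed, encoded as empty fields),
# dimension labels and demographic categories must come from the closed sets.

#' @noRd
check_scores <- function(df, cols, what) {
  for (col in cols) {
    if (!col %in% names(df)) {
      stop(sprintf("%s is missing column '%s'", what, col), call. = FALSE)
    }
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      stop(sprintf("%s: column '%s' is not numeric", what, col), call. = FALSE)
    }
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop(sprintf("%s: VAS score outside [0,100] in column '%s' (row %d: %g)",
                   what, col, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @noRd
validate_within <- function(df) {
  need <- c("respondent_id", "dimension", SCORE_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("within-dimension responses are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_dim <- setdiff(unique(df$dimension), DIM_NAMES)
  if (length(bad_dim)) {
    stop("unknown dimension label(s): ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  }
  check_scores(df, SCORE_COLS, "within-dimension responses")
  if (anyDuplicated(df[c("respondent_id", "dimension")])) {
    stop("duplicated (respondent_id, dimension) rows in within-dimension responses",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
validate_pits <- function(df) {
  need <- c("respondent_id", "score_pits", "score_dead")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("pits responses are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_scores(df, c("score_pits", "score_dead"), "pits responses")
  invisible(TRUE)
}

#' @noRd
validate_demographics <- function(df, vars = c("gender", "age_group", "education")) {
  if (!"respondent_id" %in% names(df)) {
    stop("demographics need a respondent_id column", call. = FALSE)
  }
  if (anyDuplicated(df$respondent_id)) {
    stop("duplicated respondent_id in demographics", call. = FALSE)
  }
  for (v in intersect(vars, names(df))) check_categories(df[[v]], v)
  invisible(TRUE)
}

#' Read respondent-level valuation and demographic files
#'
#' CSV readers for the package's interchange formats, one row per respondent
#' (x task for the within-dimension file). Missing VAS scores are empty
#' fields. All scores are validated against the \[0,100\] VAS bounds at parse
#' time; out-of-range values are rejected, not winsorized.
#'
#' * `read_within_responses()`: columns `respondent_id`, `dimension`,
#'   `score_L2` ... `score_L5`, `score_dead`. Level 1 is never stored (it is
#'   fixed at 100 by task design).
#' * `read_pits_responses()`: columns `respondent_id`, `score_pits`,
#'   `score_dead`.
#' * `read_demographics()`: columns `respondent_id`, `gender`, `age_group`,
#'   `education` (categories from [demographic_levels()]; missing allowed).
#' * `read_population()`: marginal table `variable`, `category`, `count`, or
#'   a joint table with demographic columns plus `count`.
#' * `read_health_states()`: either 15 level columns named as
#'   [fifteen_dimensions()] or a single `state` column of 15-digit strings.
#'
#' @param path CSV file path.
#' @return A validated data frame (for `read_health_states`, an integer
#'   matrix with one row per state).
#' @name readers
NULL

#' @rdname readers
#' @export
read_within_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_within(df)
  df
}

#' @rdname readers
#' @export
read_pits_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_pits(df)
  df
}

#' @rdname readers
#' @export
read_demographics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_demographics(df)
  df
}

#' @rdname readers
#' @export
read_population <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("variable", "category", "count") %in% names(df))) {
    for (v in unique(df$variable)) {
      check_categories(df$category[df$variable == v], v)
    }
  } else if (!"count" %in% names(df)) {
    stop("population table needs either (variable, category, count) or ",
         "demographic columns plus count", call. = FALSE)
  } else {
    for (v in intersect(c("gender", "age_group", "education"), names(df))) {
      check_categories(df[[v]], v)
    }
  }
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("population counts must be non-negative and non-missing", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_health_states <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if ("state" %in% header) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(state = "character"))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  if ("state" %in% names(df)) {
    m <- t(vapply(df$state,
                  function(s) unclass(validate_health_state(s)),
                  integer(15)))
  } else {
    missing_cols <- setdiff(DIM_NAMES, names(df))
    if (length(missing_cols)) {
      stop("states file needs a 'state' column or all 15 dimension columns; ",
           "missing: ", paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, DIM_NAMES])
  }
  rownames(m) <- NULL
  colnames(m) <- DIM_NAMES
  m
}
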