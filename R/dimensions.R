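# Canonical orderings. Every table, file and vector in the package uses the
# dimension order below; demographic categories are closed sets, ordered so
# that adjacent categories are meaningful merge candidates when sparse
# post-stratification cells must be collapsed.

DIM_NAMES <- c(
  "mobility", "vision", "hearing", "breathing", "sleep", "eating", "speech",
  "elimination", "usual_activities", "mental_function", "discomfort",
  "depression", "distress", "vitality", "sexual_activity"
)

LEVEL_LABELS <- paste0("level_", 1:5)
SCORE_COLS <- c("score_L2", "score_L3", "score_L4", "score_L5", "score_dead")

GENDER_LEVELS <- c("men", "women")
AGE_LEVELS <- c("18-24", "25-39", "40-59", "60-66", "67+")
EDU_LEVELS <- c("no_formal_education", "elementary_school", "high_school",
                "university_ba", "university_ma")

#' Canonical 15D dimension names
#'
#' The 15D descriptive system has 15 dimensions, each with five levels of
#' function (1 = best, 5 = worst). All algorithm tables, response files and
#' health-state vectors in this package use this fixed dimension order.
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' fifteen_dimensions()
fifteen_dimensions <- function() DIM_NAMES

#' Closed category sets for respondent demographics
#'
#' @param variable One of `"gender"`, `"age_group"`, `"education"`.
#' @return Character vector of admissible categories, in canonical order.
#'   For `age_group` and `education` the order is also the adjacency used
#'   when collapsing empty post-stratification cells.
#' @export
demographic_levels <- function(variable) {
  switch(match.arg(variable, c("gender", "age_group", "education")),
    gender = GENDER_LEVELS,
    age_group = AGE_LEVELS,
    education = EDU_LEVELS
  )
}

#' @noRd
check_categories <- function(x, variable, what = variable) {
  lv <- demographic_levels(variable)
  bad <- setdiff(unique(as.character(x[!is.na(x)])), lv)
  if (length(bad)) {
    stop(sprintf("unknown %s category: %s (expected one of %s)",
                 what, paste(bad, collapse = ", "), paste(lv, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
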