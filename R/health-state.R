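#' Validate a 15D health state
#'
#' A 15D health state is a vector of 15 function levels, one per dimension in
#' the canonical order of [fifteen_dimensions()], each an integer between 1
#' (best) and 5 (worst). A single 15-character digit string such as
#' `"111151111111111"` is also accepted.
#'
#' @param levels Integer vector of length 15, or one 15-character digit string.
#' @return An object of class `health_state`: a named integer vector.
#' @export
#' @examples
#' validate_health_state(rep(1, 15))          # perfect health
#' validate_health_state(rep(5, 15))          # the pits state
#' validate_health_state("211111111111111")
validate_health_state <- function(levels) {
  if (inherits(levels, "health_state")) return(levels)
  if (is.character(levels)) {
    if (length(levels) != 1L || !grepl("^[0-9]{15}$", levels)) {
      stop("a health-state string must be exactly 15 digits", call. = FALSE)
    }
    levels <- as.integer(strsplit(levels, "")[[1]])
  }
  if (length(levels) != 15L) {
    stop(sprintf("a 15D health state has 15 levels, got %d", length(levels)),
         call. = FALSE)
  }
  if (!is.numeric(levels) || anyNA(levels)) {
    stop("health-state levels must be integers with no missing values",
         call. = FALSE)
  }
  frac <- which(levels != round(levels))
  if (length(frac)) {
    stop(sprintf("non-integer level at dimension %s",
                 paste(DIM_NAMES[frac], collapse = ", ")), call. = FALSE)
  }
  out_of_range <- which(levels < 1 | levels > 5)
  if (length(out_of_range)) {
    stop(sprintf("level outside 1-5 at dimension %s (got %s)",
                 paste(DIM_NAMES[out_of_range], collapse = ", "),
                 paste(levels[out_of_range], collapse = ", ")), call. = FALSE)
  }
  structure(setNames(as.integer(round(levels)), DIM_NAMES),
            class = "health_state")
}

#' @export
print.health_state <- function(x, ...) {
  cat("15D health state:", state_string(x), "\n")
  worst <- x[x > 1]
  if (length(worst)) {
    cat("  impaired:", paste(sprintf("%s=%d", names(worst), worst),
                             collapse = ", "), "\n")
  } else {
    cat("  perfect health\n")
  }
  invisible(x)
}

#' @noRd
state_string <- function(state) paste(unclass(state), collapse = "")
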