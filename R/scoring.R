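#' Score one 15D health state
#'
#' The value of a health state is one minus the sum of the fifteen looked-up
#' disutility decrements, `V_H(l) = 1 - sum_j T[j, l_j]`: purely additive,
#' no interaction terms. Value and disutility always sum to exactly 1.
#'
#' @param state A health state accepted by [validate_health_state()].
#' @param algorithm A `value_algorithm`.
#' @return An object of class `scored_state`: list with `state`,
#'   `disutility`, `value`.
#' @export
#' @examples
#' algo <- norwegian_algorithm()
#' score_state(rep(1, 15), algo)$value      # exactly 1
#' score_state(rep(5, 15), algo)$value      # 1 - 1.5158
score_state <- function(state, algorithm) {
  state <- validate_health_state(state)
  if (!inherits(algorithm, "value_algorithm")) {
    stop("algorithm must be a value_algorithm", call. = FALSE)
  }
  T <- algorithm$decrements
  disutility <- sum(T[cbind(seq_len(15L), as.integer(state))])
  structure(list(state = state, disutility = disutility,
                 value = 1 - disutility),
            class = "scored_state")
}

#' @export
print.scored_state <- function(x, ...) {
  cat(sprintf("state %s: value %.4f (disutility %.4f)\n",
              state_string(x$state), x$value, x$disutility))
  invisible(x)
}

#' @noRd
as_state_matrix <- function(states) {
  if (inherits(states, "health_state")) {
    states <- matrix(unclass(states), nrow = 1)
  } else if (is.character(states)) {
    bad <- !grepl("^[0-9]{15}$", states)
    m <- matrix(NA_integer_, length(states), 15)
    if (any(!bad)) {
      m[!bad, ] <- t(vapply(strsplit(states[!bad], ""),
                            function(d) as.integer(d), integer(15)))
    }
    states <- m
  } else if (is.list(states) && !is.data.frame(states)) {
    states <- do.call(rbind, lapply(states, function(s) unclass(validate_health_state(s))))
  } else if (is.data.frame(states)) {
    if (all(DIM_NAMES %in% names(states))) states <- states[, DIM_NAMES]
    states <- as.matrix(states)
  }
  if (!is.matrix(states) || ncol(states) != 15L) {
    stop("states must be 15-column rows, 15-digit strings, or health_state objects",
         call. = FALSE)
  }
  storage.mode(states) <- "integer"
  colnames(states) <- DIM_NAMES
  states
}

#' Score a batch of 15D health states
#'
#' Order-preserving vectorised application of [score_state()]. In strict
#' mode (the default) any invalid row is an error naming the offending row
#' indices; in permissive mode invalid rows score `NA` with a warning and
#' the rest are scored normally.
#'
#' @param states A matrix or data frame with 15 level columns, a character
#'   vector of 15-digit strings, or a list of health states.
#' @param algorithm A `value_algorithm`.
#' @param permissive Logical; tolerate invalid rows.
#' @return Data frame with columns `state` (digit string), `disutility`,
#'   `value`, one row per input state.
#' @export
batch_score <- function(states, algorithm, permissive = FALSE) {
  if (!inherits(algorithm, "value_algorithm")) {
    stop("algorithm must be a value_algorithm", call. = FALSE)
  }
  m <- as_state_matrix(states)
  n <- nrow(m)
  if (n == 0L) {
    return(data.frame(state = character(), disutility = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  valid <- rowSums(is.na(m) | m < 1L | m > 5L) == 0L
  if (any(!valid)) {
    idx <- which(!valid)
    msg <- sprintf("invalid health state(s) at row(s): %s",
                   paste(head(idx, 10), collapse = ", "))
    if (!permissive) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  T <- algorithm$decrements
  dis <- rep(NA_real_, n)
  if (any(valid)) {
    mv <- m[valid, , drop = FALSE]
    per_dim <- vapply(seq_len(15L), function(j) T[j, mv[, j]],
                      numeric(nrow(mv)))
    dis[valid] <- if (nrow(mv) == 1L) sum(per_dim) else rowSums(per_dim)
  }
  data.frame(
    state = apply(m, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = "")),
    disutility = dis,
    value = 1 - dis,
    stringsAsFactors = FALSE
  )
}

#' Summarise a value algorithm
#'
#' Reports the health-state value range `[1 - sum_j T[j,5], 1]`, the
#' disutility range, and the dimensions ranked by their level-5 disutility
#' (ties broken by canonical dimension order).
#'
#' @param algorithm A `value_algorithm`.
#' @return An object of class `algorithm_summary`.
#' @export
#' @examples
#' algorithm_summary(norwegian_algorithm())
algorithm_summary <- function(algorithm) {
  if (!inherits(algorithm, "value_algorithm")) {
    stop("algorithm must be a value_algorithm", call. = FALSE)
  }
  T <- algorithm$decrements
  l5 <- T[, "level_5"]
  desc <- order(-l5, seq_along(l5))
  asc <- order(l5, seq_along(l5))
  ranking <- data.frame(rank = seq_along(desc),
                        dimension = rownames(T)[desc],
                        l5_disutility = as.numeric(l5[desc]),
                        stringsAsFactors = FALSE)
  structure(
    list(disutility_range = c(0, sum(l5)),
         value_range = c(1 - sum(l5), 1),
         l5_ranking = ranking,
         largest_l5 = rownames(T)[desc[1]],
         smallest_l5 = rownames(T)[asc[1]],
         omega = algorithm$omega,
         v_pits = algorithm$v_pits),
    class = "algorithm_summary"
  )
}

#' @export
print.algorithm_summary <- function(x, ...) {
  cat(sprintf("Health-state values span [%.4f, %.4f]\n",
              x$value_range[1], x$value_range[2]))
  cat(sprintf("Disutility range [0, %.4f]; v_pits = %.4f\n",
              x$disutility_range[2], x$v_pits))
  cat(sprintf("Largest level-5 disutility:  %s (%.4f)\n",
              x$largest_l5, max(x$l5_ranking$l5_disutility)))
  cat(sprintf("Smallest level-5 disutility: %s (%.4f)\n",
              x$smallest_l5, min(x$l5_ranking$l5_disutility)))
  invisible(x)
}

#' Mean value by ranked percentile bins
#'
#' Sorts scores ascending, partitions them into `n_points` equal-count bins
#' (any remainder spread over the leading bins), and reports the mean value
#' per bin — the summary behind "mean health state values by ranked
#' percentile" comparison curves.
#'
#' @param scores A numeric vector of values, or a [batch_score()] result
#'   (its `value` column is used).
#' @param n_points Number of bins; must not exceed the number of scores.
#' @return Data frame with columns `percentile` (upper bin edge, in percent)
#'   and `mean_value`, non-decreasing in `percentile`.
#' @export
percentile_curve <- function(scores, n_points) {
  if (is.data.frame(scores)) scores <- scores$value
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  n <- length(scores)
  if (n == 0L) stop("empty scores", call. = FALSE)
  if (n_points < 1L || n_points > n) {
    stop(sprintf("n_points must be between 1 and %d", n), call. = FALSE)
  }
  v <- sort(scores)
  base <- n %/% n_points
  rem <- n %% n_points
  sizes <- rep(base, n_points)
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(
    percentile = 100 * ends / n,
    mean_value = vapply(seq_len(n_points),
                        function(b) mean(v[starts[b]:ends[b]]), numeric(1))
  )
}
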