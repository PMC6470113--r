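# The four-step value-algorithm estimation procedure:
#   Step 1  weighted means of the raw within-dimension VAS scores
#   Step 2  dead-anchored relative disutility scores S[j,i]
#   Step 3  empirical pits-state disutility v_pits from the pits task
#   Step 4  rescaling T = omega * S with omega = v_pits / sum_j S[j,5]
# No rounding happens inside the pipeline; only on export.

#' @noRd
resolve_weights <- function(tasks, ids, weights, context) {
  if (is.null(weights)) return(rep(1, length(ids)))
  if (is.data.frame(weights) && all(c("respondent_id", "weight") %in% names(weights))) {
    if ("task" %in% names(weights)) {
      key <- paste(weights$task, weights$respondent_id)
      w <- weights$weight[match(paste(tasks, ids), key)]
    } else {
      w <- weights$weight[match(ids, weights$respondent_id)]
    }
  } else if (is.numeric(weights) && !is.null(names(weights))) {
    w <- weights[as.character(ids)]
  } else {
    stop("weights must be NULL, a (task, respondent_id, weight) data frame, ",
         "or a named numeric vector", call. = FALSE)
  }
  if (anyNA(w)) {
    miss <- unique(ids[is.na(w)])
    stop(sprintf("%s: no weight for respondent(s) %s", context,
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  as.numeric(w)
}

#' Step 1: weighted within-dimension level means
#'
#' Computes, for every dimension and every level L2-L5 plus "being dead", the
#' weighted mean of the respondents' raw VAS scores. Level 1 is fixed at 100
#' by task design. By default each respondent contributes to exactly the
#' level cells they answered; set `complete_cases = TRUE` to drop any task
#' response with a missing score entirely.
#'
#' @param responses Within-dimension response data frame (see
#'   [read_within_responses()] for the layout). All 15 dimensions must be
#'   present.
#' @param weights `NULL` for uniform weights, or a weight table as returned
#'   by [compute_poststrat_weights()] (its `task` column is matched against
#'   the dimension label).
#' @param complete_cases Logical full-case-per-task switch.
#' @return A 15 x 6 matrix with columns `level_1` ... `level_5`, `dead`
#'   (class `level_score_table`); all entries in \[0, 100\].
#' @export
weighted_level_means <- function(responses, weights = NULL,
                                 complete_cases = FALSE) {
  validate_within(responses)
  missing_dims <- setdiff(DIM_NAMES, unique(responses$dimension))
  if (length(missing_dims)) {
    stop("no responses for dimension(s): ",
         paste(missing_dims, collapse = ", "), call. = FALSE)
  }
  if (complete_cases) {
    responses <- responses[complete.cases(responses[SCORE_COLS]), , drop = FALSE]
  }
  w <- resolve_weights(responses$dimension, responses$respondent_id, weights,
                       "within-dimension weighting")
  out <- matrix(NA_real_, 15, 6,
                dimnames = list(DIM_NAMES, c(LEVEL_LABELS, "dead")))
  out[, "level_1"] <- 100
  targets <- c(level_2 = "score_L2", level_3 = "score_L3",
               level_4 = "score_L4", level_5 = "score_L5", dead = "score_dead")
  for (j in DIM_NAMES) {
    rows <- responses$dimension == j
    if (!any(rows)) {
      stop(sprintf("no responses for dimension %s", j), call. = FALSE)
    }
    for (k in seq_along(targets)) {
      v <- responses[[targets[[k]]]][rows]
      if (all(is.na(v))) {
        stop(sprintf("no usable responses for (%s, %s)", j, names(targets)[k]),
             call. = FALSE)
      }
      out[j, names(targets)[k]] <- weighted_mean(v, w[rows])
    }
  }
  class(out) <- c("level_score_table", class(out))
  out
}

#' Step 2: dead-anchored relative disutility scores
#'
#' Converts mean level scores into within-dimension relative disutilities
#' \deqn{S_{j,i} = \frac{100 - \bar s_i^j}{100 - \bar s_{dead}^j},}
#' each dimension anchored at its own mean "dead" score (no pooling across
#' tasks). `S[j,1] = 0` because level 1 is fixed at 100; `S` may exceed 1
#' when a level is rated below "being dead". A mean dead score within
#' `min_dead_gap` VAS units of 100 is an error, not a silent clamp: the
#' denominator would be explosive.
#'
#' @param means A `level_score_table` from [weighted_level_means()] (any
#'   matrix with columns `level_2` ... `level_5` and `dead` works).
#' @param min_dead_gap Minimum required value of `100 - mean_dead`, in VAS
#'   units.
#' @return A 15 x 5 matrix of relative scores with zero first column.
#' @export
relative_scores <- function(means, min_dead_gap = 1) {
  means <- unclass(as.matrix(means))
  need <- c(LEVEL_LABELS[2:5], "dead")
  if (!all(need %in% colnames(means))) {
    stop("means table must have columns level_2..level_5 and dead",
         call. = FALSE)
  }
  gap <- 100 - means[, "dead"]
  bad <- rownames(means)[gap < min_dead_gap]
  if (length(bad)) {
    stop("mean 'dead' score too close to 100 for dimension(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  S <- matrix(0, nrow(means), 5, dimnames = list(rownames(means), LEVEL_LABELS))
  for (i in 2:5) {
    S[, i] <- (100 - means[, LEVEL_LABELS[i]]) / gap
  }
  S
}

#' Completeness filter for the pits task
#'
#' Retains exactly the pits responses with both the pits-state score and the
#' "being dead" score present, and reports how many were excluded.
#'
#' @param responses Pits response data frame (see [read_pits_responses()]).
#' @return A list with elements `complete` (the retained data frame) and
#'   `n_excluded`.
#' @export
filter_complete_pits <- function(responses) {
  validate_pits(responses)
  keep <- !is.na(responses$score_pits) & !is.na(responses$score_dead)
  list(complete = responses[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Step 3: empirical pits-state disutility
#'
#' Estimates the disutility of the worst possible 15D health state as
#' \deqn{V_{Pits} = \frac{100 - \bar s_{Pits}}{100 - \bar s_{dead}}}
#' from weighted means over the complete pits responses only (the
#' completeness filter runs internally and its exclusion count is reported).
#' `v_pits > 1` means the pits state was rated worse than being dead on
#' average, as observed in the Norwegian data.
#'
#' @param responses Pits response data frame.
#' @param weights `NULL` for uniform, a weight table (rows with
#'   `task == "pits"` are used if a `task` column is present), or a named
#'   numeric vector keyed by respondent id.
#' @param min_dead_gap Minimum `100 - mean_dead`, in VAS units.
#' @return An object of class `pits_estimate`: a list with `v_pits`,
#'   `mean_pits`, `mean_dead`, `n_complete`, `n_excluded`.
#' @export
pits_estimate <- function(responses, weights = NULL, min_dead_gap = 1) {
  flt <- filter_complete_pits(responses)
  comp <- flt$complete
  if (!nrow(comp)) stop("no complete pits responses", call. = FALSE)
  if (is.data.frame(weights) && "task" %in% names(weights)) {
    weights <- weights[weights$task == "pits", , drop = FALSE]
  }
  w <- resolve_weights(rep("pits", nrow(comp)), comp$respondent_id, weights,
                       "pits weighting")
  mean_pits <- weighted_mean(comp$score_pits, w)
  mean_dead <- weighted_mean(comp$score_dead, w)
  if (100 - mean_dead < min_dead_gap) {
    stop("weighted mean 'dead' score in the pits task is too close to 100",
         call. = FALSE)
  }
  structure(
    list(v_pits = (100 - mean_pits) / (100 - mean_dead),
         mean_pits = mean_pits, mean_dead = mean_dead,
         n_complete = nrow(comp), n_excluded = flt$n_excluded),
    class = "pits_estimate"
  )
}

#' @export
print.pits_estimate <- function(x, ...) {
  cat(sprintf(
    "Pits-state disutility v_pits = %.4f (mean pits %.2f, mean dead %.2f; %d complete, %d excluded)\n",
    x$v_pits, x$mean_pits, x$mean_dead, x$n_complete, x$n_excluded))
  invisible(x)
}

#' Step 4: rescale relative scores into a value algorithm
#'
#' Computes the normalizing constant `omega = v_pits / sum_j S[j,5]` and the
#' disutility table `T = omega * S`, so that health-state values are bounded
#' by 1 for perfect health and `1 - v_pits` for the pits state, and the
#' level-5 column of `T` sums exactly to `v_pits`.
#'
#' @param S 15 x 5 relative-score matrix from [relative_scores()].
#' @param pits A `pits_estimate`, or a single positive number taken as
#'   `v_pits`.
#' @param metadata Optional provenance list stored on the result.
#' @return A `value_algorithm`.
#' @export
build_algorithm <- function(S, pits, metadata = NULL) {
  v_pits <- if (inherits(pits, "pits_estimate")) pits$v_pits else as.numeric(pits)
  if (length(v_pits) != 1L || is.na(v_pits) || v_pits <= 0) {
    stop("v_pits must be a single positive number", call. = FALSE)
  }
  S <- as.matrix(S)
  if (ncol(S) != 5L) stop("S must have 5 level columns", call. = FALSE)
  denom <- sum(S[, 5])
  if (denom <= 0) {
    stop("sum of level-5 relative scores must be positive", call. = FALSE)
  }
  omega <- v_pits / denom
  value_algorithm(omega * S, omega = omega, v_pits = v_pits,
                  metadata = metadata, tol = 1e-8)
}

#' Estimate a 15D value algorithm from respondent-level valuation data
#'
#' End-to-end composition of post-stratification weighting and estimation
#' Steps 1-4. Task-specific weights are computed over each task's completers
#' only: a within-dimension completer is a respondent with at least one
#' non-missing score for that dimension (all five scores when
#' `complete_cases = TRUE`); a pits completer has both pits and dead scores.
#' The pits task is weighted by `pits_vars` (gender and age by default,
#' since pits respondents need not report education). Respondents excluded
#' from weighting for missing demographics are excluded from estimation too.
#'
#' Pass `demographics = NULL` (and `population = NULL`) for an unweighted
#' estimate.
#'
#' @param within Within-dimension response data frame.
#' @param pits Pits response data frame.
#' @param demographics Demographics covering all completers, or `NULL`.
#' @param population Population table matching `scheme`, or `NULL`.
#' @param scheme,vars,pits_vars,collapse Passed to
#'   [compute_poststrat_weights()]; `pits_vars` replaces `vars` for the pits
#'   task.
#' @param complete_cases,min_dead_gap Passed to the component steps.
#' @param metadata Optional provenance list stored on the result.
#' @return A `value_algorithm` whose `"estimation_log"` attribute records
#'   completer counts per task, exclusions, cell collapses, omega, v_pits,
#'   and the mean dead scores.
#' @export
estimate_algorithm <- function(within, pits,
                               demographics = NULL, population = NULL,
                               scheme = c("crossed", "marginal"),
                               vars = c("gender", "age_group", "education"),
                               pits_vars = c("gender", "age_group"),
                               complete_cases = FALSE,
                               min_dead_gap = 1,
                               collapse = TRUE,
                               metadata = NULL) {
  scheme <- match.arg(scheme)
  validate_within(within)
  validate_pits(pits)
  use_weights <- !is.null(demographics)
  if (use_weights && is.null(population)) {
    stop("demographics supplied without a population table", call. = FALSE)
  }

  answered <- if (complete_cases) {
    complete.cases(within[SCORE_COLS])
  } else {
    rowSums(!is.na(within[SCORE_COLS])) > 0
  }
  pits_flt <- filter_complete_pits(pits)

  wt_within <- NULL
  wt_pits <- NULL
  n_dropped_demo <- 0L
  collapses <- list()
  if (use_weights) {
    completers <- split(as.character(within$respondent_id[answered]),
                        within$dimension[answered])
    missing_dims <- setdiff(DIM_NAMES, names(completers))
    if (length(missing_dims)) {
      stop("no completers for dimension(s): ",
           paste(missing_dims, collapse = ", "), call. = FALSE)
    }
    wt_within <- compute_poststrat_weights(demographics, population, completers,
                                           vars = vars, scheme = scheme,
                                           collapse = collapse)
    pits_ids <- as.character(pits_flt$complete$respondent_id)
    if (length(pits_ids)) {
      wt_pits <- compute_poststrat_weights(demographics, population,
                                           list(pits = pits_ids),
                                           vars = pits_vars, scheme = scheme,
                                           collapse = collapse)
      collapses <- c(attr(wt_within, "collapses"), attr(wt_pits, "collapses"))
    }
    # drop responses whose respondent was excluded from weighting
    wkey <- paste(wt_within$task, wt_within$respondent_id)
    keep <- paste(within$dimension, within$respondent_id) %in% wkey
    n_dropped_demo <- length(unique(within$respondent_id[!keep]))
    within <- within[keep, , drop = FALSE]
    pits <- pits[is.na(pits$score_pits) | is.na(pits$score_dead) |
                   as.character(pits$respondent_id) %in% wt_pits$respondent_id,
                 , drop = FALSE]
  }

  means <- weighted_level_means(within, wt_within, complete_cases = complete_cases)
  S <- relative_scores(means, min_dead_gap = min_dead_gap)
  pe <- pits_estimate(pits, wt_pits, min_dead_gap = min_dead_gap)
  algo <- build_algorithm(S, pe, metadata = metadata)

  completer_counts <- vapply(DIM_NAMES, function(j) {
    length(unique(within$respondent_id[within$dimension == j]))
  }, integer(1))
  attr(algo, "estimation_log") <- list(
    weighted = use_weights,
    scheme = if (use_weights) scheme else "none",
    vars = if (use_weights) vars else character(),
    pits_vars = if (use_weights) pits_vars else character(),
    completers_per_task = as.list(completer_counts),
    pits_n_complete = pe$n_complete,
    pits_n_excluded = pe$n_excluded,
    n_excluded_missing_demographics = n_dropped_demo,
    cell_collapses = collapses,
    omega = algo$omega,
    v_pits = algo$v_pits,
    mean_dead_within = as.list(means[, "dead"]),
    mean_dead_pits = pe$mean_dead
  )
  algo
}
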