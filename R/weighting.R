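#' Weighted mean with explicit missing-value and weight contracts
#'
#' Computes `sum(w * v) / sum(w)` over the pairs whose value is non-missing.
#' Unlike [stats::weighted.mean()], non-positive or missing weights are an
#' error, as is a vector with no usable value: the estimation pipeline must
#' fail loudly rather than average over nothing.
#'
#' @param values Numeric vector, may contain `NA`.
#' @param weights Positive numeric vector of the same length.
#' @return The weighted mean of the non-missing values.
#' @export
#' @examples
#' weighted_mean(c(50, 70), c(1, 1))   # 60
#' weighted_mean(c(0, 100), c(3, 1))   # 25
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("`values` and `weights` must have equal length", call. = FALSE)
  }
  keep <- !is.na(values)
  if (!any(keep)) stop("all values are missing", call. = FALSE)
  w <- weights[keep]
  if (anyNA(w) || any(w <= 0)) {
    stop("weights must be positive and non-missing", call. = FALSE)
  }
  sum(w * values[keep]) / sum(w)
}

#' @noRd
is_marginal_population <- function(population) {
  all(c("variable", "category", "count") %in% names(population))
}

#' Post-stratification weights per valuation task
#'
#' For each task, each completer in demographic cell `c` receives the weight
#' `P_pop(c) / P_sample(c)`: the population share of the cell divided by its
#' share among that task's completers. Weights are computed separately per
#' task over that task's completers only, so the weighted completer
#' composition of every retained cell matches the general population.
#'
#' Two cell definitions are supported. `scheme = "crossed"` (the default)
#' cross-classifies all `vars` and needs a joint population table (columns =
#' `vars` plus `count`). `scheme = "marginal"` multiplies one-variable
#' population/sample ratios per variable; it works from a marginal table
#' (columns `variable`, `category`, `count`) such as [norwegian_population()],
#' matches the population margin exactly for a single variable, and is only
#' an approximation (not raking) when several variables are combined.
#'
#' Under the crossed scheme, a cell with population mass but no completers is
#' collapsed deterministically: adjacent education categories are merged
#' first, then adjacent age bands, before failing. Respondents missing any
#' variable in `vars` are excluded from weighting (and recorded in the
#' `"excluded"` attribute of the result).
#'
#' @param demographics Data frame with `respondent_id` and the variables in
#'   `vars`.
#' @param population Marginal or joint population table (see above).
#' @param completers Named list mapping each task id to the character vector
#'   of its completers' respondent ids, or a data frame with columns `task`
#'   and `respondent_id`.
#' @param vars Demographic variables defining the cells.
#' @param scheme `"crossed"` or `"marginal"`.
#' @param collapse Logical; collapse empty crossed cells instead of failing.
#' @param max_weight Optional cap applied to the final weights (no trimming
#'   by default).
#' @return Data frame with columns `task`, `respondent_id`, `weight`, with
#'   attributes `"excluded"` (ids dropped for missing demographics, per task)
#'   and `"collapses"` (cell-collapse log, per task).
#' @export
#' @examples
#' demo <- data.frame(respondent_id = as.character(1:4),
#'                    gender = c("men", "men", "women", "women"))
#' pop <- data.frame(variable = "gender",
#'                   category = c("men", "women"), count = c(500, 500))
#' compute_poststrat_weights(demo, pop, list(t1 = demo$respondent_id),
#'                           vars = "gender", scheme = "marginal")
compute_poststrat_weights <- function(demographics, population, completers,
                                      vars = c("gender", "age_group", "education"),
                                      scheme = c("crossed", "marginal"),
                                      collapse = TRUE,
                                      max_weight = NULL) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(demographics) || !"respondent_id" %in% names(demographics)) {
    stop("demographics must be a data frame with a respondent_id column",
         call. = FALSE)
  }
  missing_vars <- setdiff(vars, names(demographics))
  if (length(missing_vars)) {
    stop("demographics is missing variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  validate_demographics(demographics, vars)
  demographics$respondent_id <- as.character(demographics$respondent_id)
  if (is.data.frame(completers)) {
    completers <- split(as.character(completers$respondent_id), completers$task)
  }
  if (!length(completers)) stop("empty completer set", call. = FALSE)
  if (scheme == "crossed" && is_marginal_population(population)) {
    stop("crossed weighting needs a joint population table (columns ",
         paste(vars, collapse = ", "), " + count); the marginal table only ",
         "supports scheme = \"marginal\"", call. = FALSE)
  }

  out <- vector("list", length(completers))
  names(out) <- names(completers)
  excluded <- list()
  collapses <- list()
  for (task in names(completers)) {
    ids <- unique(as.character(completers[[task]]))
    if (!length(ids)) {
      stop(sprintf("task '%s' has an empty completer set", task), call. = FALSE)
    }
    idx <- match(ids, demographics$respondent_id)
    if (anyNA(idx)) {
      orphans <- ids[is.na(idx)]
      stop(sprintf("task '%s': completer(s) without demographics: %s",
                   task, paste(head(orphans, 5), collapse = ", ")),
           call. = FALSE)
    }
    demo <- demographics[idx, c("respondent_id", vars), drop = FALSE]
    ok <- complete.cases(demo[vars])
    if (any(!ok)) excluded[[task]] <- demo$respondent_id[!ok]
    demo <- demo[ok, , drop = FALSE]
    if (!nrow(demo)) {
      stop(sprintf("task '%s': no completers with complete demographics", task),
           call. = FALSE)
    }
    if (scheme == "marginal") {
      w <- marginal_weights(demo, population, vars)
    } else {
      res <- crossed_weights(demo, population, vars, collapse)
      w <- res$weights
      if (length(res$collapses)) collapses[[task]] <- res$collapses
    }
    if (!is.null(max_weight)) w <- pmin(w, max_weight)
    out[[task]] <- data.frame(task = task, respondent_id = demo$respondent_id,
                              weight = w, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "collapses") <- collapses
  res
}

#' @noRd
marginal_weights <- function(demo, population, vars) {
  if (!is_marginal_population(population)) {
    stop("marginal weighting needs a table with columns variable, category, count",
         call. = FALSE)
  }
  w <- rep(1, nrow(demo))
  for (v in vars) {
    pop <- population[population$variable == v, , drop = FALSE]
    if (!nrow(pop)) {
      stop(sprintf("population table has no counts for variable '%s'", v),
           call. = FALSE)
    }
    check_categories(pop$category, v, paste0("population ", v))
    pop_prop <- setNames(pop$count / sum(pop$count), pop$category)
    tab <- table(demo[[v]])
    samp_prop <- setNames(as.numeric(tab) / nrow(demo), names(tab))
    orphan <- setdiff(names(samp_prop), names(pop_prop))
    if (length(orphan)) {
      stop(sprintf("sample %s categor%s absent from population table: %s",
                   v, if (length(orphan) > 1) "ies" else "y",
                   paste(orphan, collapse = ", ")), call. = FALSE)
    }
    ratio <- pop_prop[names(samp_prop)] / samp_prop
    w <- w * as.numeric(ratio[as.character(demo[[v]])])
  }
  w
}

# Crossed-cell weighting with deterministic collapse. Category groupings are
# tracked as named integer vectors over the canonical level order; merging
# the group of an empty cell with its adjacent group is a global relabelling
# of that variable, so every iteration strictly reduces the number of cells.

#' @noRd
group_labels <- function(g) {
  vapply(seq_along(g), function(i) names(g)[min(which(g == g[i]))], "")
}

#' @noRd
cell_key <- function(df, vars, grouping) {
  parts <- lapply(vars, function(v) {
    lab <- setNames(group_labels(grouping[[v]]), names(grouping[[v]]))
    as.character(lab[as.character(df[[v]])])
  })
  do.call(paste, c(parts, sep = "|"))
}

#' @noRd
merge_adjacent <- function(g, target) {
  gid <- g[[target]]
  ids <- unique(as.integer(g))        # in canonical level order
  pos <- match(gid, ids)
  other <- if (pos > 1) ids[pos - 1] else ids[pos + 1]
  g[g == other] <- gid
  g
}

#' @noRd
crossed_weights <- function(demo, population, vars, collapse) {
  need <- c(vars, "count")
  if (!all(need %in% names(population))) {
    stop("joint population table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (v in vars) check_categories(population[[v]], v, paste0("population ", v))
  pop <- aggregate(population["count"], population[vars], sum)
  grouping <- lapply(vars, function(v) {
    lv <- demographic_levels(v)
    setNames(seq_along(lv), lv)
  })
  names(grouping) <- vars
  collapse_vars <- intersect(c("education", "age_group"), vars)
  log <- character()

  repeat {
    samp_key <- cell_key(demo, vars, grouping)
    pop_key <- cell_key(pop, vars, grouping)
    pop_count <- tapply(pop$count, pop_key, sum)
    samp_tab <- table(samp_key)
    empty <- sort(setdiff(names(pop_count)[pop_count > 0], names(samp_tab)))
    if (!length(empty)) {
      no_mass <- setdiff(names(samp_tab),
                         names(pop_count)[!is.na(pop_count) & pop_count > 0])
      if (length(no_mass)) {
        stop("sample cell(s) with zero population mass: ",
             paste(no_mass, collapse = "; "), call. = FALSE)
      }
      pop_prop <- pop_count / sum(pop_count)
      samp_prop <- as.numeric(samp_tab[samp_key]) / nrow(demo)
      w <- as.numeric(pop_prop[samp_key]) / samp_prop
      return(list(weights = w, collapses = log))
    }
    if (!collapse) {
      stop("empty sample cell(s) with positive population share: ",
           paste(empty, collapse = "; "), call. = FALSE)
    }
    merged <- FALSE
    for (v in collapse_vars) {
      g <- grouping[[v]]
      if (length(unique(g)) <= 1) next
      cell_cats <- strsplit(empty[[1]], "|", fixed = TRUE)[[1]]
      target <- cell_cats[match(v, vars)]
      grouping[[v]] <- merge_adjacent(g, target)
      log <- c(log, sprintf("collapsed %s around '%s' (empty cell %s)",
                            v, target, empty[[1]]))
      merged <- TRUE
      break
    }
    if (!merged) {
      stop("empty cell(s) remain after exhausting education and age collapse: ",
           paste(empty, collapse = "; "), call. = FALSE)
    }
  }
}
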