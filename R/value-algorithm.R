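#' Construct a 15D value algorithm
#'
#' A value algorithm (value set, tariff) is a 15 x 5 look-up table of
#' disutility decrements `T[j, i]`: the value loss attached to being at level
#' `i` on dimension `j`. The value of a health state `l` is the additive
#' \deqn{V_H(l) = 1 - \sum_{j=1}^{15} T_{j, l_j},}
#' so level 1 carries decrement 0 on every dimension, perfect health scores
#' exactly 1, and the all-level-5 ("pits") state scores `1 - v_pits` where
#' `v_pits` is the sum of the level-5 column.
#'
#' @param decrements 15 x 5 numeric matrix (rows: dimensions in canonical
#'   order, columns: levels 1-5). Rows may be named with dimension labels, in
#'   which case they are reordered canonically. Level-1 entries must all be 0
#'   and no entry may be negative.
#' @param omega Positive rescaling factor that maps relative within-dimension
#'   scores `S` onto `T = omega * S`. Defaults to 1 (i.e. `T` is taken as its
#'   own scale).
#' @param v_pits Disutility of the pits state. Defaults to the level-5 column
#'   sum; if supplied it must agree with that sum to within `tol`.
#' @param metadata Optional list of free-text provenance fields.
#' @param tol Tolerance for the `sum(T[, 5]) == v_pits` consistency check.
#'   The default accommodates tables published at 4-decimal precision.
#' @return An object of class `value_algorithm` with elements `decrements`,
#'   `omega`, `v_pits`, `metadata`.
#' @seealso [norwegian_algorithm()], [build_algorithm()], [score_state()]
#' @export
value_algorithm <- function(decrements, omega = 1, v_pits = NULL,
                            metadata = NULL, tol = 2e-3) {
  T <- as.matrix(decrements)
  storage.mode(T) <- "double"
  if (!identical(dim(T), c(15L, 5L))) {
    stop(sprintf("a value algorithm table is 15 x 5, got %d x %d",
                 nrow(T), ncol(T)), call. = FALSE)
  }
  if (!is.null(rownames(T))) {
    if (!setequal(rownames(T), DIM_NAMES)) {
      stop("row names must be the 15 canonical dimension names; missing: ",
           paste(setdiff(DIM_NAMES, rownames(T)), collapse = ", "),
           call. = FALSE)
    }
    T <- T[DIM_NAMES, , drop = FALSE]
  } else {
    rownames(T) <- DIM_NAMES
  }
  colnames(T) <- LEVEL_LABELS
  if (anyNA(T)) stop("missing entries in the decrement table", call. = FALSE)
  if (any(T < 0)) {
    bad <- which(T < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative decrement at (%s, %s)",
                 rownames(T)[bad[1]], colnames(T)[bad[2]]), call. = FALSE)
  }
  if (any(T[, 1] != 0)) {
    stop("level-1 decrements must all be 0 (no value loss at full function)",
         call. = FALSE)
  }
  l5_sum <- sum(T[, 5])
  v_pits <- v_pits %||% l5_sum
  if (abs(l5_sum - v_pits) > tol) {
    stop(sprintf(
      "level-5 column sum (%.6f) inconsistent with v_pits metadata (%.6f)",
      l5_sum, v_pits), call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega <= 0) {
    stop("omega must be a single positive number", call. = FALSE)
  }
  structure(
    list(decrements = T, omega = omega, v_pits = v_pits,
         metadata = metadata %||% list()),
    class = "value_algorithm"
  )
}

#' @export
print.value_algorithm <- function(x, digits = 4, ...) {
  cat("15D value algorithm\n")
  src <- x$metadata$source
  if (!is.null(src)) cat("  source:", src, "\n")
  cat(sprintf("  v_pits = %.4f, omega = %.4f\n", x$v_pits, x$omega))
  cat(sprintf("  health-state values span [%.4f, 1]\n", 1 - sum(x$decrements[, 5])))
  print(round(x$decrements, digits))
  invisible(x)
}

#' Read a value-algorithm table from disk
#'
#' The on-disk layout is a CSV whose first column `level` labels the rows
#' `level_2` ... `level_5` and whose remaining columns are the 15 canonical
#' dimensions; level 1 is implicit (all decrements zero). A companion JSON
#' file carries `omega`, `v_pits` and `source` metadata. Reading and writing
#' round-trip bit-identically at the declared 4-decimal export precision.
#'
#' @param path Path to the CSV table.
#' @param metadata_path Path to the companion JSON; defaults to `path` with
#'   its extension replaced by `.json`. A missing metadata file is allowed:
#'   `v_pits` then defaults to the level-5 column sum and `omega` to 1.
#' @param tol Consistency tolerance passed to [value_algorithm()].
#' @return A `value_algorithm`.
#' @export
read_algorithm_table <- function(path, metadata_path = NULL, tol = 2e-3) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"level" %in% names(df)) {
    stop("algorithm table must have a leading 'level' column", call. = FALSE)
  }
  missing_dims <- setdiff(DIM_NAMES, names(df))
  if (length(missing_dims)) {
    stop("algorithm table is missing dimension column(s): ",
         paste(missing_dims, collapse = ", "), call. = FALSE)
  }
  want <- LEVEL_LABELS[2:5]
  if (!setequal(df$level, want)) {
    stop("algorithm table rows must be labelled level_2 .. level_5",
         call. = FALSE)
  }
  df <- df[match(want, df$level), , drop = FALSE]
  T <- matrix(0, nrow = 15, ncol = 5, dimnames = list(DIM_NAMES, LEVEL_LABELS))
  T[, 2:5] <- t(as.matrix(df[, DIM_NAMES]))

  metadata_path <- metadata_path %||% sub("\\.[^.]+$", ".json", path)
  omega <- 1
  v_pits <- NULL
  meta <- list()
  if (file.exists(metadata_path)) {
    meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
    omega <- meta$omega %||% 1
    v_pits <- meta$v_pits
  }
  value_algorithm(T, omega = omega, v_pits = v_pits,
                  metadata = meta[setdiff(names(meta), c("omega", "v_pits"))],
                  tol = tol)
}

#' Write a value-algorithm table to disk
#'
#' Decrements are exported rounded to `digits` decimals (the published
#' precision); the companion JSON stores `omega`, `v_pits` (rounded the same
#' way) and any `source` metadata.
#'
#' @param algorithm A `value_algorithm`.
#' @param path Output CSV path.
#' @param metadata_path Output JSON path; defaults to `path` with a `.json`
#'   extension.
#' @param digits Export precision (decimal places).
#' @return Invisibly, `path`.
#' @export
write_algorithm_table <- function(algorithm, path, metadata_path = NULL,
                                  digits = 4) {
  stopifnot(inherits(algorithm, "value_algorithm"))
  T <- round(algorithm$decrements, digits)
  df <- data.frame(level = LEVEL_LABELS[2:5], t(T[, 2:5]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("level", DIM_NAMES)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  metadata_path <- metadata_path %||% sub("\\.[^.]+$", ".json", path)
  meta <- c(list(omega = round(algorithm$omega, 6),
                 v_pits = round(algorithm$v_pits, digits)),
            algorithm$metadata)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The Norwegian 15D value algorithm
#'
#' The packaged Norwegian disutility table: 15 dimensions x levels 2-5 at
#' 4-decimal precision, with level 1 fixed at zero decrement. Its level-5
#' column sums to 1.5158, so health-state values span \[-0.5158, 1\]
#' (printed as -0.52 to 1). The pits anchor `v_pits = 1.5158` equals that
#' column sum by construction of the estimation procedure.
#'
#' @return A `value_algorithm`.
#' @export
#' @examples
#' algo <- norwegian_algorithm()
#' score_state(rep(5, 15), algo)
norwegian_algorithm <- function() {
  read_algorithm_table(
    system.file("extdata", "norwegian_15d_algorithm.csv", package = "vas15d",
                mustWork = TRUE))
}

#' Norwegian general-population margins (2010)
#'
#' Marginal counts of the Norwegian adult general population by gender, age
#' group and education, as used for post-stratification of the valuation
#' sample. Only marginal counts are available, so this table supports
#' marginal weighting exactly; crossed-cell weighting needs a joint table.
#' Note the population counts include residents from age 16 while the
#' valuation sample starts at 18; the youngest band is labelled `18-24`
#' throughout for consistency with the sample.
#'
#' @return A data frame with columns `variable`, `category`, `count`.
#' @export
norwegian_population <- function() {
  read_population(
    system.file("extdata", "norwegian_population_2010.csv", package = "vas15d",
                mustWork = TRUE))
}

#' Unweighted composition of the Norwegian valuation sample
#'
#' Marginal counts of the 2,256 respondents of the Norwegian within-dimension
#' valuation survey by gender, age group and education. Useful for
#' reconstructing the published post-stratification ratios (e.g. the men's
#' gender-only weight of about 1.03).
#'
#' @return A data frame with columns `variable`, `category`, `count`.
#' @export
norwegian_sample_margins <- function() {
  data.frame(
    variable = c("gender", "gender",
                 rep("age_group", 5), rep("education", 5)),
    category = c("men", "women", AGE_LEVELS,
                 "elementary_school", "high_school", "university_ba",
                 "university_ma", "no_formal_education"),
    count = c(1089, 1167,
              140, 433, 895, 360, 428,
              472, 960, 449, 318, 57),
    stringsAsFactors = FALSE
  )
}
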