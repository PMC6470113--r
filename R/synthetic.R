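# Synthetic valuation-study generator. The construction inverts the
# estimation algebra: a respondent first places "being dead" at d on the VAS,
# then rates level i of dimension j at 100 - S[j,i] * (100 - d) plus noise,
# clamped to the VAS bounds. With zero noise the Step 1-3 pipeline recovers
# the truth table exactly, which is the basis of the round-trip tests.

#' @noRd
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  u <- runif(n)
  if (sd == 0) {
    rep(min(max(mean, lower), upper), n)
  } else {
    p_lo <- pnorm(lower, mean, sd)
    p_hi <- pnorm(upper, mean, sd)
    qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  }
}

#' @noRd
clamp01_100 <- function(x) pmin(pmax(x, 0), 100)

#' Configuration for the synthetic valuation-study generator
#'
#' Bundles the ground truth and the sampling design of a simulated VAS
#' valuation study. The defaults emulate the Norwegian study conditions: the
#' packaged Norwegian table as truth, 2,256 within-dimension respondents and
#' 120 pits-task respondents, demographic margins drawn from the 2010
#' general-population table, and a pits task in which 48/118 of respondents
#' place both the pits state and "being dead" at zero.
#'
#' @param seed Integer seed; mandatory, every stochastic call derives its
#'   sub-stream from it (demographics at `seed + 101 + stream`, within
#'   responses at `seed + 202`, pits responses at `seed + 303`), so any part
#'   of a study is independently reproducible.
#' @param truth A `value_algorithm`, or a list with elements `S` (15 x 5
#'   relative-score matrix, zero first column) and `v_pits`. An algorithm is
#'   converted via `S = T / omega`; estimates depend on `S` only through
#'   ratios, so this scale choice is immaterial.
#' @param n_within,n_pits Respondents in the within-dimension study and the
#'   pits study.
#' @param noise_sd Response noise, VAS units (truncated-normal dead
#'   placement, normal level noise with clamping). 0 gives the exact
#'   deterministic construction.
#' @param dead_location Mean VAS placement of "being dead" per task, in
#'   \[0, 100): either one number for all tasks or a named vector
#'   `c(within = , pits = )`. The pits default of 40 is the lowest round
#'   value consistent with the Norwegian anchor: a pits disutility of 1.52
#'   with non-negative pits scores forces the mean dead score above
#'   `100 * (1 - 1/1.52) = 34`.
#' @param missing_rate Per-field missingness probability in \[0, 1).
#' @param pits_zero_mass Probability that a pits respondent scores both the
#'   pits state and "being dead" at exactly zero.
#' @param demographics_margins Marginal population table used to draw
#'   respondent demographics (variables independent; supply a joint table to
#'   [generate_demographics()] directly for crossed structure).
#' @param s_scale_by_education Optional named numeric vector of
#'   multiplicative preference shifts, e.g. `c(university_ma = 1.3)`: those
#'   respondents hold relative scores `1.3 * S`. This is the mechanism that
#'   makes post-stratification matter in validation studies.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             truth = norwegian_algorithm(),
                             n_within = 2256,
                             n_pits = 120,
                             noise_sd = 10,
                             dead_location = c(within = 15, pits = 40),
                             missing_rate = 0.02,
                             pits_zero_mass = 48 / 118,
                             demographics_margins = norwegian_population(),
                             s_scale_by_education = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (inherits(truth, "value_algorithm")) {
    S <- truth$decrements / truth$omega
    v_pits <- truth$v_pits
  } else if (is.list(truth) && !is.null(truth$S) && !is.null(truth$v_pits)) {
    S <- as.matrix(truth$S)
    v_pits <- truth$v_pits
    if (is.null(rownames(S))) rownames(S) <- DIM_NAMES
    colnames(S) <- LEVEL_LABELS
  } else {
    stop("truth must be a value_algorithm or a list(S =, v_pits =)",
         call. = FALSE)
  }
  if (length(dead_location) == 1L && is.null(names(dead_location))) {
    dead_location <- c(within = unname(dead_location), pits = unname(dead_location))
  }
  if (!all(c("within", "pits") %in% names(dead_location))) {
    stop("dead_location must be one number or c(within = , pits = )",
         call. = FALSE)
  }
  dead_location <- dead_location[c("within", "pits")]
  stopifnot(identical(dim(S), c(15L, 5L)), all(S >= 0), all(S[, 1] == 0),
            v_pits > 0,
            n_within >= 1, n_pits >= 1,
            noise_sd >= 0,
            all(dead_location >= 0), all(dead_location < 100),
            missing_rate >= 0, missing_rate < 1,
            pits_zero_mass >= 0, pits_zero_mass <= 1)
  if (v_pits * (100 - dead_location[["pits"]]) > 100) {
    warning(sprintf(
      "dead_location['pits'] = %g cannot represent v_pits = %.3f without truncation at 0; pits estimates will be biased low",
      dead_location[["pits"]], v_pits), call. = FALSE)
  }
  if (!is.null(s_scale_by_education)) {
    check_categories(names(s_scale_by_education), "education")
    stopifnot(all(s_scale_by_education > 0))
  }
  structure(
    list(seed = seed, S = S, v_pits = v_pits,
         n_within = as.integer(n_within), n_pits = as.integer(n_pits),
         noise_sd = noise_sd, dead_location = dead_location,
         missing_rate = missing_rate, pits_zero_mass = pits_zero_mass,
         demographics_margins = demographics_margins,
         s_scale_by_education = s_scale_by_education),
    class = "generator_config"
  )
}

#' The truth table implied by a generator configuration
#'
#' @param config A `generator_config`.
#' @return The `value_algorithm` that a perfect (noise-free, fully complete)
#'   study generated from `config` estimates.
#' @export
truth_algorithm <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  build_algorithm(config$S, config$v_pits,
                  metadata = list(source = "synthetic ground truth"))
}

#' Draw synthetic respondent demographics
#'
#' Each variable is drawn independently from its marginal distribution in
#' `config$demographics_margins` (crossed cells arise implicitly). A joint
#' population table (demographic columns plus `count`) may be supplied in
#' the config instead, in which case whole cells are drawn jointly.
#'
#' @param config A `generator_config`.
#' @param n Number of respondents; defaults to `config$n_within`.
#' @param variables Demographic variables to generate.
#' @param id_prefix Prefix for the generated respondent ids.
#' @param stream Integer sub-stream index, so several demographic draws from
#'   one config (e.g. within sample and pits sample) are independent.
#' @return A demographics data frame.
#' @export
generate_demographics <- function(config, n = config$n_within,
                                  variables = c("gender", "age_group", "education"),
                                  id_prefix = "R", stream = 0L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 101L + as.integer(stream))
  margins <- config$demographics_margins
  out <- data.frame(respondent_id = sprintf("%s%05d", id_prefix, seq_len(n)),
                    stringsAsFactors = FALSE)
  if (is_marginal_population(margins)) {
    for (v in variables) {
      sub <- margins[margins$variable == v, , drop = FALSE]
      if (!nrow(sub)) {
        stop(sprintf("margins have no counts for variable '%s'", v),
             call. = FALSE)
      }
      if (sum(sub$count) <= 0) {
        stop(sprintf("margins for '%s' do not normalize", v), call. = FALSE)
      }
      out[[v]] <- sample(sub$category, n, replace = TRUE,
                         prob = sub$count / sum(sub$count))
    }
  } else {
    cells <- margins[sample.int(nrow(margins), n, replace = TRUE,
                                prob = margins$count / sum(margins$count)), ,
                     drop = FALSE]
    for (v in variables) out[[v]] <- cells[[v]]
  }
  validate_demographics(out, variables)
  out
}

#' Generate within-dimension task responses
#'
#' For each respondent and each dimension: "being dead" is placed at
#' `d ~ TruncNormal(dead_location, noise_sd)` on \[0, 99\]; level `i` is
#' scored `100 - S[j,i] * (100 - d) + e`, `e ~ Normal(0, noise_sd)`, clamped
#' to \[0, 100\]. Each score field is then independently missing with
#' probability `missing_rate`. With `noise_sd = 0` and no missingness the
#' construction inverts the relative-score formula exactly.
#'
#' @param config A `generator_config`.
#' @param demographics Optional demographics frame supplying respondent ids
#'   and (for `s_scale_by_education`) education; if `NULL`, plain ids are
#'   generated for `config$n_within` respondents.
#' @return A within-dimension response data frame.
#' @export
generate_within_responses <- function(config, demographics = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 202L)
  if (is.null(demographics)) {
    ids <- sprintf("R%05d", seq_len(config$n_within))
    edu <- rep(NA_character_, config$n_within)
  } else {
    ids <- as.character(demographics$respondent_id)
    edu <- if ("education" %in% names(demographics)) {
      as.character(demographics$education)
    } else {
      rep(NA_character_, nrow(demographics))
    }
  }
  n <- length(ids)
  scale_r <- rep(1, n)
  if (!is.null(config$s_scale_by_education)) {
    hit <- edu %in% names(config$s_scale_by_education)
    scale_r[hit] <- config$s_scale_by_education[edu[hit]]
  }
  S <- config$S
  d <- matrix(rtrunc_norm(n * 15L, config$dead_location[["within"]],
                          config$noise_sd, 0, 99),
              n, 15L)
  parts <- vector("list", 15L)
  for (j in seq_len(15L)) {
    gap <- 100 - d[, j]
    df <- data.frame(respondent_id = ids, dimension = DIM_NAMES[j],
                     stringsAsFactors = FALSE)
    for (i in 2:5) {
      s <- clamp01_100(100 - scale_r * S[j, i] * gap +
                         rnorm(n, 0, config$noise_sd))
      df[[SCORE_COLS[i - 1]]] <- s
    }
    df$score_dead <- d[, j]
    if (config$missing_rate > 0) {
      mask <- matrix(runif(n * 5L) < config$missing_rate, n, 5L)
      for (k in seq_len(5L)) df[[SCORE_COLS[k]]][mask[, k]] <- NA_real_
    } else {
      runif(n * 5L)  # keep the RNG stream aligned across missingness settings
    }
    parts[[j]] <- df
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Generate pits-task responses
#'
#' Same construction as the within-dimension tasks with the truth `v_pits`
#' in place of `S`: "being dead" at `d`, pits state at
#' `100 - v_pits * (100 - d) + e`, clamped. A point mass at zero mimics
#' respondents who place both the pits state and "being dead" at the bottom
#' of the scale; with `v_pits > 1` a share of the remaining respondents
#' rates the pits state below "being dead", as the Norwegian sample did.
#'
#' @param config A `generator_config`.
#' @param demographics Optional demographics frame supplying respondent ids;
#'   if `NULL`, ids `P00001` ... are generated for `config$n_pits`
#'   respondents.
#' @return A pits response data frame.
#' @export
generate_pits_responses <- function(config, demographics = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 303L)
  ids <- if (is.null(demographics)) {
    sprintf("P%05d", seq_len(config$n_pits))
  } else {
    as.character(demographics$respondent_id)
  }
  n <- length(ids)
  zero <- runif(n) < config$pits_zero_mass
  d <- rtrunc_norm(n, config$dead_location[["pits"]], config$noise_sd, 0, 99)
  s_pits <- clamp01_100(100 - config$v_pits * (100 - d) +
                          rnorm(n, 0, config$noise_sd))
  s_dead <- d
  s_pits[zero] <- 0
  s_dead[zero] <- 0
  out <- data.frame(respondent_id = ids, score_pits = s_pits,
                    score_dead = s_dead, stringsAsFactors = FALSE)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * 2L) < config$missing_rate, n, 2L)
    out$score_pits[mask[, 1]] <- NA_real_
    out$score_dead[mask[, 2]] <- NA_real_
  } else {
    runif(n * 2L)
  }
  out
}

#' Simulate a complete valuation study
#'
#' Generates demographics, within-dimension responses and pits responses
#' from one configuration. The within sample carries gender, age and
#' education; the pits sample, mirroring the face-to-face collection design,
#' reports gender and age only (education is `NA`).
#'
#' @param config A `generator_config`.
#' @return A list with elements `within`, `pits`, `demographics` (both
#'   samples stacked), and `truth` (the implied `value_algorithm`).
#' @export
#' @examples
#' sim <- simulate_valuation_study(generator_config(seed = 1, n_within = 50,
#'                                                  n_pits = 20))
#' str(sim$within)
simulate_valuation_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  demo_within <- generate_demographics(config, config$n_within,
                                       c("gender", "age_group", "education"),
                                       id_prefix = "R", stream = 0L)
  demo_pits <- generate_demographics(config, config$n_pits,
                                     c("gender", "age_group"),
                                     id_prefix = "P", stream = 1L)
  demo_pits$education <- NA_character_
  within <- generate_within_responses(config, demo_within)
  pits <- generate_pits_responses(config, demo_pits)
  list(within = within, pits = pits,
       demographics = rbind(demo_within, demo_pits),
       truth = truth_algorithm(config))
}
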