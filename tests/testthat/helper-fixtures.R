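# Shared fixtures, all built in code.

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Smooth monotone relative-score table with distinct rows, plus an anchor.
toy_S <- function() {
  S <- matrix(0, 15, 5,
              dimnames = list(fifteen_dimensions(), paste0("level_", 1:5)))
  base <- seq(0.2, 0.9, length.out = 15)
  for (i in 2:5) S[, i] <- base * (i - 1) / 4
  S
}

toy_truth <- function(v_pits = 1.2) list(S = toy_S(), v_pits = v_pits)

# Noise-free within-dimension responses implied by a relative-score table:
# every respondent places "dead" at `dead` and each level at the exact
# inversion of the relative-score formula.
exact_within <- function(ids, S, dead = 20, scale = 1) {
  do.call(rbind, lapply(rownames(S), function(j) {
    data.frame(
      respondent_id = ids, dimension = j,
      score_L2 = 100 - scale * S[j, 2] * (100 - dead),
      score_L3 = 100 - scale * S[j, 3] * (100 - dead),
      score_L4 = 100 - scale * S[j, 4] * (100 - dead),
      score_L5 = 100 - scale * S[j, 5] * (100 - dead),
      score_dead = dead, stringsAsFactors = FALSE
    )
  }))
}

exact_pits <- function(ids, v_pits, dead = 40) {
  data.frame(respondent_id = ids,
             score_pits = 100 - v_pits * (100 - dead),
             score_dead = dead, stringsAsFactors = FALSE)
}

uniform_demo <- function(ids) {
  n <- length(ids)
  data.frame(respondent_id = ids,
             gender = rep_len(c("men", "women"), n),
             age_group = rep_len(demographic_levels("age_group"), n),
             education = rep_len(demographic_levels("education"), n),
             stringsAsFactors = FALSE)
}
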