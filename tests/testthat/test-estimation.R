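test_that("weighted level means follow the stated closed forms", {
  S <- toy_S()
  w1 <- exact_within("r1", S, dead = 20)
  w2 <- exact_within("r2", S, dead = 20)
  # single respondent: their scores verbatim
  m1 <- weighted_level_means(w1)
  expect_equal(unname(m1["mobility", "level_2"]), w1$score_L2[1])
  expect_equal(unname(m1[, "dead"]), rep(20, 15))
  expect_equal(unname(m1[, "level_1"]), rep(100, 15))

  # two respondents, equal weights: arithmetic mean
  both <- rbind(w1, w2)
  both$score_L3[both$dimension == "mobility"] <- c(40, 60)
  m2 <- weighted_level_means(both)
  expect_equal(unname(m2["mobility", "level_3"]), 50)

  # 3:1 weights on scores 0 and 100
  both$score_L2[both$dimension == "mobility"] <- c(0, 100)
  wt <- data.frame(task = rep(rownames(S), each = 2),
                   respondent_id = rep(c("r1", "r2"), 15),
                   weight = rep(c(3, 1), 15))
  m3 <- weighted_level_means(both, wt)
  expect_equal(unname(m3["mobility", "level_2"]), 25)

  # respondents contribute only to the cells they answered
  both$score_L4[both$dimension == "vision"] <- c(NA, 70)
  m4 <- weighted_level_means(both)
  expect_equal(unname(m4["vision", "level_4"]), 70)
  # ... unless full-case mode drops the partial response
  both$score_L5[both$dimension == "vision"] <- c(55, 66)
  m5 <- weighted_level_means(both, complete_cases = TRUE)
  expect_equal(unname(m5["vision", "level_5"]), 66)
})

test_that("missing dimensions and empty cells are hard errors", {
  S <- toy_S()
  w <- exact_within(c("r1", "r2"), S)
  expect_error(weighted_level_means(w[w$dimension != "hearing", ]), "hearing")
  w$score_L2[w$dimension == "sleep"] <- NA
  expect_error(weighted_level_means(w), "sleep, level_2")
})

test_that("relative scores are the dead-anchored ratios, per dimension", {
  m <- matrix(100, 15, 6,
              dimnames = list(fifteen_dimensions(),
                              c(paste0("level_", 1:5), "dead")))
  m[, "dead"] <- 0
  m[, "level_2"] <- 50
  m["mobility", "dead"] <- 10
  m["mobility", "level_5"] <- 5
  S <- relative_scores(m)
  expect_equal(unname(S[, "level_1"]), rep(0, 15))
  expect_equal(unname(S["vision", "level_2"]), 0.5)
  # s = 100 gives 0 regardless of the dead anchor
  expect_equal(unname(S["vision", "level_3"]), 0)
  # a level scored below dead exceeds 1 (here with mobility's own anchor)
  expect_equal(unname(S["mobility", "level_5"]), 95 / 90)
  # dead mean at 100 is rejected per dimension
  m["sleep", "dead"] <- 100
  expect_error(relative_scores(m), "sleep")
  m["sleep", "dead"] <- 99.5
  expect_error(relative_scores(m), "sleep")
  expect_silent(relative_scores(m, min_dead_gap = 0.1))
})

test_that("the pits completeness filter retains exactly the complete records", {
  pits <- exact_pits(sprintf("P%03d", 1:120), v_pits = 1.5)
  pits$score_pits[5] <- NA
  pits$score_dead[77] <- NA
  flt <- filter_complete_pits(pits)
  expect_identical(nrow(flt$complete), 118L)
  expect_identical(flt$n_excluded, 2L)
  # identity on fully complete data
  all_in <- filter_complete_pits(exact_pits(c("a", "b"), 1.2))
  expect_identical(all_in$n_excluded, 0L)
  expect_identical(nrow(all_in$complete), 2L)
  # all incomplete: empty result, downstream fails loudly
  none <- data.frame(respondent_id = c("a", "b"),
                     score_pits = c(NA_real_, 2), score_dead = c(3, NA_real_))
  expect_identical(filter_complete_pits(none)$n_excluded, 2L)
  expect_error(pits_estimate(none), "no complete pits responses")
})

test_that("pits estimation anchors correctly, including worse-than-dead", {
  p <- data.frame(respondent_id = "a", score_pits = 20, score_dead = 10)
  expect_equal(pits_estimate(p)$v_pits, 80 / 90)
  # pits exactly at dead: disutility 1
  p2 <- data.frame(respondent_id = c("a", "b"),
                   score_pits = c(30, 30), score_dead = c(30, 30))
  expect_equal(pits_estimate(p2)$v_pits, 1)
  # pits below dead: disutility above 1 (worse than dead)
  p3 <- data.frame(respondent_id = "a", score_pits = 5, score_dead = 30)
  expect_gt(pits_estimate(p3)$v_pits, 1)
  expect_equal(pits_estimate(p3)$v_pits, 95 / 70)
  # weights flow into the means
  p4 <- data.frame(respondent_id = c("a", "b"),
                   score_pits = c(0, 100), score_dead = c(0, 0))
  wt <- data.frame(task = "pits", respondent_id = c("a", "b"), weight = c(3, 1))
  expect_equal(pits_estimate(p4, wt)$v_pits, (100 - 25) / 100)
  expect_error(pits_estimate(data.frame(respondent_id = "a", score_pits = 50,
                                        score_dead = 99.9)),
               "too close to 100")
})

test_that("build_algorithm rescales so the level-5 sum reproduces v_pits", {
  S <- toy_S()
  # closed form: v_pits / sum(S5) scales every cell
  algo <- build_algorithm(S, 1.5)
  expect_equal(algo$omega, 1.5 / sum(S[, 5]))
  expect_equal(algo$decrements, algo$omega * S, ignore_attr = TRUE)
  expect_equal(sum(algo$decrements[, 5]), 1.5, tolerance = 1e-12)
  # omega = 1 identity when v_pits equals the level-5 sum
  algo2 <- build_algorithm(S, sum(S[, 5]))
  expect_equal(algo2$omega, 1)
  expect_equal(algo2$decrements, S, ignore_attr = TRUE)
  expect_error(build_algorithm(matrix(0, 15, 5), 1.5), "positive")
})

test_that("noise-free synthetic data is recovered exactly, for any truth table", {
  for (truth in list(toy_truth(1.2), norwegian_algorithm())) {
    cfg <- generator_config(seed = 5, truth = truth, n_within = 120,
                            n_pits = 40, noise_sd = 0, missing_rate = 0,
                            pits_zero_mass = 0)
    sim <- simulate_valuation_study(cfg)
    est <- estimate_algorithm(sim$within, sim$pits, sim$demographics,
                              norwegian_population(), scheme = "marginal")
    expect_lt(max(abs(est$decrements - sim$truth$decrements)), 1e-9)
    expect_equal(est$v_pits, sim$truth$v_pits, tolerance = 1e-12)
  }
})

test_that("estimates are invariant under duplicating every respondent", {
  cfg <- generator_config(seed = 9, n_within = 80, n_pits = 30, noise_sd = 8,
                          missing_rate = 0, pits_zero_mass = 0)
  sim <- simulate_valuation_study(cfg)
  dup_ids <- function(df) {
    d <- df
    d$respondent_id <- paste0(d$respondent_id, "_b")
    rbind(df, d)
  }
  est1 <- estimate_algorithm(sim$within, sim$pits, sim$demographics,
                             norwegian_population(), scheme = "marginal")
  est2 <- estimate_algorithm(dup_ids(sim$within), dup_ids(sim$pits),
                             dup_ids(sim$demographics),
                             norwegian_population(), scheme = "marginal")
  expect_equal(est1$decrements, est2$decrements, tolerance = 1e-12)
  expect_equal(est1$v_pits, est2$v_pits, tolerance = 1e-12)
})

test_that("relative scores are invariant under per-task affine VAS maps", {
  S <- toy_S()
  ids <- sprintf("r%02d", 1:6)
  w <- exact_within(ids, S, dead = 25)
  # contract all mobility-task distances to 100 by a common factor c,
  # dead included: score -> 100 - c * (100 - score)
  c_factor <- 0.6
  rows <- w$dimension == "mobility"
  for (col in c("score_L2", "score_L3", "score_L4", "score_L5", "score_dead")) {
    w[[col]][rows] <- 100 - c_factor * (100 - w[[col]][rows])
  }
  S_hat <- relative_scores(weighted_level_means(w))
  expect_equal(S_hat, S, tolerance = 1e-12)
})

test_that("estimation log records the audit trail", {
  cfg <- generator_config(seed = 3, n_within = 60, n_pits = 25, noise_sd = 5,
                          missing_rate = 0.1, pits_zero_mass = 0)
  sim <- simulate_valuation_study(cfg)
  est <- estimate_algorithm(sim$within, sim$pits, sim$demographics,
                            norwegian_population(), scheme = "marginal")
  log <- attr(est, "estimation_log")
  expect_identical(log$scheme, "marginal")
  expect_identical(log$pits_vars, c("gender", "age_group"))
  expect_length(log$completers_per_task, 15)
  expect_true(all(unlist(log$completers_per_task) <= 60))
  expect_identical(log$pits_n_complete + log$pits_n_excluded, 25L)
  expect_equal(log$v_pits, est$v_pits)
  expect_equal(log$omega, est$omega)
})

test_that("weighting recovers mixture preferences when the sample is skewed", {
  # two education groups hold different preferences; the sample
  # over-represents the group whose disutilities are 40% larger
  S <- toy_S()
  v_base <- 0.9  # keeps 1.4 * v_base * (100 - dead) inside the VAS bounds
  share_pop <- c(high_school = 0.8, university_ma = 0.2)
  n_hs <- 30
  n_ma <- 70  # sample share 0.7 vs population share 0.2
  ids <- sprintf("r%03d", seq_len(n_hs + n_ma))
  edu <- rep(c("high_school", "university_ma"), c(n_hs, n_ma))
  demo <- data.frame(respondent_id = ids, education = edu,
                     stringsAsFactors = FALSE)
  dead <- 30
  w <- rbind(exact_within(ids[seq_len(n_hs)], S, dead = dead),
             exact_within(ids[-seq_len(n_hs)], S, dead = dead, scale = 1.4))
  p <- rbind(exact_pits(ids[seq_len(n_hs)], v_base, dead = dead),
             exact_pits(ids[-seq_len(n_hs)], 1.4 * v_base, dead = dead))
  pop <- data.frame(variable = "education",
                    category = names(share_pop),
                    count = share_pop * 1000)
  # truth: the population mixture (common dead location, so the ratio of
  # weighted means is the plain mixture of the group-level scores)
  S_mix <- 0.8 * S + 0.2 * 1.4 * S
  truth <- build_algorithm(S_mix, 0.8 * v_base + 0.2 * 1.4 * v_base)

  est_w <- estimate_algorithm(w, p, demo, pop, scheme = "marginal",
                              vars = "education", pits_vars = "education")
  est_u <- estimate_algorithm(w, p)
  expect_lt(rmse(est_w$decrements, truth$decrements),
            rmse(est_u$decrements, truth$decrements))
  expect_lt(rmse(est_w$decrements, truth$decrements), 1e-9)
  expect_equal(est_w$v_pits, truth$v_pits, tolerance = 1e-12)
})
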