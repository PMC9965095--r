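test_that("questionnaire dichotomisation follows the category rules and propagates missing", {
  expect_identical(
    flag_exhaustion(c("often (3-4 days)", "most (5-7 days)",
                      "rarely (<1 day)", "some (1-2 days)", NA)),
    c(1L, 1L, 0L, 0L, NA_integer_))
  expect_error(flag_exhaustion("sometimes"), class = "frailscreen_coding_error")

  expect_identical(flag_weight_loss(c("yes", "no", NA)), c(1L, 0L, NA_integer_))
  expect_error(flag_weight_loss("maybe"), class = "frailscreen_coding_error")

  expect_identical(
    flag_low_activity(c("hardly ever or never", "1-3 times a month",
                        "once a week", "more than once a week",
                        "every day", NA)),
    c(1L, 1L, 0L, 0L, 0L, NA_integer_))
  expect_error(flag_low_activity("weekly"), class = "frailscreen_coding_error")
})

test_that("trial averaging uses present trials and yields NA only when both are missing", {
  expect_equal(mean_of_trials(30, 34), 32)
  expect_equal(mean_of_trials(30, NA), 30)
  expect_equal(mean_of_trials(NA, 28), 28)
  expect_true(is.na(mean_of_trials(NA_real_, NA_real_)))
  expect_equal(mean_of_trials(c(30, NA, 10), c(34, 6, NA)), c(32, 6, 10))
})

test_that("cutoffs use the lower-value quantile convention", {
  cohort <- make_cohort(10, grip = 1:10, walk = 1:10)
  cuts <- derive_cutoffs(cohort, scoring_config())
  grip_thr <- cuts$threshold[cuts$measure == "grip"]
  expect_equal(unique(grip_thr), 2)           # 20th percentile of 1..10
  walk_thr <- cuts$threshold[cuts$measure == "walk"]
  expect_equal(unique(walk_thr), 8)           # slowest 20% start at the 80th
})

test_that("a degenerate stratum with identical values flags everything at-or-below", {
  cohort <- make_cohort(8, grip = 5)
  cuts <- derive_cutoffs(cohort, scoring_config())
  expect_equal(unique(cuts$threshold[cuts$measure == "grip"]), 5)
  g <- flag_weak_grip(cohort, cuts, scoring_config())
  expect_true(all(g == 1L))
  g2 <- flag_weak_grip(cohort, cuts,
                       scoring_config(tie_rule = "flag_strictly_below"))
  expect_true(all(g2 == 0L))
})

test_that("per-stratum thresholds are local to their stratum", {
  # two height strata with disjoint walk-time ranges
  cohort <- make_cohort(20,
                        height = rep(c(150, 170), each = 10),
                        walk = c(1:10, 101:110))
  cuts <- derive_cutoffs(cohort, scoring_config())
  wt <- cuts[cuts$measure == "walk", ]
  expect_equal(wt$threshold[wt$stratum == "height <= median"],
               quantile_oracle(1:10, 0.8))
  expect_equal(wt$threshold[wt$stratum == "height > median"],
               quantile_oracle(101:110, 0.8))
})

test_that("thresholds match the sort-and-index oracle on small strata", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    vals <- round(runif(n, 5, 50), 1)
    cohort <- make_cohort(n, grip = vals)
    p <- sample(c(0.2, 0.25, 0.4), 1)
    cuts <- derive_cutoffs(cohort, scoring_config(quintile_proportion = p))
    expect_equal(unique(cuts$threshold[cuts$measure == "grip"]),
                 quantile_oracle(vals, p))
  }
})

test_that("tie handling: a grip mean exactly at the threshold is flagged by default", {
  cohort <- make_cohort(10, grip = 1:10)
  cfg <- scoring_config()
  cuts <- derive_cutoffs(cohort, cfg)
  g <- flag_weak_grip(cohort, cuts, cfg)
  expect_equal(g, as.integer(1:10 <= 2))
  w <- flag_slow_walk(make_cohort(10, walk = 1:10),
                      derive_cutoffs(make_cohort(10, walk = 1:10), cfg), cfg)
  expect_equal(w[10], 1L)  # slowest walker always flagged under slowest_flagged
})

test_that("scoring sums flags, applies the deficit threshold, and drops incomplete rows", {
  # distinct measures put known rows in the flagged tails:
  # G = rows 1-2, W = rows 1-3, E = rows 1-3, L = rows 1-2, P = rows 1-3
  n <- 10
  cohort <- make_cohort(n,
                        grip = c(1, 2, 30:37),
                        walk = c(101, 102, 103, seq(5.1, 5.7, by = 0.1)),
                        exhaustion = c(rep("most (5-7 days)", 3),
                                       rep("rarely (<1 day)", n - 3)),
                        weight_loss = c(rep("yes", 2), rep("no", n - 2)),
                        activity = c(rep("hardly ever or never", 3),
                                     rep("every day", n - 3)))
  scores <- score_and_classify(cohort)
  expect_s3_class(scores, "frailty_scores")
  expect_equal(scores$flags$S[1:3], c(5L, 5L, 3L))
  expect_equal(scores$flags$S[4:10], rep(0L, 7))
  expect_equal(scores$flags$frail, as.integer(scores$flags$S >= 3))
  expect_equal(sum(scores$flags$frail), 3L)

  # drop rule: any missing component removes the row and is counted
  cohort$grip_trial1[4] <- NA; cohort$grip_trial2[4] <- NA
  cohort$exhaustion_response[5] <- NA
  scores2 <- score_and_classify(cohort)
  expect_equal(scores2$n_dropped, 2L)
  expect_false(any(scores2$flags$id %in% cohort$id[4:5]))

  # single-trial fallback keeps the row
  cohort$grip_trial1[6] <- NA
  scores3 <- score_and_classify(cohort)
  expect_true(cohort$id[6] %in% scores3$flags$id)
})

test_that("raising the frail threshold never increases the frail count", {
  cohort <- generate_cohort(small_gen_config(n = 800, seed = 17))
  counts <- vapply(1:5, function(th) {
    sum(score_and_classify(cohort,
                           scoring_config(frail_threshold = th))$flags$frail)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("row order changes neither cutoffs nor flags", {
  cohort <- generate_cohort(small_gen_config(n = 300, seed = 23))
  cfg <- scoring_config()
  shuffled <- cohort[rev(seq_len(nrow(cohort))), ]
  a <- score_and_classify(cohort, cfg)
  b <- score_and_classify(shuffled, cfg)
  ca <- as.data.frame(a$cutoffs); cb <- as.data.frame(b$cutoffs)
  expect_equal(ca[order(ca$measure, ca$sex, ca$stratum), ],
               cb[order(cb$measure, cb$sex, cb$stratum), ],
               ignore_attr = TRUE)
  fa <- a$flags[order(a$flags$id), ]; fb <- b$flags[order(b$flags$id), ]
  expect_equal(fa, fb, ignore_attr = TRUE)
})

test_that("all-missing cohorts abort scoring with a clear error", {
  cohort <- inject_missingness(generate_cohort(small_gen_config(n = 40)), 1)
  expect_error(score_and_classify(cohort), "no complete cases",
               class = "frailscreen_scoring_error")
})

test_that("survey-weighted quantiles shift cutoffs toward heavy observations", {
  cohort <- make_cohort(10, grip = 1:10, weight = c(rep(10, 5), rep(0.1, 5)))
  cfg_w <- scoring_config(quantile_weighting = "survey_weighted")
  cuts_w <- derive_cutoffs(cohort, cfg_w)
  cuts_u <- derive_cutoffs(cohort, scoring_config())
  # weight mass sits on values 1..5, so the weighted 20% point is lower
  expect_lte(cuts_w$threshold[cuts_w$measure == "grip"][1],
             cuts_u$threshold[cuts_u$measure == "grip"][1])
})
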