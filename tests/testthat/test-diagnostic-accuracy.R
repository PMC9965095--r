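test_that("marker rules follow their truth tables", {
  flags <- make_flags(E = c(0, 0), G = c(1, 0), W = c(0, 0),
                      L = c(0, 0), P = c(0, 0))
  or_gp <- marker_definition(c("G", "P"), rule = "parallel_or")
  and_gp <- marker_definition(c("G", "P"), rule = "serial_and")
  expect_equal(apply_marker(flags, or_gp), c(1L, 0L))
  expect_equal(apply_marker(flags, and_gp), c(0L, 0L))
  expect_equal(apply_marker(flags, marker_definition("G")), c(1L, 0L))
  expect_error(marker_definition("Q"), class = "frailscreen_marker_error")
  expect_error(marker_definition(c("G", "P"), rule = "single"),
               class = "frailscreen_marker_error")
  expect_equal(marker_definition(c("G", "P"))$name,
               "Grip strength and physical activity")
})

test_that("2x2 cells enumerate positivity against the frail label", {
  tab <- build_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(tab[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
  ident <- build_contingency(c(1, 0, 1), c(1, 0, 1))
  expect_equal(ident$FP + ident$FN, 0)
  expect_error(build_contingency(c(1, 0), c(1, 0, 1)),
               class = "frailscreen_marker_error")
  expect_error(build_contingency(c(1, NA), c(1, 0)),
               class = "frailscreen_marker_error")
})

test_that("uniform weights scale every cell without changing the metrics", {
  pos <- c(1, 1, 0, 0, 1, 0); frail <- c(1, 0, 1, 0, 1, 1)
  t1 <- build_contingency(pos, frail)
  t2 <- build_contingency(pos, frail, weights = rep(2, 6))
  for (cell in c("TP", "FP", "FN", "TN")) {
    expect_equal(t2[[cell]], 2 * t1[[cell]])
  }
  m1 <- metrics_from_table(t1); m2 <- metrics_from_table(t2)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$ppv, m2$ppv)
})

test_that("metrics follow the standard epidemiologic definitions", {
  sym <- metrics_from_table(build_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(unlist(sym[c("sensitivity", "specificity", "ppv", "npv",
                            "prevalence")]),
               c(sensitivity = .5, specificity = .5, ppv = .5, npv = .5,
                 prevalence = .5))

  tab <- structure(list(TP = 98, FP = 68, FN = 2, TN = 32, n = 200),
                   class = "contingency_2x2")
  m <- metrics_from_table(tab)
  expect_equal(m$sensitivity, 0.98)
  expect_equal(m$specificity, 0.32)

  undef <- metrics_from_table(build_contingency(c(0, 0), c(0, 0)))
  expect_true(is.na(undef$sensitivity))
  expect_true(is.na(undef$ppv))
  expect_setequal(attr(undef, "undefined"), c("sensitivity", "ppv"))
  expect_false(is.na(undef$specificity))
})

test_that("Wilson continuity-corrected interval honours its boundary rules and geometry", {
  expect_equal(wilson_cc(0, 10)[["lower"]], 0)
  expect_equal(wilson_cc(10, 10)[["upper"]], 1)

  ci <- wilson_cc(81, 263)
  expect_gt(ci[["lower"]], 0.25)
  expect_lt(ci[["upper"]], 0.37)
  expect_lt(ci[["lower"]], 81 / 263)
  expect_gt(ci[["upper"]], 81 / 263)

  # the interval always contains the point estimate
  for (n in c(5, 17, 40)) for (s in 0:n) {
    ci <- wilson_cc(s, n)
    expect_lte(ci[["lower"]], s / n)
    expect_gte(ci[["upper"]], s / n)
  }

  # width shrinks monotonically in n at fixed phat
  widths <- vapply(c(10, 20, 40, 80, 160, 320), function(n) {
    ci <- wilson_cc(0.3 * n, n); ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(wilson_cc(5, 0), class = "frailscreen_ci_error")
  expect_error(wilson_cc(11, 10), class = "frailscreen_ci_error")
})

test_that("Bayes identities agree with count-based metrics to machine precision", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    pos <- rbinom(n, 1, runif(1, .2, .8))
    frail <- rbinom(n, 1, runif(1, .2, .8))
    if (sum(frail) %in% c(0, n) || sum(pos) %in% c(0, n)) next
    m <- metrics_from_table(build_contingency(pos, frail))
    expect_lt(abs(m$ppv - ppv_from_bayes(m$sensitivity, m$specificity,
                                         m$prevalence)), 1e-12)
    expect_lt(abs(m$npv - npv_from_bayes(m$sensitivity, m$specificity,
                                         m$prevalence)), 1e-12)
  }
  expect_equal(ppv_from_bayes(1, 1, 0.3), 1)
  expect_true(is.na(ppv_from_bayes(0, 1, 0.5)))
})

test_that("the marker sweep covers 5 singles and 10 pairs per sex, deterministically", {
  cfg <- small_gen_config(n = 500, seed = 19)
  scores <- score_and_classify(generate_cohort(cfg), target_scoring_config(cfg))
  t3 <- evaluate_all_markers(scores)
  expect_equal(nrow(t3), 30L)
  expect_equal(sum(t3$rule == "single"), 10L)
  expect_equal(sum(t3$rule == "parallel_or"), 20L)
  expect_equal(length(unique(t3$components[t3$rule == "parallel_or"])), 10L)
  expect_identical(t3$marker, evaluate_all_markers(scores)$marker)
  expect_identical(t3[order(t3$sex, t3$marker), "sensitivity"],
                   evaluate_all_markers(scores)[order(t3$sex, t3$marker),
                                                "sensitivity"])
})

test_that("a marker identical to the frail label scores perfectly", {
  flags <- make_flags(E = c(1, 1, 0, 0, 1), G = c(1, 1, 0, 0, 0),
                      W = c(1, 1, 0, 0, 1), L = c(0, 1, 0, 0, 1),
                      P = c(0, 1, 1, 0, 0))
  flags$G <- flags$frail  # G now reproduces the label exactly
  m <- metrics_from_table(
    build_contingency(apply_marker(flags, marker_definition("G")), flags$frail))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})

test_that("parallel-OR pairs dominate their members in sensitivity on a scored cohort", {
  cfg <- small_gen_config(n = 1500, seed = 29)
  scores <- score_and_classify(generate_cohort(cfg), target_scoring_config(cfg))
  t3 <- evaluate_all_markers(scores)
  for (sx in c("male", "female")) {
    sub <- t3[t3$sex == sx, ]
    singles <- sub[sub$rule == "single", ]
    for (i in which(sub$rule == "parallel_or")) {
      comps <- strsplit(sub$components[i], "+", fixed = TRUE)[[1]]
      ind <- singles[match(comps, singles$components), ]
      expect_gte(sub$sensitivity[i], max(ind$sensitivity))
      expect_lte(sub$specificity[i], min(ind$specificity))
    }
  }
})

test_that("components rank by prevalence with alphabetical tie-breaking", {
  flags <- make_flags(E = c(1, 0, 0, 0), G = c(1, 1, 1, 0),
                      W = c(1, 1, 0, 0), L = c(1, 0, 0, 0), P = c(1, 1, 0, 0))
  r <- rank_components(flags)
  expect_equal(names(r), c("G", "P", "W", "E", "L"))
  expect_equal(attr(r, "ties"), list(c("P", "W"), c("E", "L")))

  equal <- make_flags(E = c(1, 0), G = c(1, 0), W = c(1, 0),
                      L = c(1, 0), P = c(1, 0))
  re <- rank_components(equal)
  expect_equal(names(re), c("E", "G", "L", "P", "W"))
  expect_equal(attr(re, "ties"), list(c("E", "G", "L", "P", "W")))

  rs <- rank_components(flags, criterion = "sensitivity")
  expect_equal(unname(rs["G"]), 1)  # every frail row carries G
})
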