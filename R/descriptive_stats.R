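# Survey-weighted percentage distributions by sex and age group, and
# chi-square tests of association (the shape of the published background
# and prevalence tables).

#' Survey-weighted category percentages
#'
#' `percent(c) = 100 * sum(w_i : x_i = c) / sum(w_i)`. With equal weights
#' this reduces to unweighted relative frequencies.
#'
#' @param values categorical vector.
#' @param weights positive weights, same length.
#' @return named numeric vector of percentages (sums to 100).
#' @export
weighted_percent <- function(values, weights) {
  if (length(values) == 0L) {
    stop_frailscreen("weighted_percent needs at least one value",
                     class = "frailscreen_descriptive_error")
  }
  if (length(values) != length(weights)) {
    stop_frailscreen("values and weights differ in length",
                     class = "frailscreen_descriptive_error")
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop_frailscreen("weights must be positive",
                     class = "frailscreen_descriptive_error")
  }
  tot <- tapply(weights, as.character(values), sum)
  stats::setNames(as.numeric(100 * tot / sum(weights)), names(tot))
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with `E = row total * column total / n`,
#' `df = (r - 1)(c - 1)`, p-value from the upper chi-square tail; no
#' continuity correction.
#'
#' @param tab matrix (or table) of unweighted counts, at least 2x2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_frailscreen("chi-square needs at least a 2x2 table",
                     class = "frailscreen_descriptive_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_frailscreen("chi-square table has a zero marginal row or column",
                     class = "frailscreen_descriptive_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Display-format a p-value
#'
#' Three decimals, with values below 0.001 shown as `"<0.001"`.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

crosstab_one <- function(values, age_group, weights, sex) {
  cats <- sort(unique(as.character(values)))
  rows <- list()
  for (ag in AGE_LEVELS) {
    idx <- age_group == ag
    if (!any(idx)) next
    pc <- weighted_percent(values[idx], weights[idx])
    for (ct in cats) {
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sex, category = ct, age_group = ag,
        n = sum(values[idx] == ct),
        wpct = unname(ifelse(ct %in% names(pc), pc[ct], 0)),
        stringsAsFactors = FALSE)
    }
  }
  pc_tot <- weighted_percent(values, weights)
  for (ct in cats) {
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, category = ct, age_group = "total",
      n = sum(values == ct),
      wpct = unname(ifelse(ct %in% names(pc_tot), pc_tot[ct], 0)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Weighted background-characteristics table
#'
#' One crosstab per covariate: per sex and age-group column, the
#' unweighted count `n` and survey-weighted percent `wpct` of each
#' category (columns sum to 100), plus a Pearson chi-square test of the
#' category x age-group association within sex on unweighted counts.
#'
#' @param cohort cohort `data.frame`.
#' @param covariates covariate column names; defaults to all eight.
#' @return list with `cells` (long `data.frame`: covariate, sex, category,
#'   age_group, n, wpct) and `tests` (covariate, sex, statistic, df,
#'   p_value, p_display).
#' @export
build_table1 <- function(cohort, covariates = COVARIATE_FIELDS) {
  if (!all(c("sex", "age_group", "weight") %in% names(cohort))) {
    stop_frailscreen("cohort lacks sex/age_group/weight columns",
                     class = "frailscreen_descriptive_error")
  }
  cells <- list(); tests <- list()
  for (cv in covariates) {
    for (sx in SEX_LEVELS) {
      sub <- cohort[cohort$sex == sx, , drop = FALSE]
      if (nrow(sub) == 0L) next
      cc <- crosstab_one(sub[[cv]], sub$age_group, sub$weight, sx)
      cc$covariate <- cv
      cells[[length(cells) + 1L]] <- cc
      tab <- table(sub[[cv]], factor(sub$age_group, levels = AGE_LEVELS))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
        ht <- chi_square_test(tab)
        tests[[length(tests) + 1L]] <- data.frame(
          covariate = cv, sex = sx, statistic = ht$statistic, df = ht$df,
          p_value = ht$p_value, p_display = format_p(ht$p_value),
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  cells <- cells[, c("covariate", "sex", "category", "age_group", "n", "wpct")]
  rownames(cells) <- NULL
  list(cells = cells,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Weighted component-prevalence table
#'
#' For each frailty component and for the composite frail label: per sex
#' and age group (plus a total column), the unweighted count of flagged
#' participants and the survey-weighted percent flagged among the scored
#' (complete-case) participants.
#'
#' @param scores a `frailty_scores` object or its flags `data.frame`
#'   (needs `sex`, `age_group`, `weight`, the five components and
#'   `frail`).
#' @return long `data.frame`: component, sex, age_group, n_flagged, wpct.
#' @export
build_table2 <- function(scores) {
  flags <- if (inherits(scores, "frailty_scores")) scores$flags else scores
  comps <- c(COMPONENTS, "frail")
  labels <- c(COMPONENT_LABELS, frail = "Frailty combined")
  rows <- list()
  for (k in comps) {
    for (sx in SEX_LEVELS) {
      sub <- flags[flags$sex == sx, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (ag in c(AGE_LEVELS, "total")) {
        idx <- if (ag == "total") rep(TRUE, nrow(sub)) else sub$age_group == ag
        if (!any(idx)) next
        rows[[length(rows) + 1L]] <- data.frame(
          component = unname(labels[k]), sex = sx, age_group = ag,
          n_flagged = sum(sub[[k]][idx]),
          wpct = 100 * sum(sub$weight[idx] * sub[[k]][idx]) /
            sum(sub$weight[idx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
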