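# Diagnostic accuracy of single and dual deficits as screening markers for
# the composite frail label: 2x2 tables, the five accuracy statistics with
# Wilson continuity-corrected intervals, and marker ranking.

#' Define a screening marker
#'
#' A marker is one component, or a pair of components combined in parallel
#' (OR: positive when either deficit is present) or in series (AND:
#' positive only when both are).
#'
#' @param components character vector of 1 or 2 component letters among
#'   `E, G, W, L, P`.
#' @param rule `"single"` for one component; `"parallel_or"` (default for
#'   pairs) or `"serial_and"` for two.
#' @param name optional display name; defaults to the component labels
#'   joined with "and".
#' @return an object of class `marker_definition`.
#' @export
marker_definition <- function(components,
                              rule = if (length(components) == 1L) "single"
                                     else "parallel_or",
                              name = NULL) {
  components <- unique(as.character(components))
  bad <- setdiff(components, COMPONENTS)
  if (length(bad)) {
    stop_frailscreen("unknown component letter '%s'", bad[1L],
                     class = "frailscreen_marker_error")
  }
  rule <- match.arg(rule, c("single", "parallel_or", "serial_and"))
  if (rule == "single" && length(components) != 1L) {
    stop_frailscreen("single markers need exactly one component",
                     class = "frailscreen_marker_error")
  }
  if (rule != "single" && length(components) != 2L) {
    stop_frailscreen("pair rules need exactly two components",
                     class = "frailscreen_marker_error")
  }
  if (is.null(name)) {
    labs <- COMPONENT_LABELS[components]
    name <- if (length(labs) == 1L) unname(labs) else
      paste(labs[1L], "and", tolower(labs[2L]))
  }
  structure(list(name = name, components = components, rule = rule),
            class = "marker_definition")
}

#' All single and pair markers
#'
#' The five single-component markers plus the ten unordered component
#' pairs under `pair_rule`.
#'
#' @param pair_rule `"parallel_or"` (default) or `"serial_and"`.
#' @return list of [marker_definition()] objects in deterministic order
#'   (singles first, then pairs, each in component order E,G,W,L,P).
#' @export
all_markers <- function(pair_rule = "parallel_or") {
  singles <- lapply(COMPONENTS, marker_definition)
  pairs <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    pairs[[length(pairs) + 1L]] <-
      marker_definition(c(COMPONENTS[i], COMPONENTS[j]), rule = pair_rule)
  }
  c(singles, pairs)
}

#' Apply a marker to component flags
#'
#' @param flags `data.frame` with 0/1 columns for the marker's components
#'   (e.g. the `flags` element of [score_and_classify()]).
#' @param marker a [marker_definition()].
#' @return integer 0/1 positivity vector.
#' @export
apply_marker <- function(flags, marker) {
  miss <- setdiff(marker$components, names(flags))
  if (length(miss)) {
    stop_frailscreen("flags lack component column(s) %s",
                     paste(miss, collapse = ", "),
                     class = "frailscreen_marker_error")
  }
  cols <- lapply(marker$components, function(k) flags[[k]])
  switch(marker$rule,
    single = as.integer(cols[[1L]]),
    parallel_or = as.integer(cols[[1L]] | cols[[2L]]),
    serial_and = as.integer(cols[[1L]] & cols[[2L]])
  )
}

#' Build a 2x2 contingency table
#'
#' Cross-classifies marker positivity against the frail label:
#' TP = positive and frail, FP = positive and non-frail, FN = negative and
#' frail, TN = negative and non-frail. With `weights`, cells are weight
#' sums instead of counts.
#'
#' @param positive 0/1 marker positivity vector.
#' @param frail 0/1 reference frail labels, same length.
#' @param weights optional positive weights.
#' @return an object of class `contingency_2x2` with elements
#'   `TP, FP, FN, TN, n`.
#' @export
build_contingency <- function(positive, frail, weights = NULL) {
  if (length(positive) != length(frail)) {
    stop_frailscreen("positivity and frail vectors differ in length (%d vs %d)",
                     length(positive), length(frail),
                     class = "frailscreen_marker_error")
  }
  if (anyNA(positive) || anyNA(frail)) {
    stop_frailscreen("2x2 inputs must be complete-case (no missing values)",
                     class = "frailscreen_marker_error")
  }
  w <- weights %||% rep(1, length(positive))
  if (length(w) != length(positive) || any(w <= 0)) {
    stop_frailscreen("weights must be positive and match the vector length",
                     class = "frailscreen_marker_error")
  }
  positive <- as.logical(positive); frail <- as.logical(frail)
  tab <- list(
    TP = sum(w[positive & frail]),
    FP = sum(w[positive & !frail]),
    FN = sum(w[!positive & frail]),
    TN = sum(w[!positive & !frail])
  )
  tab$n <- tab$TP + tab$FP + tab$FN + tab$TN
  if (tab$n <= 0) {
    stop_frailscreen("empty 2x2 table", class = "frailscreen_marker_error")
  }
  structure(tab, class = "contingency_2x2")
}

#' Wilson score interval with continuity correction
#'
#' Newcombe's closed-form continuity-corrected Wilson (score) interval for
#' a binomial proportion. By the boundary rules, the lower limit is 0 when
#' no successes are observed and the upper limit is 1 when all trials
#' succeed; limits are clamped to `[0, 1]`.
#'
#' @param successes number of successes (0..n); may be non-integral when
#'   cells are survey-weight sums.
#' @param n number of trials (> 0).
#' @param conf confidence level in (0, 1); default 0.95
#'   (z = 1.959964).
#' @return numeric vector `c(lower, upper)`; vectorised over `successes`
#'   and `n` (then a 2-column matrix).
#' @examples
#' wilson_cc(81, 263)
#' @export
wilson_cc <- function(successes, n, conf = 0.95) {
  if (any(n <= 0)) {
    stop_frailscreen("n must be positive", class = "frailscreen_ci_error")
  }
  if (any(successes < 0) || any(successes > n)) {
    stop_frailscreen("successes must lie in [0, n]",
                     class = "frailscreen_ci_error")
  }
  if (conf <= 0 || conf >= 1) {
    stop_frailscreen("conf must lie in (0, 1)", class = "frailscreen_ci_error")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  lo <- (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  lo <- ifelse(p == 0, 0, pmax(0, lo))
  hi <- ifelse(p == 1, 1, pmin(1, hi))
  out <- cbind(lower = lo, upper = hi)
  if (nrow(out) == 1L) out[1L, ] else out
}

metric_with_ci <- function(num, den, conf) {
  if (den <= 0) return(c(NA_real_, NA_real_, NA_real_))
  ci <- wilson_cc(num, den, conf)
  c(num / den, ci[[1L]], ci[[2L]])
}

#' Accuracy metrics from a 2x2 table
#'
#' Standard epidemiologic definitions: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), prevalence (TP+FN)/n. Each
#' metric carries a Wilson continuity-corrected interval on its own
#' natural denominator. A metric whose denominator is zero is undefined:
#' reported as `NA` and named in the `undefined` attribute, never coerced
#' to 0 or 1.
#'
#' @param tab a [build_contingency()] table.
#' @param conf confidence level; default 0.95.
#' @return one-row `data.frame` with columns `sensitivity, sens_lo,
#'   sens_hi, specificity, spec_lo, spec_hi, ppv, ppv_lo, ppv_hi, npv,
#'   npv_lo, npv_hi, prevalence, prev_lo, prev_hi, n` and attribute
#'   `undefined` (character vector of undefined metrics).
#' @export
metrics_from_table <- function(tab, conf = 0.95) {
  if (!inherits(tab, "contingency_2x2")) {
    stop_frailscreen("tab must come from build_contingency()",
                     class = "frailscreen_marker_error")
  }
  vals <- c(
    metric_with_ci(tab$TP, tab$TP + tab$FN, conf),
    metric_with_ci(tab$TN, tab$TN + tab$FP, conf),
    metric_with_ci(tab$TP, tab$TP + tab$FP, conf),
    metric_with_ci(tab$TN, tab$TN + tab$FN, conf),
    metric_with_ci(tab$TP + tab$FN, tab$n, conf)
  )
  out <- as.data.frame(as.list(vals))
  names(out) <- c("sensitivity", "sens_lo", "sens_hi",
                  "specificity", "spec_lo", "spec_hi",
                  "ppv", "ppv_lo", "ppv_hi",
                  "npv", "npv_lo", "npv_hi",
                  "prevalence", "prev_lo", "prev_hi")
  out$n <- tab$n
  undef <- c("sensitivity", "specificity", "ppv", "npv")[
    is.na(c(out$sensitivity, out$specificity, out$ppv, out$npv))]
  attr(out, "undefined") <- undef
  out
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' The Bayes identity `ppv = sens * prev / (sens * prev +
#' (1 - spec) * (1 - prev))`. Agrees with [metrics_from_table()] on any
#' 2x2 table to machine precision; applied to independently rounded table
#' entries it quantifies their internal consistency.
#'
#' @param sens,spec,prev proportions in `[0, 1]` (vectorised).
#' @return PPV as a proportion; `NA` where the denominator is zero.
#' @export
ppv_from_bayes <- function(sens, spec, prev) {
  den <- sens * prev + (1 - spec) * (1 - prev)
  ifelse(den <= 0, NA_real_, sens * prev / den)
}

#' Negative predictive value from sensitivity, specificity and prevalence
#'
#' The Bayes identity `npv = spec * (1 - prev) / (spec * (1 - prev) +
#' (1 - sens) * prev)`.
#'
#' @inheritParams ppv_from_bayes
#' @return NPV as a proportion; `NA` where the denominator is zero.
#' @export
npv_from_bayes <- function(sens, spec, prev) {
  den <- spec * (1 - prev) + (1 - sens) * prev
  ifelse(den <= 0, NA_real_, spec * (1 - prev) / den)
}

#' Evaluate all single and dual markers
#'
#' Screens every component and every component pair against the composite
#' frail label, per sex stratum: 5 single markers + 10 pairs per sex (30
#' rows for two sexes). Output order is deterministic (sex, then singles
#' before pairs in component order).
#'
#' @param scores a `frailty_scores` object or a flags `data.frame` with
#'   the component columns, `frail`, and (if `by_sex`) `sex`.
#' @param conf confidence level for the Wilson intervals.
#' @param by_sex evaluate within each sex stratum (default) or pooled.
#' @param pair_rule combination rule for pairs, `"parallel_or"` (default)
#'   or `"serial_and"`.
#' @param weighted use survey-weight sums instead of counts in the 2x2
#'   cells (requires a `weight` column).
#' @return `data.frame` with columns `sex, marker, rule, components`, the
#'   fifteen metric/CI columns of [metrics_from_table()], and `n`.
#' @export
evaluate_all_markers <- function(scores, conf = 0.95, by_sex = TRUE,
                                 pair_rule = "parallel_or",
                                 weighted = FALSE) {
  flags <- if (inherits(scores, "frailty_scores")) scores$flags else scores
  strata <- if (by_sex) SEX_LEVELS else "all"
  markers <- all_markers(pair_rule)
  out <- list()
  for (sx in strata) {
    sub <- if (by_sex) flags[flags$sex == sx, , drop = FALSE] else flags
    if (nrow(sub) == 0L) {
      stop_frailscreen("empty sex stratum '%s'", sx,
                       class = "frailscreen_marker_error")
    }
    w <- if (weighted) sub$weight else NULL
    for (mk in markers) {
      tab <- build_contingency(apply_marker(sub, mk), sub$frail, w)
      m <- metrics_from_table(tab, conf)
      out[[length(out) + 1L]] <- cbind(
        data.frame(sex = sx, marker = mk$name, rule = mk$rule,
                   components = paste(mk$components, collapse = "+"),
                   stringsAsFactors = FALSE),
        m)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank components by a screening criterion
#'
#' Orders the five components by descending marginal prevalence (the share
#' of participants carrying the deficit) or by descending sensitivity
#' against the frail label. Ties are broken alphabetically by component
#' letter and reported via the `ties` attribute.
#'
#' @param flags flags `data.frame` with the five component columns (and
#'   `frail` for the sensitivity criterion).
#' @param criterion `"prevalence"` (default) or `"sensitivity"`.
#' @return named numeric vector of criterion values, ordered; attribute
#'   `ties` lists tied groups (empty if none).
#' @export
rank_components <- function(flags, criterion = c("prevalence", "sensitivity")) {
  criterion <- match.arg(criterion)
  vals <- vapply(COMPONENTS, function(k) {
    if (criterion == "prevalence") {
      mean(flags[[k]])
    } else {
      frail <- flags$frail
      if (sum(frail) == 0) NA_real_ else mean(flags[[k]][frail == 1])
    }
  }, numeric(1))
  ord <- order(-vals, names(vals))
  out <- vals[ord]
  dup <- unique(out[duplicated(out)])
  ties <- lapply(dup, function(v) names(out)[out == v])
  attr(out, "ties") <- ties
  out
}

#' Format an accuracy table for reporting
#'
#' Renders proportions as percentages with two decimals and the interval
#' in parentheses, mirroring the published table layout.
#'
#' @param table3 output of [evaluate_all_markers()].
#' @return `data.frame` of formatted strings.
#' @export
format_accuracy_table <- function(table3) {
  pct <- function(p, lo, hi) {
    ifelse(is.na(p), "undefined",
           sprintf("%.2f (%.2f,%.2f)", 100 * p, 100 * lo, 100 * hi))
  }
  data.frame(
    sex = table3$sex, marker = table3$marker, rule = table3$rule,
    sensitivity = pct(table3$sensitivity, table3$sens_lo, table3$sens_hi),
    specificity = pct(table3$specificity, table3$spec_lo, table3$spec_hi),
    ppv = pct(table3$ppv, table3$ppv_lo, table3$ppv_hi),
    npv = pct(table3$npv, table3$npv_lo, table3$npv_hi),
    prevalence = pct(table3$prevalence, table3$prev_lo, table3$prev_hi),
    n = table3$n, stringsAsFactors = FALSE
  )
}
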