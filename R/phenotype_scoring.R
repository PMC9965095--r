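# Phenotype scoring: raw measures -> five binary deficits -> 0-5 score ->
# frail / non-frail label.

#' Scoring configuration
#'
#' @param frail_threshold minimum number of deficits (of 5) for the frail
#'   label; default 3.
#' @param quintile_proportion tail proportion flagged for the measured
#'   components. Either a single proportion in (0,1) (default 0.20, the
#'   bottom quintile), or a list with elements `grip` and/or `walk`, each a
#'   single proportion or a named vector `c(male=, female=)`. Per-sex values
#'   support reproducing published marginal prevalences whose cutoffs were
#'   derived outside the analysis sample.
#' @param grip_strata `"sex_bmi_quartile"` (default; sex crossed with
#'   within-sex BMI quartiles, the original phenotype operationalisation) or
#'   `"sex_bmi_median"`.
#' @param walk_strata fixed at `"sex_height_median"`.
#' @param walk_direction `"slowest_flagged"` (default; the slowest
#'   `quintile_proportion` of walkers are flagged, matching the construct)
#'   or `"fastest_flagged"` (the literal bottom quintile of time values;
#'   non-standard, retained for sensitivity analyses).
#' @param quantile_weighting `"unweighted"` (default) or `"survey_weighted"`
#'   cutoff quantiles.
#' @param tie_rule `"flag_at_or_below"` (default: values exactly at the
#'   threshold are flagged, guaranteeing at-least-quintile coverage) or
#'   `"flag_strictly_below"`.
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(frail_threshold = 3L,
                           quintile_proportion = 0.20,
                           grip_strata = c("sex_bmi_quartile", "sex_bmi_median"),
                           walk_strata = "sex_height_median",
                           walk_direction = c("slowest_flagged", "fastest_flagged"),
                           quantile_weighting = c("unweighted", "survey_weighted"),
                           tie_rule = c("flag_at_or_below", "flag_strictly_below")) {
  if (length(frail_threshold) != 1L || is.na(frail_threshold) ||
      frail_threshold < 1 || frail_threshold > 5 ||
      frail_threshold != floor(frail_threshold)) {
    stop_frailscreen("frail_threshold must be an integer in 1..5",
                     class = "frailscreen_config_error")
  }
  qp <- quintile_proportion
  if (is.numeric(qp) && length(qp) == 1L) {
    qp <- list(grip = qp, walk = qp)
  }
  if (!is.list(qp) || !all(names(qp) %in% c("grip", "walk"))) {
    stop_frailscreen(
      "quintile_proportion must be a single proportion or a list over grip/walk",
      class = "frailscreen_config_error")
  }
  qp$grip <- qp$grip %||% 0.20
  qp$walk <- qp$walk %||% 0.20
  for (m in c("grip", "walk")) {
    v <- qp[[m]]
    if (anyNA(v) || any(v <= 0) || any(v >= 1)) {
      stop_frailscreen("quintile_proportion$%s must lie in (0, 1)", m,
                       class = "frailscreen_config_error")
    }
    if (length(v) > 1L && !all(SEX_LEVELS %in% names(v))) {
      stop_frailscreen("per-sex quintile_proportion$%s must name male and female",
                       m, class = "frailscreen_config_error")
    }
  }
  structure(
    list(
      frail_threshold = as.integer(frail_threshold),
      quintile_proportion = qp,
      grip_strata = match.arg(grip_strata),
      walk_strata = match.arg(walk_strata),
      walk_direction = match.arg(walk_direction),
      quantile_weighting = match.arg(quantile_weighting),
      tie_rule = match.arg(tie_rule)
    ),
    class = "scoring_config"
  )
}

#' Scoring configuration matched to a generator's marginal targets
#'
#' Returns a [scoring_config()] whose grip and walk tail proportions equal,
#' per sex, the generator's marginal prevalence targets for those
#' components. Scoring a generated cohort with this configuration
#' reproduces the configured (published) component marginals, emulating an
#' analysis whose dichotomisation cutoffs were fixed outside the sample.
#'
#' @param gen_config a [cohort_config()].
#' @param ... passed on to [scoring_config()].
#' @return a `scoring_config`.
#' @export
target_scoring_config <- function(gen_config, ...) {
  tg <- gen_config$target_component_prevalence
  scoring_config(
    quintile_proportion = list(
      grip = c(male = tg$male[["G"]], female = tg$female[["G"]]),
      walk = c(male = tg$male[["W"]], female = tg$female[["W"]])
    ),
    ...
  )
}

resolve_proportion <- function(config, measure, sex) {
  v <- config$quintile_proportion[[measure]]
  if (length(v) == 1L) unname(v) else unname(v[[sex]])
}

#' Dichotomise the exhaustion response
#'
#' Flags participants reporting tiredness/low energy "often (3-4 days)" or
#' "most (5-7 days)" in the last week on the CES-D item; the two lower
#' frequency categories are unflagged. Missing responses propagate.
#'
#' @param response character/factor vector over the four CES-D frequency
#'   categories, or `NA`.
#' @return integer 0/1 vector with `NA` for missing input.
#' @export
flag_exhaustion <- function(response) {
  response <- as.character(response)
  known <- response %in% EXHAUSTION_LEVELS
  if (any(!known & !is.na(response))) {
    stop_frailscreen("unknown exhaustion category '%s'",
                     response[!known & !is.na(response)][1L],
                     class = "frailscreen_coding_error")
  }
  ifelse(is.na(response), NA_integer_,
         as.integer(response %in% EXHAUSTION_LEVELS[3:4]))
}

#' Dichotomise the weight-loss response
#'
#' Flags participants who report having lost weight in the last 12 months
#' because there was not enough food. Missing responses propagate.
#'
#' @param response "yes"/"no" vector or `NA`.
#' @return integer 0/1 vector with `NA` for missing input.
#' @export
flag_weight_loss <- function(response) {
  response <- as.character(response)
  known <- response %in% WEIGHT_LOSS_LEVELS
  if (any(!known & !is.na(response))) {
    stop_frailscreen("unknown weight-loss category '%s'",
                     response[!known & !is.na(response)][1L],
                     class = "frailscreen_coding_error")
  }
  ifelse(is.na(response), NA_integer_, as.integer(response == "yes"))
}

#' Dichotomise the physical-activity frequency
#'
#' Flags participants reporting sports or vigorous activity 1-3 times a
#' month or hardly ever/never; weekly-or-better frequencies are unflagged.
#' Missing responses propagate.
#'
#' @param frequency character/factor vector over the five frequency
#'   categories, or `NA`.
#' @return integer 0/1 vector with `NA` for missing input.
#' @export
flag_low_activity <- function(frequency) {
  frequency <- as.character(frequency)
  known <- frequency %in% ACTIVITY_LEVELS
  if (any(!known & !is.na(frequency))) {
    stop_frailscreen("unknown activity category '%s'",
                     frequency[!known & !is.na(frequency)][1L],
                     class = "frailscreen_coding_error")
  }
  ifelse(is.na(frequency), NA_integer_,
         as.integer(frequency %in% ACTIVITY_LEVELS[4:5]))
}

#' Mean of two measurement trials
#'
#' Arithmetic mean of the trials that are present: both -> their mean, one
#' -> that trial (maximising complete cases), neither -> `NA`.
#'
#' @param t1,t2 numeric vectors (may contain `NA`).
#' @return numeric vector of per-row means.
#' @export
mean_of_trials <- function(t1, t2) {
  out <- rowMeans(cbind(t1, t2), na.rm = TRUE)
  out[is.na(t1) & is.na(t2)] <- NA_real_
  unname(out)
}

grip_stratum_breaks <- function(bmi, config, w = NULL) {
  probs <- if (config$grip_strata == "sex_bmi_quartile") c(.25, .5, .75) else 0.5
  vapply(probs, function(p) lower_quantile(bmi, p, w), numeric(1))
}

grip_stratum_labels <- function(config) {
  if (config$grip_strata == "sex_bmi_quartile")
    paste0("BMI Q", 1:4)
  else c("BMI <= median", "BMI > median")
}

assign_stratum <- function(x, breaks, labels) {
  labels[findInterval(x, breaks, left.open = TRUE) + 1L]
}

#' Derive stratified cutoffs for the measured components
#'
#' Computes, within each stratum, the threshold that flags the configured
#' tail of the averaged measure: for grip strength the low tail (the
#' `quintile_proportion` quantile, lower-value convention) within sex x BMI
#' strata; for walk time the slow tail (the `1 - quintile_proportion`
#' quantile) within sex x height-median strata under the default
#' `slowest_flagged` direction. Quantiles are unweighted unless
#' `quantile_weighting = "survey_weighted"`.
#'
#' Rows lacking the relevant measure or stratifier are ignored for that
#' measure. Only realised strata appear; BMI quartile breaks and height
#' medians are attached as the `"strata_breaks"` attribute so externally
#' supplied cutoffs can be applied to new rows.
#'
#' @param cohort cohort `data.frame`.
#' @param config a [scoring_config()].
#' @return a `data.frame` (class `cutoff_table`) with columns
#'   `measure, sex, stratum, threshold, n`.
#' @export
derive_cutoffs <- function(cohort, config = scoring_config()) {
  grip <- mean_of_trials(cohort$grip_trial1, cohort$grip_trial2)
  walk <- mean_of_trials(cohort$walk_trial1, cohort$walk_trial2)
  use_w <- config$quantile_weighting == "survey_weighted"
  rows <- list()
  breaks <- list()
  for (sx in SEX_LEVELS) {
    gi <- which(cohort$sex == sx & !is.na(grip) & !is.na(cohort$bmi))
    if (length(gi)) {
      wts <- if (use_w) cohort$weight[gi] else NULL
      gb <- grip_stratum_breaks(cohort$bmi[gi], config, wts)
      breaks[[paste0("grip_", sx)]] <- gb
      labs <- grip_stratum_labels(config)
      strat <- assign_stratum(cohort$bmi[gi], gb, labs)
      p <- resolve_proportion(config, "grip", sx)
      for (s in labs[labs %in% strat]) {
        idx <- gi[strat == s]
        rows[[length(rows) + 1L]] <- data.frame(
          measure = "grip", sex = sx, stratum = s,
          threshold = lower_quantile(grip[idx], p,
                                     if (use_w) cohort$weight[idx] else NULL),
          n = length(idx), stringsAsFactors = FALSE)
      }
    }
    wi <- which(cohort$sex == sx & !is.na(walk) & !is.na(cohort$height))
    if (length(wi)) {
      wts <- if (use_w) cohort$weight[wi] else NULL
      med <- lower_quantile(cohort$height[wi], 0.5, wts)
      breaks[[paste0("walk_", sx)]] <- med
      labs <- c("height <= median", "height > median")
      strat <- assign_stratum(cohort$height[wi], med, labs)
      p <- resolve_proportion(config, "walk", sx)
      qp <- if (config$walk_direction == "slowest_flagged") 1 - p else p
      for (s in labs[labs %in% strat]) {
        idx <- wi[strat == s]
        rows[[length(rows) + 1L]] <- data.frame(
          measure = "walk", sex = sx, stratum = s,
          threshold = lower_quantile(walk[idx], qp,
                                     if (use_w) cohort$weight[idx] else NULL),
          n = length(idx), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    stop_frailscreen("stratification error: no stratum has usable values",
                     class = "frailscreen_stratum_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "strata_breaks") <- breaks
  attr(out, "config") <- config
  class(out) <- c("cutoff_table", "data.frame")
  out
}

lookup_threshold <- function(cutoffs, measure, sex, stratum) {
  hit <- cutoffs$measure == measure & cutoffs$sex == sex &
    cutoffs$stratum == stratum
  if (!any(hit)) {
    stop_frailscreen("stratification error: no cutoff for %s / %s / %s",
                     measure, sex, stratum,
                     class = "frailscreen_stratum_error")
  }
  cutoffs$threshold[which(hit)[1L]]
}

#' Flag weak grip strength
#'
#' Flags rows whose averaged grip strength falls at or below (default tie
#' rule) the threshold of their sex x BMI stratum.
#'
#' @param cohort cohort `data.frame` (needs sex, bmi and the grip trials).
#' @param cutoffs a [derive_cutoffs()] table.
#' @param config the [scoring_config()] used to derive `cutoffs`.
#' @return integer 0/1 vector, `NA` where the averaged grip or BMI is
#'   missing.
#' @export
flag_weak_grip <- function(cohort, cutoffs, config = scoring_config()) {
  grip <- mean_of_trials(cohort$grip_trial1, cohort$grip_trial2)
  out <- rep(NA_integer_, nrow(cohort))
  breaks <- attr(cutoffs, "strata_breaks")
  labs <- grip_stratum_labels(config)
  for (sx in SEX_LEVELS) {
    idx <- which(cohort$sex == sx & !is.na(grip) & !is.na(cohort$bmi))
    if (!length(idx)) next
    gb <- breaks[[paste0("grip_", sx)]]
    if (is.null(gb)) {
      stop_frailscreen("stratification error: cutoffs carry no grip strata for %s",
                       sx, class = "frailscreen_stratum_error")
    }
    strat <- assign_stratum(cohort$bmi[idx], gb, labs)
    thr <- vapply(strat, function(s) lookup_threshold(cutoffs, "grip", sx, s),
                  numeric(1))
    out[idx] <- if (config$tie_rule == "flag_at_or_below")
      as.integer(grip[idx] <= thr) else as.integer(grip[idx] < thr)
  }
  out
}

#' Flag slow walking time
#'
#' Under the default `slowest_flagged` direction, flags rows whose averaged
#' 4-m walk time is at or above (default tie rule) the threshold of their
#' sex x height-median stratum; under `fastest_flagged` the comparison is
#' reversed.
#'
#' @inheritParams flag_weak_grip
#' @return integer 0/1 vector, `NA` where the averaged walk time or height
#'   is missing.
#' @export
flag_slow_walk <- function(cohort, cutoffs, config = scoring_config()) {
  walk <- mean_of_trials(cohort$walk_trial1, cohort$walk_trial2)
  out <- rep(NA_integer_, nrow(cohort))
  breaks <- attr(cutoffs, "strata_breaks")
  labs <- c("height <= median", "height > median")
  for (sx in SEX_LEVELS) {
    idx <- which(cohort$sex == sx & !is.na(walk) & !is.na(cohort$height))
    if (!length(idx)) next
    med <- breaks[[paste0("walk_", sx)]]
    if (is.null(med)) {
      stop_frailscreen("stratification error: cutoffs carry no walk strata for %s",
                       sx, class = "frailscreen_stratum_error")
    }
    strat <- assign_stratum(cohort$height[idx], med, labs)
    thr <- vapply(strat, function(s) lookup_threshold(cutoffs, "walk", sx, s),
                  numeric(1))
    slow <- config$walk_direction == "slowest_flagged"
    at_or <- config$tie_rule == "flag_at_or_below"
    out[idx] <- if (slow) {
      if (at_or) as.integer(walk[idx] >= thr) else as.integer(walk[idx] > thr)
    } else {
      if (at_or) as.integer(walk[idx] <= thr) else as.integer(walk[idx] < thr)
    }
  }
  out
}

#' Score the phenotype and classify frailty
#'
#' Builds the five binary deficits, drops every row with any missing
#' component (complete-case rule), derives cutoffs on the retained rows
#' (unless supplied), sums the deficits into the 0-5 score `S`, and labels
#' a participant frail when `S >= frail_threshold`.
#'
#' @param cohort cohort `data.frame`.
#' @param config a [scoring_config()].
#' @param cutoffs optional externally derived [derive_cutoffs()] table; by
#'   default cutoffs are derived on the complete cases of `cohort` itself.
#' @return an object of class `frailty_scores`: a list with `flags` (a
#'   `data.frame` with columns `id, sex, age_group, weight, E, G, W, L, P,
#'   S, frail`), `cutoffs`, `n_input`, `n_dropped` and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_male = 300, n_female = 300))
#' scores <- score_and_classify(cohort)
#' table(scores$flags$frail)
#' @export
score_and_classify <- function(cohort, config = scoring_config(),
                               cutoffs = NULL) {
  n_input <- nrow(cohort)
  E <- flag_exhaustion(cohort$exhaustion_response)
  L <- flag_weight_loss(cohort$weight_loss_response)
  P <- flag_low_activity(cohort$activity_frequency)
  grip <- mean_of_trials(cohort$grip_trial1, cohort$grip_trial2)
  walk <- mean_of_trials(cohort$walk_trial1, cohort$walk_trial2)
  complete <- !is.na(E) & !is.na(L) & !is.na(P) &
    !is.na(grip) & !is.na(walk) & !is.na(cohort$bmi) & !is.na(cohort$height) &
    cohort$sex %in% SEX_LEVELS
  kept <- cohort[complete, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop_frailscreen("no complete cases after dropping missing components",
                     class = "frailscreen_scoring_error")
  }
  if (is.null(cutoffs)) cutoffs <- derive_cutoffs(kept, config)
  G <- flag_weak_grip(kept, cutoffs, config)
  W <- flag_slow_walk(kept, cutoffs, config)
  flags <- data.frame(
    id = kept$id, sex = kept$sex, age_group = kept$age_group,
    weight = kept$weight,
    E = E[complete], G = G, W = W, L = L[complete], P = P[complete],
    stringsAsFactors = FALSE
  )
  flags$S <- flags$E + flags$G + flags$W + flags$L + flags$P
  flags$frail <- as.integer(flags$S >= config$frail_threshold)
  rownames(flags) <- NULL
  structure(
    list(flags = flags, cutoffs = cutoffs,
         n_input = n_input, n_dropped = n_input - nrow(flags),
         config = config),
    class = "frailty_scores"
  )
}

#' @export
print.frailty_scores <- function(x, ...) {
  cat(sprintf(
    "frailty_scores: %d scored (%d of %d input rows dropped), %d frail (%.1f%%)\n",
    nrow(x$flags), x$n_dropped, x$n_input, sum(x$flags$frail),
    100 * mean(x$flags$frail)))
  invisible(x)
}

#' Write component flags to CSV
#'
#' @param scores a `frailty_scores` object or its `flags` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(scores, path) {
  flags <- if (inherits(scores, "frailty_scores")) scores$flags else scores
  utils::write.csv(flags, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
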