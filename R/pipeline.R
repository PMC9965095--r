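# End-to-end orchestration: generate (or read) a cohort, score it,
# evaluate markers, build the descriptive tables, and record a manifest
# sufficient to reproduce the run.

#' Pipeline run configuration
#'
#' @param generator a [cohort_config()] (ignored when `input_path` points
#'   at an existing cohort CSV).
#' @param scoring a [scoring_config()], or `NULL` (default) to score with
#'   [target_scoring_config()] built from `generator`, so the default
#'   synthetic run mirrors the published marginal dichotomisation.
#' @param conf confidence level for Wilson intervals.
#' @param pair_rule pair combination rule for the marker sweep.
#' @param weighted_tables use survey-weight sums in the 2x2 cells.
#' @param missingness_rate optional missingness injected into the raw
#'   fields before scoring (exercises the complete-case drop).
#' @param input_path optional path to a real cohort CSV.
#' @param out_dir output directory (created if needed).
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = cohort_config(),
                       scoring = NULL,
                       conf = 0.95,
                       pair_rule = "parallel_or",
                       weighted_tables = FALSE,
                       missingness_rate = 0,
                       input_path = NULL,
                       out_dir = tempfile("frailscreen_run_")) {
  assert_proportion(missingness_rate, "missingness_rate")
  if (is.null(scoring)) scoring <- target_scoring_config(generator)
  structure(
    list(generator = generator, scoring = scoring, conf = conf,
         pair_rule = pair_rule, weighted_tables = weighted_tables,
         missingness_rate = missingness_rate, input_path = input_path,
         out_dir = out_dir),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_frailscreen("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e), class = "frailscreen_pipeline_error")
  })
}

config_fingerprint <- function(config) {
  dump <- tempfile(fileext = ".json")
  on.exit(unlink(dump))
  jsonlite::write_json(unclass_deep(config), dump, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(dump))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Run the full screening pipeline
#'
#' Stages: (1) generate the synthetic cohort (or read a real one) and
#' optionally inject missingness; (2) score the phenotype (complete-case
#' drop, cutoff derivation, 0-5 score, frail label); (3) evaluate all
#' single and dual markers; (4) build the weighted descriptive tables.
#' Every stage's output is written as CSV under `out_dir`, together with a
#' sensitivity/specificity bar figure and a JSON manifest recording the
#' seed, a configuration fingerprint, and row counts in and out of every
#' stage. Re-running with the same configuration reproduces byte-identical
#' machine outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    cutoffs = file.path(config$out_dir, "cutoffs.csv"),
    flags = file.path(config$out_dir, "flags.csv"),
    table1_cells = file.path(config$out_dir, "table1_cells.csv"),
    table1_tests = file.path(config$out_dir, "table1_tests.csv"),
    table2 = file.path(config$out_dir, "table2.csv"),
    table3 = file.path(config$out_dir, "table3.csv"),
    figure = file.path(config$out_dir, "fig_sens_spec.png"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  counts <- list()

  cohort <- stage("cohort", {
    x <- if (!is.null(config$input_path)) {
      read_cohort(config$input_path)
    } else {
      generate_cohort(config$generator)
    }
    if (config$missingness_rate > 0) {
      x <- inject_missingness(x, config$missingness_rate,
                              seed = config$generator$seed + 1L)
    }
    x
  })
  counts$cohort_rows <- nrow(cohort)
  write_cohort(cohort, paths$cohort)

  scores <- stage("scoring", score_and_classify(cohort, config$scoring))
  counts$scored_rows <- nrow(scores$flags)
  counts$dropped_rows <- scores$n_dropped
  write_flags(scores, paths$flags)
  utils::write.csv(as.data.frame(scores$cutoffs), paths$cutoffs,
                   row.names = FALSE, quote = FALSE)

  table3 <- stage("evaluation", evaluate_all_markers(
    scores, conf = config$conf, pair_rule = config$pair_rule,
    weighted = config$weighted_tables))
  counts$table3_rows <- nrow(table3)
  utils::write.csv(table3, paths$table3, row.names = FALSE)
  stage("figure", plot_sens_spec(table3, paths$figure))

  t1 <- stage("descriptives", build_table1(cohort))
  utils::write.csv(t1$cells, paths$table1_cells, row.names = FALSE)
  if (!is.null(t1$tests)) {
    utils::write.csv(t1$tests, paths$table1_tests, row.names = FALSE)
  }
  t2 <- stage("descriptives", build_table2(scores))
  utils::write.csv(t2, paths$table2, row.names = FALSE)

  manifest <- list(
    package = "frailscreen",
    seed = config$generator$seed,
    config_md5 = config_fingerprint(config),
    synthetic = is.null(config$input_path),
    missingness_rate = config$missingness_rate,
    counts = counts,
    files = lapply(paths[names(paths) != "manifest"], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Check a marker table against the Bayes identities
#'
#' Recomputes every row's PPV and NPV from its sensitivity, specificity
#' and prevalence via [ppv_from_bayes()]/[npv_from_bayes()] and reports
#' the absolute discrepancies. On tables produced by
#' [evaluate_all_markers()] from exact counts the maximum discrepancy is
#' at machine precision; on tables re-entered at printed (2-decimal)
#' precision, discrepancies up to a few 1e-4 are expected on
#' well-conditioned rows.
#'
#' @param table3 a marker table `data.frame` (or path to its CSV) with
#'   columns `sensitivity, specificity, prevalence, ppv, npv`.
#' @param tol discrepancy above which a row is flagged; default `1e-8`.
#' @return list with `per_row` (`data.frame` of discrepancies and flags),
#'   `max_ppv_discrepancy`, `max_npv_discrepancy`, `n_flagged`.
#' @export
validate_against_bayes <- function(table3, tol = 1e-8) {
  if (is.character(table3)) {
    table3 <- utils::read.csv(table3, stringsAsFactors = FALSE)
  }
  need <- c("sensitivity", "specificity", "prevalence", "ppv", "npv")
  miss <- setdiff(need, names(table3))
  if (length(miss)) {
    stop_frailscreen("marker table lacks column(s) %s",
                     paste(miss, collapse = ", "),
                     class = "frailscreen_pipeline_error")
  }
  ppv_b <- ppv_from_bayes(table3$sensitivity, table3$specificity,
                          table3$prevalence)
  npv_b <- npv_from_bayes(table3$sensitivity, table3$specificity,
                          table3$prevalence)
  d_ppv <- abs(table3$ppv - ppv_b)
  d_npv <- abs(table3$npv - npv_b)
  per_row <- data.frame(
    row = seq_len(nrow(table3)),
    ppv_discrepancy = d_ppv, npv_discrepancy = d_npv,
    flagged = !is.na(d_ppv) & !is.na(d_npv) & (d_ppv > tol | d_npv > tol)
  )
  list(per_row = per_row,
       max_ppv_discrepancy = max(d_ppv, na.rm = TRUE),
       max_npv_discrepancy = max(d_npv, na.rm = TRUE),
       n_flagged = sum(per_row$flagged))
}

#' Sensitivity/specificity bar figure
#'
#' Grouped bar chart of sensitivity and specificity of the five single
#' components, one panel per sex.
#'
#' @param table3 output of [evaluate_all_markers()].
#' @param path optional PNG path; when given the figure is written there.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_sens_spec <- function(table3, path = NULL) {
  singles <- table3[table3$rule == "single", , drop = FALSE]
  if (!is.null(path)) {
    grDevices::png(path, width = 1400, height = 650, res = 120)
    on.exit(grDevices::dev.off())
  }
  sexes <- unique(singles$sex)
  graphics::par(mfrow = c(1, length(sexes)), mar = c(8, 4, 3, 1))
  for (sx in sexes) {
    sub <- singles[singles$sex == sx, , drop = FALSE]
    m <- rbind(sensitivity = 100 * sub$sensitivity,
               specificity = 100 * sub$specificity)
    colnames(m) <- sub$marker
    graphics::barplot(m, beside = TRUE, las = 2, ylim = c(0, 100),
                      col = c("grey25", "grey70"), ylab = "%",
                      main = sprintf("Screening accuracy (%s)", sx))
    graphics::legend("topright", legend = rownames(m),
                     fill = c("grey25", "grey70"), bty = "n", cex = 0.8)
  }
  invisible(path)
}
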