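# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

COMPONENTS <- c("E", "G", "W", "L", "P")

COMPONENT_LABELS <- c(
  E = "Exhaustion",
  G = "Grip strength",
  W = "Walk time",
  L = "Weight loss",
  P = "Physical activity"
)

SEX_LEVELS <- c("male", "female")
AGE_LEVELS <- c("60-69", "70-79", "80+")

EXHAUSTION_LEVELS <- c(
  "rarely (<1 day)", "some (1-2 days)", "often (3-4 days)", "most (5-7 days)"
)
WEIGHT_LOSS_LEVELS <- c("yes", "no")
ACTIVITY_LEVELS <- c(
  "every day", "more than once a week", "once a week",
  "1-3 times a month", "hardly ever or never"
)

# Raw fields a frailty component is built from (missingness injection targets).
FRAILTY_RAW_FIELDS <- c(
  "grip_trial1", "grip_trial2", "walk_trial1", "walk_trial2",
  "exhaustion_response", "weight_loss_response", "activity_frequency"
)

COVARIATE_FIELDS <- c(
  "residence", "marital", "education", "work",
  "smoking", "alcohol", "adl", "iadl"
)

COHORT_COLUMNS <- c(
  "id", "sex", "age_group", "weight", "bmi", "height",
  "grip_trial1", "grip_trial2", "walk_trial1", "walk_trial2",
  "exhaustion_response", "weight_loss_response", "activity_frequency",
  COVARIATE_FIELDS
)

stop_frailscreen <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "frailscreen_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_proportion <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_frailscreen("%s must be a proportion in [0, 1]", what,
                     class = "frailscreen_config_error")
  }
  invisible(x)
}

assert_sums_to_one <- function(p, what, tol = 1e-9) {
  if (abs(sum(p) - 1) > tol) {
    stop_frailscreen("proportions of %s must sum to 1 (got %.12f)", what, sum(p),
                     class = "frailscreen_config_error")
  }
  invisible(p)
}

#' Lower-value sample quantile
#'
#' The quantile convention used for all cutoff derivation: the smallest
#' observed value whose cumulative fraction reaches `p` (type-1 inverse
#' empirical CDF). Deterministic and exactly checkable against a
#' sort-and-index oracle on small inputs.
#'
#' @param x numeric values (no missing).
#' @param p probability in (0, 1).
#' @param w optional positive weights; when supplied the quantile is the
#'   smallest value whose cumulative weight fraction reaches `p`.
#' @return a single numeric value drawn from `x`.
#' @keywords internal
lower_quantile <- function(x, p, w = NULL) {
  if (length(x) == 0L) {
    stop_frailscreen("cannot take a quantile of zero values",
                     class = "frailscreen_stratum_error")
  }
  if (is.null(w)) {
    return(unname(stats::quantile(x, probs = p, type = 1, names = FALSE)))
  }
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= p - 1e-12)[1L]]
}

round_half_up <- function(x, digits = 2) {
  # Decimal rounding matching how the published tables print values
  # (ties away from zero), insulated from binary floating error.
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
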