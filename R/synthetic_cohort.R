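# Synthetic cohort generator: seeded, survey-shaped individual-level records
# with a single latent frailty liability driving all five deficits.

#' Default per-sex component prevalence targets
#'
#' Marginal prevalence (proportion) of each frailty deficit per sex, taken
#' from the published weighted totals of the source survey's prevalence
#' table. Components: E exhaustion, G weak grip, W slow walk, L weight
#' loss, P low physical activity.
#'
#' @return named list with `male` and `female` numeric vectors over
#'   `c("E","G","W","L","P")`.
#' @export
default_component_targets <- function() {
  list(
    male   = c(E = 0.3794, G = 0.7907, W = 0.1540, L = 0.0585, P = 0.6421),
    female = c(E = 0.3954, G = 0.6709, W = 0.2631, L = 0.0553, P = 0.8163)
  )
}

#' Default per-sex age-group mix
#'
#' Proportions of the 60-69 / 70-79 / 80+ age groups, back-calculated from
#' the survey's age-specific component counts and weighted prevalences.
#'
#' @return named list of numeric vectors over the three age groups.
#' @export
default_age_mix <- function() {
  list(
    male   = c(`60-69` = 0.590, `70-79` = 0.300, `80+` = 0.110),
    female = c(`60-69` = 0.615, `70-79` = 0.280, `80+` = 0.105)
  )
}

#' Default per-sex covariate category marginals
#'
#' Category proportions per covariate and sex, computed from the published
#' background-characteristics table's unweighted category counts
#' (normalised to sum exactly to one). Covariates are sampled independently
#' of age group and of the frailty liability.
#'
#' @return nested list: covariate -> sex -> named proportion vector.
#' @export
default_covariate_marginals <- function() {
  raw <- list(
    residence = list(
      levels = c("urban", "rural"),
      male = c(4892, 9993), female = c(5572, 10521)
    ),
    marital = list(
      levels = c("in wedlock", "not in wedlock"),
      male = c(12246, 2639), female = c(7513, 8580)
    ),
    education = list(
      levels = c("no education", "primary", "secondary", "higher and above"),
      male = c(5398, 4441, 3240, 1806), female = c(11230, 3012, 1291, 560)
    ),
    work = list(
      levels = c("never worked", "currently working", "not currently working",
                 "retired"),
      male = c(811, 6281, 5784, 1991), female = c(7940, 2951, 4846, 349)
    ),
    smoking = list(
      levels = c("no", "yes"),
      male = c(6549, 8327), female = c(12417, 3670)
    ),
    alcohol = list(
      levels = c("no", "yes"),
      male = c(10227, 4651), female = c(15414, 679)
    ),
    adl = list(
      levels = c("no", "yes"),
      male = c(12323, 2559), female = c(12319, 3772)
    ),
    iadl = list(
      levels = c("no", "yes"),
      male = c(9770, 5100), female = c(7729, 8333)
    )
  )
  lapply(raw, function(v) {
    list(
      male   = stats::setNames(v$male / sum(v$male), v$levels),
      female = stats::setNames(v$female / sum(v$female), v$levels)
    )
  })
}

#' Generator configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator.
#' A single person-level latent liability `Z ~ N(0,1) + age shift` drives
#' all five deficits; `liability_loading` sets how strongly each deficit's
#' underlying continuous scale correlates with `Z` (and hence with age and
#' with the other deficits). Loadings are deliberately weak by default:
#' they are calibrated so the composite frail prevalence implied by the
#' default marginals stays close to the published male composite total
#' (see the methods vignette for the calibration and its limits).
#'
#' @param n_male,n_female non-negative row counts per sex.
#' @param seed integer RNG seed; the generator is bit-reproducible given it.
#' @param target_component_prevalence list with `male`/`female` named
#'   vectors over `c("E","G","W","L","P")`; marginal deficit prevalences.
#' @param liability_loading named vector over the five components, each in
#'   `[0, 0.99]`: correlation of the component's latent scale with `Z`.
#' @param age_group_mix list with `male`/`female` proportion vectors over
#'   the three age groups (each sums to 1).
#' @param age_liability_shift numeric length 3, non-decreasing: additive
#'   shift of the latent liability for the 60-69 / 70-79 / 80+ groups.
#' @param covariate_marginals nested list covariate -> sex -> proportions.
#' @param weight_dispersion log-scale SD of the survey weights (log-normal
#'   with mean 1); `0` gives unit weights.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_male = 14885,
                          n_female = 16093,
                          seed = 1L,
                          target_component_prevalence = default_component_targets(),
                          liability_loading = c(E = 0.12, G = 0.15, W = 0.18,
                                                L = 0.08, P = 0.15),
                          age_group_mix = default_age_mix(),
                          age_liability_shift = c(0, 0.3, 0.6),
                          covariate_marginals = default_covariate_marginals(),
                          weight_dispersion = 0.5) {
  if (length(n_male) != 1L || length(n_female) != 1L ||
      is.na(n_male) || is.na(n_female) || n_male < 0 || n_female < 0 ||
      n_male != floor(n_male) || n_female != floor(n_female)) {
    stop_frailscreen("n_male and n_female must be single non-negative integers",
                     class = "frailscreen_config_error")
  }
  for (sx in SEX_LEVELS) {
    tg <- target_component_prevalence[[sx]]
    if (is.null(tg) || !all(COMPONENTS %in% names(tg))) {
      stop_frailscreen("target_component_prevalence$%s must name all of %s",
                       sx, paste(COMPONENTS, collapse = ","),
                       class = "frailscreen_config_error")
    }
    assert_proportion(tg, sprintf("target_component_prevalence$%s", sx))
    mix <- age_group_mix[[sx]]
    assert_proportion(mix, sprintf("age_group_mix$%s", sx))
    assert_sums_to_one(mix, sprintf("age_group_mix$%s", sx))
  }
  if (!all(COMPONENTS %in% names(liability_loading))) {
    stop_frailscreen("liability_loading must name all five components",
                     class = "frailscreen_config_error")
  }
  if (any(liability_loading < 0) || any(liability_loading > 0.99)) {
    stop_frailscreen("liability_loading values must lie in [0, 0.99]",
                     class = "frailscreen_config_error")
  }
  if (length(age_liability_shift) != 3L || is.unsorted(age_liability_shift)) {
    stop_frailscreen("age_liability_shift must be 3 non-decreasing values",
                     class = "frailscreen_config_error")
  }
  for (cv in names(covariate_marginals)) {
    for (sx in SEX_LEVELS) {
      p <- covariate_marginals[[cv]][[sx]]
      assert_proportion(p, sprintf("covariate_marginals$%s$%s", cv, sx))
      assert_sums_to_one(p, sprintf("covariate_marginals$%s$%s", cv, sx))
    }
  }
  if (weight_dispersion < 0) {
    stop_frailscreen("weight_dispersion must be >= 0",
                     class = "frailscreen_config_error")
  }
  structure(
    list(
      n_male = as.integer(n_male), n_female = as.integer(n_female),
      seed = as.integer(seed),
      target_component_prevalence = lapply(
        target_component_prevalence, function(x) x[COMPONENTS]),
      liability_loading = liability_loading[COMPONENTS],
      age_group_mix = age_group_mix,
      age_liability_shift = age_liability_shift,
      covariate_marginals = covariate_marginals,
      weight_dispersion = weight_dispersion
    ),
    class = "cohort_config"
  )
}

empty_cohort <- function() {
  df <- data.frame(
    id = character(0), sex = character(0), age_group = character(0),
    weight = numeric(0), bmi = numeric(0), height = numeric(0),
    grip_trial1 = numeric(0), grip_trial2 = numeric(0),
    walk_trial1 = numeric(0), walk_trial2 = numeric(0),
    exhaustion_response = character(0), weight_loss_response = character(0),
    activity_frequency = character(0),
    stringsAsFactors = FALSE
  )
  for (cv in COVARIATE_FIELDS) df[[cv]] <- character(0)
  df[, COHORT_COLUMNS]
}

# Assign ordinal categories by the within-sex rank of a latent scale,
# so that category marginals are exact up to rank granularity. `cuts` are
# cumulative proportions; higher latent rank falls into later categories.
categories_from_rank <- function(u, cuts, labels) {
  r <- (rank(u, ties.method = "first") - 0.5) / length(u)
  labels[findInterval(r, cuts, left.open = TRUE) + 1L]
}

generate_sex_block <- function(n, sex, config) {
  if (n == 0L) return(empty_cohort())
  mix <- config$age_group_mix[[sex]]
  rho <- config$liability_loading
  tg <- config$target_component_prevalence[[sex]]

  age <- sample(AGE_LEVELS, n, replace = TRUE, prob = mix[AGE_LEVELS])
  shift <- config$age_liability_shift[match(age, AGE_LEVELS)]
  z <- stats::rnorm(n) + shift
  latent <- function(comp) {
    rho[comp] * z + sqrt(1 - rho[comp]^2) * stats::rnorm(n)
  }

  bmi_mu <- if (sex == "male") 21.0 else 22.0
  bmi <- round_half_up(pmin(pmax(stats::rnorm(n, bmi_mu, 3.4), 12), 55), 2)
  ht_mu <- if (sex == "male") 164 else 151
  ht_sd <- if (sex == "male") 6.5 else 6.0
  height <- round_half_up(pmin(pmax(stats::rnorm(n, ht_mu, ht_sd), 125), 195), 1)

  # Grip (kg): lower with higher liability; two dynamometer trials.
  u_g <- latent("G")
  grip_mu <- if (sex == "male") 28 else 20
  grip_true <- grip_mu - 5.5 * u_g
  grip_trial <- function() {
    round_half_up(pmax(grip_true + stats::rnorm(n, 0, 1.0), 0.5), 1)
  }
  grip1 <- grip_trial(); grip2 <- grip_trial()

  # 4-m walk time (s): log-normal, slower with higher liability.
  u_w <- latent("W")
  log_walk <- log(5.0) + 0.30 * u_w
  walk_trial <- function() {
    round_half_up(
      pmin(pmax(exp(log_walk + stats::rnorm(n, 0, 0.06)), 1.05), 119), 2)
  }
  walk1 <- walk_trial(); walk2 <- walk_trial()

  # CES-D tiredness item: the top tg["E"] of the latent scale answers
  # often/most (the flagged categories), split 60/40; the rest rarely/some.
  pe <- tg[["E"]]
  exh <- categories_from_rank(
    latent("E"),
    cuts = c(0.7 * (1 - pe), 1 - pe, 1 - 0.4 * pe),
    labels = EXHAUSTION_LEVELS
  )

  # Food-insecurity weight loss: top tg["L"] answer yes.
  wl <- ifelse(
    (rank(latent("L"), ties.method = "first") - 0.5) / n > 1 - tg[["L"]],
    "yes", "no")

  # Activity frequency: the flagged tail (1-3/month or hardly ever) totals
  # tg["P"], split 35/65; active categories split 25/45/30.
  pp <- tg[["P"]]
  act <- categories_from_rank(
    latent("P"),
    cuts = c(0.25 * (1 - pp), 0.70 * (1 - pp), 1 - pp, 1 - 0.65 * pp),
    labels = ACTIVITY_LEVELS
  )

  d <- config$weight_dispersion
  wt <- if (d == 0) rep(1, n) else
    round_half_up(stats::rlnorm(n, meanlog = -d^2 / 2, sdlog = d), 6)

  out <- data.frame(
    id = NA_character_, sex = sex, age_group = age, weight = wt,
    bmi = bmi, height = height,
    grip_trial1 = grip1, grip_trial2 = grip2,
    walk_trial1 = walk1, walk_trial2 = walk2,
    exhaustion_response = exh, weight_loss_response = wl,
    activity_frequency = act, stringsAsFactors = FALSE
  )
  for (cv in COVARIATE_FIELDS) {
    p <- config$covariate_marginals[[cv]][[sex]]
    out[[cv]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  out[, COHORT_COLUMNS]
}

#' Generate a synthetic cohort
#'
#' Draws `n_male + n_female` individual records. Each person carries a
#' latent liability `Z ~ N(0,1)` shifted upward by age group; every deficit's
#' underlying continuous scale is `rho * Z + sqrt(1 - rho^2) * noise`, so
#' lower grip strength, slower walk time and worse questionnaire responses
#' all associate monotonically with `Z` and with each other. Dichotomising
#' any component at its within-sex marginal target quantile reproduces
#' `target_component_prevalence` up to rank granularity (exact for the
#' questionnaire items, Monte-Carlo-exact for the measured ones).
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with one row per participant and the full cohort
#'   schema (see [read_cohort()] for the column contract).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_male = 200, n_female = 200))
#' table(cohort$sex)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_frailscreen("config must be built with cohort_config()",
                     class = "frailscreen_config_error")
  }
  out <- withr::with_seed(config$seed, {
    rbind(
      generate_sex_block(config$n_male, "male", config),
      generate_sex_block(config$n_female, "female", config)
    )
  })
  if (nrow(out) > 0) {
    out$id <- sprintf("P%06d", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  out
}

#' Inject missingness into frailty raw fields
#'
#' Sets each of the seven frailty-relevant raw fields (two grip trials, two
#' walk trials, and the three questionnaire responses) to missing
#' independently with probability `rate`. Covariates, anthropometry and
#' weights are untouched. Used to exercise the complete-case drop rule.
#'
#' @param cohort a cohort `data.frame`.
#' @param rate missingness probability in `[0, 1]` per field and row.
#' @param seed integer seed.
#' @return the cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  assert_proportion(rate, "rate")
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  withr::with_seed(as.integer(seed), {
    for (f in FRAILTY_RAW_FIELDS) {
      hit <- stats::runif(nrow(cohort)) < rate
      cohort[[f]][hit] <- NA
    }
  })
  cohort
}
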