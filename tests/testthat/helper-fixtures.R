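# Deterministic in-code fixtures.

# Hand-built cohort with controllable measures; no RNG. Scalar arguments
# recycle across the n rows.
make_cohort <- function(n,
                        sex = "male",
                        grip = 30,
                        walk = 5,
                        bmi = 22,
                        height = 160,
                        exhaustion = "rarely (<1 day)",
                        weight_loss = "no",
                        activity = "every day",
                        weight = 1,
                        age_group = "60-69") {
  df <- data.frame(
    id = sprintf("T%04d", seq_len(n)),
    sex = rep_len(sex, n), age_group = rep_len(age_group, n),
    weight = rep_len(weight, n), bmi = rep_len(bmi, n),
    height = rep_len(height, n),
    grip_trial1 = rep_len(grip, n), grip_trial2 = rep_len(grip, n),
    walk_trial1 = rep_len(walk, n), walk_trial2 = rep_len(walk, n),
    exhaustion_response = rep_len(exhaustion, n),
    weight_loss_response = rep_len(weight_loss, n),
    activity_frequency = rep_len(activity, n),
    residence = "rural", marital = "in wedlock", education = "no education",
    work = "currently working", smoking = "no", alcohol = "no",
    adl = "no", iadl = "no",
    stringsAsFactors = FALSE
  )
  df
}

# Small component-flag table with an explicit frail label.
make_flags <- function(E, G, W, L, P, threshold = 3, sex = "male",
                       weight = 1) {
  n <- length(E)
  df <- data.frame(
    id = sprintf("F%04d", seq_len(n)), sex = rep_len(sex, n),
    age_group = "60-69", weight = rep_len(weight, n),
    E = E, G = G, W = W, L = L, P = P
  )
  df$S <- df$E + df$G + df$W + df$L + df$P
  df$frail <- as.integer(df$S >= threshold)
  df
}

small_gen_config <- function(n = 400, seed = 42) {
  cohort_config(n_male = n, n_female = n, seed = seed)
}
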