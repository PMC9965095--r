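# Independent oracles, kept free of the implementation paths they check.

# Continuity-corrected score-test inversion: the interval is
# {p : |phat - p| - 1/(2n) <= z * sqrt(p(1-p)/n)}, bounds found by root
# search, with the boundary rules lower = 0 at phat = 0 and upper = 1 at
# phat = 1.
wilson_oracle <- function(successes, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- successes / n
  h <- function(p) abs(phat - p) - 1 / (2 * n) - z * sqrt(p * (1 - p) / n)
  eps <- 1e-12
  lower <- if (phat == 0 || h(eps) < 0) 0 else
    uniroot(h, c(eps, phat), tol = 1e-13)$root
  upper <- if (phat == 1 || h(1 - eps) < 0) 1 else
    uniroot(h, c(phat, 1 - eps), tol = 1e-13)$root
  c(lower = lower, upper = upper)
}

# Direct enumeration of the five accuracy statistics from raw vectors.
metrics_oracle <- function(positive, frail) {
  positive <- as.logical(positive); frail <- as.logical(frail)
  list(
    sensitivity = if (any(frail)) mean(positive[frail]) else NA_real_,
    specificity = if (any(!frail)) mean(!positive[!frail]) else NA_real_,
    ppv = if (any(positive)) mean(frail[positive]) else NA_real_,
    npv = if (any(!positive)) mean(!frail[!positive]) else NA_real_,
    prevalence = mean(frail)
  )
}

# Textbook Pearson chi-square.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Sort-and-index lower quantile: smallest value whose cumulative fraction
# reaches p.
quantile_oracle <- function(x, p) {
  sort(x)[ceiling(p * length(x))]
}
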