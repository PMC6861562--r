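# Independent oracles, deliberately written from the textbook formulas and
# kept free of any package internals.

# Simple linear regression by the normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# One-way ANOVA F from sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  k <- length(unique(groups))
  n <- length(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(tapply(values, groups, function(v) {
    sum((v - mean(v))^2)
  }))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, df1 = k - 1, df2 = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Classic Levene: ANOVA on absolute deviations from the group means.
levene_oracle <- function(x, y) {
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  anova_oracle(z, rep(c("a", "b"), c(length(x), length(y))))
}

cohens_d_oracle <- function(a, b) {
  pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / pooled
}

# A second, loop-based paired bootstrap that consumes the same seeded
# stream as the package (one sample.int call of n * n_boot draws).
bootstrap_mae_oracle <- function(a, b, n_boot, seed) {
  n <- length(a)
  idx <- withr::with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot))
  diffs <- vapply(seq_len(n_boot), function(i) {
    mean(abs(a[idx[i, ]])) - mean(abs(b[idx[i, ]]))
  }, numeric(1))
  min(1, 2 * (min(sum(diffs <= 0), sum(diffs >= 0)) + 1) / (n_boot + 1))
}

# Small convenience builders -------------------------------------------------

# A cohort whose single feature equals age exactly (perfect linear signal).
noiseless_cohort <- function(n = 20, seed = 1) {
  generate_cohort(generator_config(
    n_per_group = c(CN = n), n_features = 1,
    feature_loadings = 1, feature_intercepts = 0, feature_noise_sd = 0,
    group_offsets = c(CN = 0), seed = seed
  ))
}

# A prediction tibble built directly from vectors.
pred_set <- function(age, predicted_raw, group = "CN",
                     provenance = "cv_out_of_fold") {
  tibble::tibble(
    subject_id = sprintf("S%05d", seq_along(age)),
    age = age, group = group,
    predicted_raw = predicted_raw, delta = predicted_raw - age,
    provenance = provenance
  )
}

# Random attenuated prediction sets used by the property suites.
random_pred_set <- function(seed, n = 60) {
  withr::with_seed(seed, {
    age <- runif(n, 47, 94)
    atten <- runif(1, 0.2, 0.9)
    noise <- runif(1, 1, 8)
    pred_set(age, 70 + atten * (age - 70) + rnorm(n, 0, noise))
  })
}
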