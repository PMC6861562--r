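boot_index_matrix <- function(n, n_boot, seed) {
  withr::with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot))
}

#' Prediction accuracy metrics
#'
#' Computes the standard brain-age accuracy panel for one prediction arm:
#' mean absolute error, root mean square error, R-squared, the delta-age
#' Pearson correlation with its two-sided p-value, and the mean delta with
#' a percentile-bootstrap 95% confidence interval.
#'
#' R-squared is the squared Pearson correlation between chronological and
#' predicted age, not `1 - SSE/SST`. The squared-correlation definition is
#' invariant under affine transforms of the predictions, which is why
#' Cole-style rescaling leaves R-squared unchanged even while it moves MAE
#' and RMSE.
#'
#' @param predictions A prediction tibble with an `age` column.
#' @param predicted Bare column name of the predicted ages to score
#'   (default `predicted_raw`; use `predicted_adjusted` for an adjusted
#'   arm).
#' @param n_boot Bootstrap resamples for the mean-delta CI.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `n`, `mae`, `rmse`, `r2`, `delta_age_r`,
#'   `delta_age_p`, `mean_delta`, `mean_delta_lo`, `mean_delta_hi`,
#'   `boot_seed`.
#' @export
accuracy_metrics <- function(predictions, predicted = predicted_raw,
                             n_boot = 1000, seed = 1L) {
  age <- predictions$age
  pred <- dplyr::pull(predictions, {{ predicted }})
  if (length(age) != length(pred) || length(age) < 3L) {
    abort_agebias("Need matched age/prediction vectors with n >= 3.",
                  "agebias_input_error")
  }
  delta <- pred - age
  r2 <- if (sd(pred) == 0 || sd(age) == 0) NA_real_ else cor(age, pred)^2
  if (sd(delta) == 0) {
    r <- 0
    p <- 1
  } else {
    ct <- cor.test(delta, age)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  md <- mean_delta_ci(delta, n_boot = n_boot, seed = seed)
  tibble::tibble(
    n = length(age),
    mae = mean(abs(delta)),
    rmse = sqrt(mean(delta^2)),
    r2 = r2,
    delta_age_r = r,
    delta_age_p = p,
    mean_delta = md$mean_delta,
    mean_delta_lo = md$ci_lo,
    mean_delta_hi = md$ci_hi,
    boot_seed = seed
  )
}

#' Mean delta with percentile bootstrap confidence interval
#'
#' @param deltas Numeric vector of brain-age deltas, `n >= 3`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; the same seed reproduces the same interval.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `mean_delta`, `ci_lo`, `ci_hi`, `n`, `n_boot`,
#'   `seed`.
#' @export
mean_delta_ci <- function(deltas, n_boot = 1000, seed = 1L, conf = 0.95) {
  if (!is.numeric(deltas) || length(deltas) < 3L) {
    abort_agebias("`deltas` must be numeric with n >= 3.",
                  "agebias_insufficient_data_error")
  }
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  idx <- boot_index_matrix(length(deltas), n_boot, seed)
  boot_means <- rowMeans(matrix(deltas[idx], nrow = n_boot))
  qs <- unname(stats::quantile(boot_means, c((1 - conf) / 2, (1 + conf) / 2)))
  tibble::tibble(
    mean_delta = mean(deltas), ci_lo = qs[1], ci_hi = qs[2],
    n = length(deltas), n_boot = n_boot, seed = seed
  )
}

#' Paired bootstrap comparison of two MAEs
#'
#' Compares the accuracy of two prediction arms on the same subjects by a
#' paired bootstrap: subjects are resampled with replacement, each resample
#' yields the two MAEs and their difference, and the two-sided p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` with a `1/(n_boot + 1)`
#' continuity guard so p is never exactly zero. 95% percentile intervals
#' are reported for each arm's MAE.
#'
#' @param abs_errors_a,abs_errors_b Per-subject absolute errors of arms A
#'   and B, in the same subject order.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return A one-row tibble: `p`, `mae_a`, `mae_a_lo`, `mae_a_hi`, `mae_b`,
#'   `mae_b_lo`, `mae_b_hi`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_mae_comparison <- function(abs_errors_a, abs_errors_b,
                                     n_boot = 1000, seed = 1L) {
  if (length(abs_errors_a) != length(abs_errors_b)) {
    abort_agebias("Paired error vectors must share one length.",
                  "agebias_pairing_error")
  }
  n <- length(abs_errors_a)
  if (n < 3L) {
    abort_agebias("Need n >= 3 paired errors.", "agebias_input_error")
  }
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  idx <- boot_index_matrix(n, n_boot, seed)
  mae_a <- rowMeans(matrix(abs_errors_a[idx], nrow = n_boot))
  mae_b <- rowMeans(matrix(abs_errors_b[idx], nrow = n_boot))
  diff <- mae_a - mae_b
  p <- min(1, 2 * (min(sum(diff <= 0), sum(diff >= 0)) + 1) / (n_boot + 1))
  ci_a <- unname(stats::quantile(mae_a, c(0.025, 0.975)))
  ci_b <- unname(stats::quantile(mae_b, c(0.025, 0.975)))
  tibble::tibble(
    p = p,
    mae_a = mean(abs_errors_a), mae_a_lo = ci_a[1], mae_a_hi = ci_a[2],
    mae_b = mean(abs_errors_b), mae_b_lo = ci_b[1], mae_b_hi = ci_b[2],
    n = n, n_boot = n_boot, seed = seed
  )
}

#' Levene's test for equality of variances between two samples
#'
#' Classic Levene test: an ANOVA F on absolute deviations from the group
#' means (or medians with `center = "median"`, the Brown-Forsythe
#' variant).
#'
#' @param x,y Numeric samples, each with `n >= 2`.
#' @param center `"mean"` (classic Levene, default) or `"median"`.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p`, `center`.
#' @export
levene_variance_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2L || length(y) < 2L) {
    abort_agebias("Each sample needs n >= 2.",
                  "agebias_insufficient_data_error")
  }
  values <- c(x, y)
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  res <- car::leveneTest(values, g, center = if (center == "mean") mean else stats::median)
  tibble::tibble(
    f = res$`F value`[1], df1 = res$Df[1], df2 = res$Df[2],
    p = res$`Pr(>F)`[1], center = center
  )
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Omnibus one-way ANOVA of brain-age deltas across groups followed by
#' Tukey's honestly-significant-difference pairwise comparisons with
#' family-wise adjusted p-values.
#'
#' @param data A data frame with delta and group columns.
#' @param delta,group Bare column names (defaults `delta`, `group`).
#' @return An object of class `group_anova`: `f`, `df` (between, within),
#'   `p`, and `tukey`, a tibble with one row per unordered group pair
#'   (`pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
group_anova_tukey <- function(data, delta = delta, group = group) {
  df <- tibble::tibble(
    delta = dplyr::pull(data, {{ delta }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  counts <- table(df$group)
  if (length(counts) < 2L) {
    abort_agebias("ANOVA needs >= 2 groups.", "agebias_degenerate_error")
  }
  if (any(counts < 2L)) {
    abort_agebias("Every group needs >= 2 subjects.",
                  "agebias_insufficient_data_error")
  }
  df$group <- factor(df$group)
  fit <- aov(delta ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(
    list(
      f = tab$`F value`[1],
      df = c(between = tab$Df[1], within = tab$Df[2]),
      p = tab$`Pr(>F)`[1],
      tukey = tibble::tibble(
        pair = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      ),
      n = nrow(df)
    ),
    class = "group_anova"
  )
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("<group_anova> F(%d, %d) = %.2f, p = %.3g\n",
              x$df[["between"]], x$df[["within"]], x$f, x$p))
  print(x$tukey)
  invisible(x)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`, where the pooled SD weights each
#' group's variance by `n - 1`.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @return The standardized mean difference (positive when `a` has the
#'   larger mean).
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_agebias("Each group needs n >= 2.",
                  "agebias_insufficient_data_error")
  }
  na <- length(a)
  nb <- length(b)
  pooled <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (pooled == 0) {
    abort_agebias("Pooled SD is zero; effect size undefined.",
                  "agebias_undefined_effect_error")
  }
  (mean(a) - mean(b)) / pooled
}

#' Full group comparison of brain-age deltas
#'
#' Bundles everything a clinical-group contrast reports: per-group mean
#' delta with a bootstrap 95% CI, the omnibus ANOVA with Tukey HSD, Levene
#' variance tests of each non-reference group against the reference, and
#' Cohen's d for each non-reference group versus the reference.
#'
#' @param data A data frame with delta and group columns.
#' @param delta,group Bare column names (defaults `delta`, `group`).
#' @param reference Reference group label (default `"CN"`); must be present.
#' @param n_boot,seed Bootstrap resamples and seed for the per-group CIs.
#' @return An object of class `group_comparison`: `group_means` (tibble),
#'   `anova` (a `group_anova`), `levene` (tibble of per-contrast F/p) and
#'   `cohens_d` (tibble of per-contrast d).
#' @export
compare_groups <- function(data, delta = delta, group = group,
                           reference = "CN", n_boot = 1000, seed = 1L) {
  df <- tibble::tibble(
    delta = dplyr::pull(data, {{ delta }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  if (!reference %in% df$group) {
    abort_agebias(sprintf("Reference group '%s' not present.", reference),
                  "agebias_input_error")
  }
  groups <- unique(df$group)
  means <- purrr::imap(setNames(groups, groups), function(g, nm) {
    ci <- mean_delta_ci(df$delta[df$group == g], n_boot = n_boot,
                        seed = seed + match(g, groups))
    dplyr::mutate(ci, group = g, .before = 1)
  })
  ref <- df$delta[df$group == reference]
  others <- setdiff(groups, reference)
  contrasts <- purrr::map(others, function(g) {
    x <- df$delta[df$group == g]
    lv <- levene_variance_test(x, ref)
    tibble::tibble(
      contrast = paste0(g, "-", reference),
      levene_f = lv$f, levene_p = lv$p,
      cohens_d = cohens_d(x, ref)
    )
  })
  structure(
    list(
      group_means = dplyr::bind_rows(means),
      anova = group_anova_tukey(df),
      contrasts = dplyr::bind_rows(contrasts),
      reference = reference
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$group_means[c("group", "mean_delta", "ci_lo", "ci_hi", "n")])
  cat(sprintf("ANOVA F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df[["between"]], x$anova$df[["within"]],
              x$anova$f, x$anova$p))
  print(x$contrasts)
  invisible(x)
}
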