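test_that("MAE and RMSE follow the textbook arithmetic", {
  age <- c(60, 65, 70, 75)
  preds <- pred_set(age, age + c(1, -1, 2, -2))
  m <- accuracy_metrics(preds, n_boot = 200, seed = 1)
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5))
  expect_gte(m$rmse, m$mae)
})

test_that("perfect predictions give the degenerate accuracy panel", {
  age <- seq(50, 90, length.out = 10)
  m <- accuracy_metrics(pred_set(age, age), n_boot = 200, seed = 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$mean_delta, 0)
  expect_equal(m$delta_age_r, 0)
  expect_equal(m$delta_age_p, 1)
})

test_that("R-squared as squared correlation is affine-invariant", {
  age <- seq(47, 94, length.out = 20)
  m <- accuracy_metrics(pred_set(age, 5 + 0.4 * age), n_boot = 200, seed = 1)
  expect_equal(m$r2, 1)
  expect_gt(m$mae, 0)
})

test_that("bootstrap MAE comparison handles exact null and deterministic separation", {
  e <- abs(withr::with_seed(2, rnorm(40, 0, 3)))
  same <- bootstrap_mae_comparison(e, e, n_boot = 500, seed = 3)
  expect_equal(same$p, 1)
  shifted <- bootstrap_mae_comparison(e, e + 5, n_boot = 500, seed = 3)
  expect_equal(shifted$p, 2 / 501)
  expect_error(bootstrap_mae_comparison(e, e[-1]),
               class = "agebias_pairing_error")
})

test_that("bootstrap MAE comparison matches an independent same-stream oracle", {
  withr::with_seed(10, {
    a <- rnorm(75, 0, 4)
    b <- rnorm(75, 0.8, 4)
  })
  got <- bootstrap_mae_comparison(abs(a), abs(b), n_boot = 1000, seed = 42)
  expect_equal(got$p, bootstrap_mae_oracle(a, b, 1000, 42), tolerance = 1e-12)
  # and it is reproducible under the seed
  again <- bootstrap_mae_comparison(abs(a), abs(b), n_boot = 1000, seed = 42)
  expect_identical(got, again)
})

test_that("Levene's test agrees with the hand-coded deviation ANOVA", {
  x <- withr::with_seed(4, rnorm(100))
  same <- levene_variance_test(x, x)
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)

  spread <- levene_variance_test(x, 3 * (x - mean(x)))
  expect_gt(spread$f, 50)
  expect_lt(spread$p, 1e-6)

  for (s in 1:20) {
    withr::with_seed(s, {
      a <- rnorm(30, 0, 1)
      b <- rnorm(40, 0, runif(1, 0.5, 3))
    })
    got <- levene_variance_test(a, b)
    exp <- levene_oracle(a, b)
    expect_equal(got$f, exp$f, tolerance = 1e-8)
    expect_equal(got$p, exp$p, tolerance = 1e-8)
  }
  expect_error(levene_variance_test(1, c(1, 2)),
               class = "agebias_insufficient_data_error")
})

test_that("group ANOVA reports the clinical-scale degrees of freedom", {
  df <- withr::with_seed(6, tibble::tibble(
    delta = rnorm(75 + 561 + 362),
    group = rep(c("CN", "MCI", "AD"), c(75, 561, 362))
  ))
  res <- group_anova_tukey(df)
  expect_equal(unname(res$df), c(2, 995))
  expect_equal(nrow(res$tukey), 3)
})

test_that("group ANOVA and Tukey agree with oracles and handle identical groups", {
  for (s in 1:20) {
    df <- withr::with_seed(s + 100, tibble::tibble(
      delta = rnorm(60, rep(c(0, 1, 2), each = 20), 2),
      group = rep(c("A", "B", "C"), each = 20)
    ))
    got <- group_anova_tukey(df)
    exp <- anova_oracle(df$delta, df$group)
    expect_equal(got$f, exp$f, tolerance = 1e-8)
    expect_equal(got$p, exp$p, tolerance = 1e-8)
  }
  same <- tibble::tibble(delta = rep(withr::with_seed(1, rnorm(20)), 3),
                         group = rep(c("A", "B", "C"), each = 20))
  res <- group_anova_tukey(same)
  expect_lt(res$f, 1e-20)
  expect_true(all(res$tukey$p_adj > 0.999))
  expect_error(group_anova_tukey(dplyr::filter(same, group == "A")),
               class = "agebias_degenerate_error")
})

test_that("Cohen's d follows the pooled-SD formula", {
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -sqrt(2))
  x <- withr::with_seed(3, rnorm(30))
  expect_equal(cohens_d(x, x), 0)
  for (s in 1:10) {
    withr::with_seed(s, {
      a <- rnorm(25, 1, 2)
      b <- rnorm(35, 0, 3)
    })
    expect_equal(cohens_d(a, b), cohens_d_oracle(a, b), tolerance = 1e-10)
  }
  expect_error(cohens_d(c(1, 1), c(1, 1)),
               class = "agebias_undefined_effect_error")
})

test_that("mean delta CI is seeded, degenerate-safe and has normal-theory width", {
  zero <- mean_delta_ci(rep(0, 20), n_boot = 300, seed = 1)
  expect_equal(zero$mean_delta, 0)
  expect_equal(zero$ci_lo, 0)
  expect_equal(zero$ci_hi, 0)

  d <- withr::with_seed(5, rnorm(75))
  a <- mean_delta_ci(d, n_boot = 1000, seed = 9)
  b <- mean_delta_ci(d, n_boot = 1000, seed = 9)
  expect_identical(a, b)

  widths <- vapply(1:50, function(s) {
    ci <- mean_delta_ci(withr::with_seed(s, rnorm(75)), n_boot = 500,
                        seed = s)
    ci$ci_hi - ci$ci_lo
  }, numeric(1))
  expect_equal(mean(widths), 2 * 1.96 / sqrt(75), tolerance = 0.1)
  expect_error(mean_delta_ci(c(1, 2)),
               class = "agebias_insufficient_data_error")
})

test_that("compare_groups bundles means, ANOVA, Levene and effect sizes coherently", {
  df <- withr::with_seed(8, tibble::tibble(
    delta = rnorm(150, rep(c(0, 2, 4), each = 50), 3),
    group = rep(c("CN", "MCI", "AD"), each = 50)
  ))
  res <- compare_groups(df, n_boot = 300, seed = 2)
  expect_setequal(res$group_means$group, c("CN", "MCI", "AD"))
  expect_true(all(res$group_means$ci_lo <= res$group_means$mean_delta &
                  res$group_means$mean_delta <= res$group_means$ci_hi))
  expect_setequal(res$contrasts$contrast, c("MCI-CN", "AD-CN"))
  d_ad <- cohens_d(df$delta[df$group == "AD"], df$delta[df$group == "CN"])
  expect_equal(res$contrasts$cohens_d[res$contrasts$contrast == "AD-CN"], d_ad)
  expect_equal(glance(res)$df_between, 2)
  td <- tidy(res)
  expect_true(all(c("mean_delta", "cohens_d", "levene_f") %in% names(td)))
})
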