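test_that("a noiseless delta-on-age line is recovered exactly", {
  age <- c(50, 60, 70, 80)
  preds <- pred_set(age, age + (-0.7 * age + 50))
  om <- fit_offset_model(preds, "proposed")
  expect_equal(om$slope, -0.7, tolerance = 1e-12)
  expect_equal(om$intercept, 50, tolerance = 1e-10)
  expect_equal(om$n_train, 4L)
  expect_equal(om$fit_provenance, "cv_out_of_fold")
})

test_that("constant deltas fit slope zero and intercept at the constant", {
  preds <- pred_set(c(50, 60, 70), c(53, 63, 73))
  om <- fit_offset_model(preds, "proposed")
  expect_equal(om$slope, 0, tolerance = 1e-12)
  expect_equal(om$intercept, 3, tolerance = 1e-12)
})

test_that("offset coefficients match the normal-equations oracle", {
  for (s in 1:10) {
    preds <- random_pred_set(s, n = 50)
    om_p <- fit_offset_model(preds, "proposed")
    om_c <- fit_offset_model(preds, "cole")
    exp_p <- ols_oracle(preds$age, preds$delta)
    exp_c <- ols_oracle(preds$age, preds$predicted_raw)
    expect_equal(om_p$slope, exp_p[["slope"]], tolerance = 1e-10)
    expect_equal(om_p$intercept, exp_p[["intercept"]], tolerance = 1e-10)
    expect_equal(om_c$slope, exp_c[["slope"]], tolerance = 1e-10)
    expect_equal(om_c$intercept, exp_c[["intercept"]], tolerance = 1e-10)
  }
})

test_that("the offset correction applies Eq.-style arithmetic per subject", {
  om <- structure(list(scheme = "proposed", slope = -0.7, intercept = 50,
                       r = NA_real_, n_train = 10L,
                       fit_provenance = "cv_out_of_fold"),
                  class = "offset_model")
  preds <- pred_set(c(60, 71.4286), c(70, 70))
  adj <- apply_proposed(preds, om)
  # offset at age 60 is -0.7*60 + 50 = 8
  expect_equal(adj$predicted_adjusted[1], 62)
  expect_equal(adj$delta_adjusted, adj$predicted_adjusted - adj$age)
  # the offset line crosses zero at age 50/0.7
  expect_equal(adj$predicted_adjusted[2], 70, tolerance = 1e-3)

  null_om <- om
  null_om$slope <- 0
  null_om$intercept <- 0
  null_adj <- apply_proposed(preds, null_om)
  expect_equal(null_adj$predicted_adjusted, preds$predicted_raw)
})

test_that("Cole rescaling applies (raw - intercept)/slope per subject", {
  om <- structure(list(scheme = "cole", slope = 0.5, intercept = 35,
                       r = NA_real_, n_train = 10L,
                       fit_provenance = "cv_out_of_fold"),
                  class = "offset_model")
  preds <- pred_set(c(70, 80), c(70, 80))
  adj <- apply_cole(preds, om)
  expect_equal(adj$predicted_adjusted, c(70, 90))

  ident <- om
  ident$slope <- 1
  ident$intercept <- 0
  expect_equal(apply_cole(preds, ident)$predicted_adjusted,
               preds$predicted_raw)
})

test_that("scheme mismatches and unstable Cole slopes are rejected", {
  preds <- random_pred_set(1)
  om_p <- fit_offset_model(preds, "proposed")
  om_c <- fit_offset_model(preds, "cole")
  expect_error(apply_proposed(preds, om_c),
               class = "agebias_scheme_mismatch_error")
  expect_error(apply_cole(preds, om_p),
               class = "agebias_scheme_mismatch_error")
  shallow <- om_c
  shallow$slope <- 0.01
  expect_error(apply_cole(preds, shallow),
               class = "agebias_unstable_adjustment_error")
  flat <- pred_set(c(50, 60, 70), c(65, 65, 65))
  expect_warning(fit_offset_model(flat, "cole"),
                 class = "agebias_unusable_cole_warning")
  expect_error(fit_offset_model(pred_set(c(60, 60), c(61, 62)), "proposed"),
               class = "agebias_singular_fit_error")
})

test_that("adjusted deltas are orthogonal to age on the fitting set (both schemes)", {
  for (s in 1:20) {
    preds <- random_pred_set(s)
    adj_p <- apply_proposed(preds, fit_offset_model(preds, "proposed"))
    adj_c <- apply_cole(preds, fit_offset_model(preds, "cole"))
    expect_lt(abs(cor(adj_p$delta_adjusted, adj_p$age)), 1e-8)
    expect_lt(abs(cor(adj_c$delta_adjusted, adj_c$age)), 1e-8)
  }
})

test_that("variance ordering holds on the fitting set", {
  for (s in 1:20) {
    preds <- random_pred_set(s)
    om_p <- fit_offset_model(preds, "proposed")
    om_c <- fit_offset_model(preds, "cole")
    adj_p <- apply_proposed(preds, om_p)
    adj_c <- apply_cole(preds, om_c)
    expect_lte(var(adj_p$delta_adjusted), var(preds$delta))
    # cole deltas are the proposed residuals rescaled by 1/alpha
    expect_equal(var(adj_c$delta_adjusted),
                 var(adj_p$delta_adjusted) / om_c$slope^2,
                 tolerance = 1e-8)
    if (abs(om_c$slope) <= 1) {
      expect_gte(var(adj_c$delta_adjusted), var(adj_p$delta_adjusted))
    }
  }
})

test_that("a training-set offset transfers to exchangeable test data", {
  rs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      age_tr <- runif(400, 47, 94)
      age_te <- runif(400, 47, 94)
      train <- pred_set(age_tr, 71 + 0.3 * (age_tr - 71) + rnorm(400, 0, 5))
      test <- pred_set(age_te, 71 + 0.3 * (age_te - 71) + rnorm(400, 0, 5),
                       provenance = "independent_test")
    })
    om <- fit_offset_model(train, "proposed")
    adj <- apply_proposed(test, om)
    cor(adj$delta_adjusted, adj$age)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(max(abs(rs)), 0.25)
})

test_that("offset models round-trip through JSON exactly", {
  om <- fit_offset_model(random_pred_set(3), "cole")
  path <- withr::local_tempfile(fileext = ".json")
  write_offset_model(om, path)
  back <- read_offset_model(path)
  expect_equal(back$slope, om$slope, tolerance = 0)
  expect_equal(back$intercept, om$intercept, tolerance = 0)
  expect_identical(back$scheme, om$scheme)
  expect_identical(back$n_train, om$n_train)
  expect_identical(back$fit_provenance, om$fit_provenance)
})

test_that("the covariate-adjusted group test detects injected offsets despite age bias", {
  withr::with_seed(77, {
    n <- c(CN = 75, MCI = 120, AD = 120)
    offs <- c(CN = 0, MCI = 2, AD = 4)  # shifts applied directly to predictions
    rows <- purrr::imap(n, function(k, g) {
      age <- runif(k, 47, 94)
      # strong age bias plus a direct group shift of the prediction
      pred <- 71 + 0.3 * (age - 71) + offs[[g]] + rnorm(k, 0, 5)
      tibble::tibble(age = age, group = g, delta = pred - age)
    })
  })
  df <- dplyr::bind_rows(rows)
  res <- le_group_test(df)
  expect_lt(res$p, 0.001)
  expect_equal(unname(res$df), c(2, nrow(df) - 4))
  expect_equal(nrow(res$adjusted_means), 3)
  # group F agrees with a direct nested-model fit
  full <- lm(delta ~ age + factor(group), df)
  red <- lm(delta ~ age, df)
  expect_equal(res$f, anova(red, full)$F[2], tolerance = 1e-10)
})

test_that("the covariate-adjusted group test is calibrated at the null", {
  hits <- vapply(1:300, function(s) {
    df <- withr::with_seed(s + 5000, tibble::tibble(
      age = runif(90, 47, 94),
      group = rep(c("A", "B", "C"), each = 30),
      delta = rnorm(90, 0, 3)
    ))
    le_group_test(df)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("two identical groups give a near-zero group effect", {
  base <- withr::with_seed(9, tibble::tibble(
    age = runif(40, 50, 90), delta = rnorm(40)
  ))
  df <- dplyr::bind_rows(
    dplyr::mutate(base, group = "A"),
    dplyr::mutate(base, group = "B")
  )
  res <- le_group_test(df)
  expect_lt(res$f, 1e-20)
  expect_error(
    le_group_test(dplyr::filter(df, group == "A")),
    class = "agebias_insufficient_data_error"
  )
})
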