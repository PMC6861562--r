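#' Fit a bias-adjustment offset model
#'
#' Both correction schemes rest on an ordinary-least-squares line fitted on
#' a training prediction set:
#'
#' * `scheme = "proposed"` regresses the brain-age delta on chronological
#'   age. The fitted line `alpha * age + beta` is the per-subject offset to
#'   subtract from the raw prediction.
#' * `scheme = "cole"` regresses the raw predicted age on chronological
#'   age. The fitted slope and intercept rescale raw predictions as
#'   `(predicted_raw - beta) / alpha`.
#'
#' Fit the offset on out-of-fold cross-validation predictions of the
#' training set, never on test data: refitting on a test set would leak its
#' age-bias into the correction.
#'
#' @param predictions A prediction tibble (columns `age`, `predicted_raw`,
#'   `delta`) with at least 2 distinct ages.
#' @param scheme `"proposed"` or `"cole"`.
#' @return An object of class `offset_model` with fields `scheme`, `slope`
#'   (alpha), `intercept` (beta), `r` (Pearson correlation of the fitted
#'   relation), `n_train` and `fit_provenance`.
#' @export
#' @examples
#' preds <- tibble::tibble(
#'   age = c(50, 60, 70, 80),
#'   predicted_raw = c(50, 60, 70, 80) * 0.3 + 50,
#'   delta = predicted_raw - age, provenance = "cv_out_of_fold"
#' )
#' fit_offset_model(preds, "proposed")  # slope -0.7, intercept 50
fit_offset_model <- function(predictions, scheme = c("proposed", "cole")) {
  scheme <- match.arg(scheme)
  check_prediction_set(predictions)
  if (nrow(predictions) < 2L || length(unique(predictions$age)) < 2L) {
    abort_agebias("Offset fitting needs >= 2 distinct ages.",
                  "agebias_singular_fit_error")
  }
  response <- if (scheme == "proposed") predictions$delta else predictions$predicted_raw
  fit <- lm(response ~ age, data = data.frame(response = response,
                                              age = predictions$age))
  slope <- unname(coef(fit)[["age"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  r <- if (sd(response) == 0) 0 else cor(predictions$age, response)
  if (scheme == "cole" && abs(slope) < 1e-12) {
    rlang::warn(paste0("Cole fit has slope 0; the model cannot be used ",
                       "for adjustment (Eq. divides by the slope)."),
                class = "agebias_unusable_cole_warning")
  }
  structure(
    list(
      scheme = scheme,
      slope = slope,
      intercept = intercept,
      r = r,
      n_train = nrow(predictions),
      fit_provenance = paste(unique(predictions$provenance %||% "unknown"),
                             collapse = "+")
    ),
    class = "offset_model"
  )
}

#' @export
print.offset_model <- function(x, ...) {
  cat(sprintf(
    "<offset_model> scheme %s: slope %.4f, intercept %.3f (r = %.3f, n = %d, fit on %s)\n",
    x$scheme, x$slope, x$intercept, x$r, x$n_train, x$fit_provenance))
  invisible(x)
}

new_adjusted <- function(predictions, predicted_adjusted, scheme) {
  dplyr::mutate(predictions,
    predicted_adjusted = predicted_adjusted,
    delta_adjusted = predicted_adjusted - .data$age,
    scheme = scheme
  )
}

#' Apply the delta-on-age offset correction
#'
#' Subtracts the fitted per-subject offset `alpha * age + beta` from the
#' raw predicted age, yielding a bias-free brain age per subject. When the
#' model was fitted on the same prediction set, the adjusted delta is an
#' OLS residual and is therefore exactly uncorrelated with age.
#'
#' @param predictions A prediction tibble.
#' @param model An `offset_model` with `scheme = "proposed"`.
#' @return The prediction tibble extended with `predicted_adjusted`,
#'   `delta_adjusted` and `scheme` columns.
#' @export
apply_proposed <- function(predictions, model) {
  check_prediction_set(predictions)
  if (!inherits(model, "offset_model") || model$scheme != "proposed") {
    abort_agebias("`model` must be an offset_model with scheme 'proposed'.",
                  "agebias_scheme_mismatch_error")
  }
  offset <- model$slope * predictions$age + model$intercept
  new_adjusted(predictions, predictions$predicted_raw - offset, "proposed")
}

#' Apply Cole's rescaling correction
#'
#' Rescales raw predictions as `(predicted_raw - beta) / alpha`, where the
#' slope and intercept come from regressing predicted age on chronological
#' age in the training set. Division by the slope inflates the prediction
#' noise by `1/alpha`, so slopes below `slope_floor` in magnitude are
#' rejected as unstable.
#'
#' @param predictions A prediction tibble.
#' @param model An `offset_model` with `scheme = "cole"`.
#' @param slope_floor Minimum `|alpha|` accepted for adjustment.
#' @return The prediction tibble extended with `predicted_adjusted`,
#'   `delta_adjusted` and `scheme` columns.
#' @export
apply_cole <- function(predictions, model, slope_floor = 0.05) {
  check_prediction_set(predictions)
  if (!inherits(model, "offset_model") || model$scheme != "cole") {
    abort_agebias("`model` must be an offset_model with scheme 'cole'.",
                  "agebias_scheme_mismatch_error")
  }
  if (abs(model$slope) < slope_floor) {
    abort_agebias(
      sprintf("Cole slope %.4g is below the stability floor %.4g; rescaling would explode variance.",
              model$slope, slope_floor),
      "agebias_unstable_adjustment_error"
    )
  }
  new_adjusted(predictions,
               (predictions$predicted_raw - model$intercept) / model$slope,
               "cole")
}

#' Covariate-adjusted group comparison of brain-age deltas
#'
#' Fits the ANCOVA `delta ~ age + group` and tests the group effect with a
#' nested-model F test, reporting covariate-adjusted group means (at the
#' overall mean age). This is a group-level procedure only: unlike the
#' offset corrections it produces no per-subject bias-free brain age.
#'
#' @param data A data frame with a delta column, an age column and a group
#'   column; at least 2 groups with at least 2 subjects each.
#' @param delta,age,group Bare column names (tidy evaluation); defaults
#'   `delta`, `age`, `group`.
#' @return An object of class `le_group_test`: `f`, `df` (between, within),
#'   `p`, and `adjusted_means` (tibble of covariate-adjusted group means
#'   with 95% confidence limits).
#' @export
le_group_test <- function(data, delta = delta, age = age, group = group) {
  df <- tibble::tibble(
    delta = dplyr::pull(data, {{ delta }}),
    age = dplyr::pull(data, {{ age }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  counts <- table(df$group)
  if (length(counts) < 2L) {
    abort_agebias("Need at least 2 groups.", "agebias_insufficient_data_error")
  }
  if (any(counts < 2L)) {
    abort_agebias(
      sprintf("Every group needs >= 2 subjects (offending: %s).",
              paste(names(counts)[counts < 2], collapse = ", ")),
      "agebias_insufficient_data_error"
    )
  }
  df$group <- factor(df$group)
  full <- lm(delta ~ age + group, data = df)
  reduced <- lm(delta ~ age, data = df)
  cmp <- anova(reduced, full)
  means <- tibble::as_tibble(
    as.data.frame(emmeans::emmeans(full, "group"))
  )
  names(means)[names(means) == "emmean"] <- "adjusted_mean"
  structure(
    list(
      f = cmp$F[2],
      df = c(between = cmp$Df[2], within = cmp$Res.Df[2]),
      p = cmp$`Pr(>F)`[2],
      adjusted_means = means,
      n = nrow(df)
    ),
    class = "le_group_test"
  )
}

#' @export
print.le_group_test <- function(x, ...) {
  cat(sprintf("<le_group_test> F(%d, %d) = %.2f, p = %.3g\n",
              x$df[["between"]], x$df[["within"]], x$f, x$p))
  print(x$adjusted_means)
  invisible(x)
}

#' Serialize and restore offset models as JSON
#'
#' The JSON object carries `scheme`, `slope`, `intercept`, `n_train` and
#' `fit_provenance` and round-trips exactly (full double precision).
#'
#' @param model An `offset_model`.
#' @param path File path.
#' @return `write_offset_model()` returns `path` invisibly;
#'   `read_offset_model()` returns the restored `offset_model`.
#' @export
write_offset_model <- function(model, path) {
  jsonlite::write_json(
    list(scheme = model$scheme, slope = model$slope,
         intercept = model$intercept, r = model$r,
         n_train = model$n_train, fit_provenance = model$fit_provenance),
    path, auto_unbox = TRUE, digits = I(17)  # 17 significant digits: exact IEEE round trip
  )
  invisible(path)
}

#' @rdname write_offset_model
#' @export
read_offset_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(scheme = raw$scheme, slope = raw$slope, intercept = raw$intercept,
         r = raw$r %||% NA_real_, n_train = as.integer(raw$n_train),
         fit_provenance = raw$fit_provenance),
    class = "offset_model"
  )
}
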