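#' Fit a brain-age regressor on cohort features
#'
#' Regresses chronological age on the regional feature columns
#' (`feat_*`). The default backend is linear epsilon-insensitive support
#' vector regression with library-default hyperparameters (cost 1,
#' epsilon 0.1), fitted on features standardized by the training-set mean
#' and SD; the standardization is stored with the model and re-applied at
#' prediction time. An ordinary-least-squares backend is available so that
#' downstream bias-correction results can be checked independently of SVR
#' specifics.
#'
#' @param cohort A cohort tibble with an `age` column and `feat_*` feature
#'   columns; at least 2 subjects, no missing feature values.
#' @param backend `"svr"` (default) or `"ols"`.
#' @return An object of class `brainage_model` holding the fitted backend,
#'   the per-feature standardization, and fit metadata.
#' @seealso [cross_val_predict()], [predict.brainage_model()]
#' @export
fit_regressor <- function(cohort, backend = c("svr", "ols")) {
  backend <- match.arg(backend)
  feats <- feature_columns(cohort)
  if (length(feats) == 0L) {
    abort_agebias("`cohort` has no `feat_*` feature columns.",
                  "agebias_input_error")
  }
  if (nrow(cohort) < 2L) {
    abort_agebias("Training requires at least 2 subjects.",
                  "agebias_degenerate_training_error")
  }
  x <- as.matrix(cohort[feats])
  if (anyNA(x) || anyNA(cohort$age)) {
    abort_agebias("Missing feature or age values are not supported.",
                  "agebias_input_error")
  }
  if (sd(cohort$age) == 0) {
    abort_agebias("Age column is constant; cannot train a regressor.",
                  "agebias_degenerate_training_error")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1  # constant features carry no signal; leave as-is
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  fit <- switch(backend,
    svr = e1071::svm(x = xs, y = cohort$age, type = "eps-regression",
                     kernel = "linear", cost = 1, epsilon = 0.1,
                     scale = FALSE),
    ols = lm(y ~ ., data = data.frame(y = cohort$age, xs, check.names = FALSE))
  )

  structure(
    list(
      backend = backend,
      fit = fit,
      center = center,
      scale = scale_,
      feature_names = feats,
      n_train = nrow(cohort),
      hyperparameters = if (backend == "svr") {
        list(kernel = "linear", cost = 1, epsilon = 0.1)
      } else {
        list()
      }
    ),
    class = "brainage_model"
  )
}

#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf("<brainage_model> backend %s, %d features, n_train %d\n",
              x$backend, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict brain age for a cohort
#'
#' Applies a fitted [fit_regressor()] model (including its stored feature
#' standardization) to a cohort and returns a prediction tibble with the
#' delta (predicted minus chronological age) computed per row.
#'
#' @param object A `brainage_model`.
#' @param cohort A cohort tibble whose `feat_*` columns match the model's
#'   training features. An empty cohort yields an empty prediction set.
#' @param provenance Provenance label for the rows (default
#'   `"independent_test"`).
#' @param ... Unused.
#' @return A prediction tibble: `subject_id`, `age`, `group`,
#'   `predicted_raw`, `delta`, `provenance`.
#' @export
predict.brainage_model <- function(object, cohort,
                                   provenance = "independent_test", ...) {
  feats <- feature_columns(cohort)
  if (!identical(sort(feats), sort(object$feature_names))) {
    abort_agebias(
      sprintf("Cohort features (%d) do not match the model's features (%d).",
              length(feats), length(object$feature_names)),
      "agebias_shape_error"
    )
  }
  if (nrow(cohort) == 0L) {
    return(tibble::tibble(
      subject_id = character(), age = double(), group = character(),
      predicted_raw = double(), delta = double(), provenance = character()
    ))
  }
  x <- as.matrix(cohort[object$feature_names])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pred <- switch(object$backend,
    svr = as.numeric(predict(object$fit, xs)),
    ols = as.numeric(predict(object$fit,
                             newdata = data.frame(xs, check.names = FALSE)))
  )
  tibble::tibble(
    subject_id = if ("subject_id" %in% names(cohort)) cohort$subject_id else sprintf("S%05d", seq_len(nrow(cohort))),
    age = cohort$age,
    group = if ("group" %in% names(cohort)) cohort$group else NA_character_,
    predicted_raw = pred,
    delta = pred - cohort$age,
    provenance = provenance
  )
}

#' Out-of-fold brain-age predictions by k-fold cross-validation
#'
#' Randomly partitions the cohort into `k` folds of sizes differing by at
#' most one (seeded), fits a regressor on each set of `k - 1` folds and
#' predicts the held-out fold, so every subject receives exactly one
#' prediction from a model that never saw it.
#'
#' @param cohort A cohort tibble.
#' @param k Number of folds, `2 <= k <= nrow(cohort)`.
#' @param seed Integer seed for the fold assignment.
#' @param backend Regressor backend, see [fit_regressor()].
#' @return A prediction tibble with provenance `"cv_out_of_fold"`, in the
#'   cohort's row order.
#' @export
cross_val_predict <- function(cohort, k = 10, seed = 1L,
                              backend = c("svr", "ols")) {
  backend <- match.arg(backend)
  n <- nrow(cohort)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > n) {
    abort_agebias(sprintf("`k` must satisfy 2 <= k <= n (= %d).", n),
                  "agebias_parameter_error")
  }
  k <- as.integer(k)
  seed <- assert_count(seed, "seed", min = 0L)
  fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  out <- purrr::map(seq_len(k), function(f) {
    model <- fit_regressor(cohort[fold != f, , drop = FALSE], backend = backend)
    preds <- predict(model, cohort[fold == f, , drop = FALSE],
                     provenance = "cv_out_of_fold")
    preds$.row <- which(fold == f)
    preds
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$.row)
  out$.row <- NULL
  out
}
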