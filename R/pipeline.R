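#' Configuration for a full bias-adjustment experiment
#'
#' Describes one end-to-end run: cohort generation (or loading), a seeded
#' train/test split of the reference group, k-fold cross-validation on the
#' training set, offset fitting on the out-of-fold predictions, prediction
#' of the held-out and clinical test sets, the requested adjustment arms,
#' and the statistical evaluation.
#'
#' All stage seeds are derived from the single `seed` by fixed documented
#' offsets (generator +1001, split +2002, folds +3003, bootstraps +4004),
#' so any stage can be re-run in isolation reproducibly.
#'
#' @param generator A [generator_config()]; its own seed is overridden by
#'   the derived generator seed. Ignored when `cohort_paths` is given.
#' @param cohort_paths Optional character vector of cohort CSV paths to
#'   load (rows are concatenated) instead of generating data.
#' @param split_frac Fraction of the reference group used for training,
#'   in (0, 1); default 0.9.
#' @param k Cross-validation folds (default 10).
#' @param backend Regressor backend, `"svr"` or `"ols"`.
#' @param schemes Adjustment arms to run, a non-empty subset of
#'   `c("none", "proposed", "cole")`.
#' @param reference Reference (training) group label, default `"CN"`.
#' @param n_boot Bootstrap resamples for CIs and MAE comparisons.
#' @param cole_slope_floor Minimum `|slope|` for Cole adjustment.
#' @param seed Master seed.
#' @param verbose Emit one log line per stage.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              cohort_paths = NULL,
                              split_frac = 0.9,
                              k = 10,
                              backend = c("svr", "ols"),
                              schemes = c("none", "proposed", "cole"),
                              reference = "CN",
                              n_boot = 1000,
                              cole_slope_floor = 0.05,
                              seed = 42L,
                              verbose = FALSE) {
  backend <- match.arg(backend)
  if (!is.numeric(split_frac) || split_frac <= 0 || split_frac >= 1) {
    abort_agebias("`split_frac` must lie strictly in (0, 1).",
                  "agebias_config_error")
  }
  if (length(schemes) == 0 ||
      !all(schemes %in% c("none", "proposed", "cole"))) {
    abort_agebias(
      "`schemes` must be a non-empty subset of {none, proposed, cole}.",
      "agebias_config_error"
    )
  }
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(generator = generator, cohort_paths = cohort_paths,
         split_frac = split_frac, k = k, backend = backend,
         schemes = unique(schemes), reference = reference, n_boot = n_boot,
         cole_slope_floor = cole_slope_floor, seed = seed,
         verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

stage_seeds <- function(seed) {
  list(generator = seed + 1001L, split = seed + 2002L,
       folds = seed + 3003L, boot = seed + 4004L)
}

with_stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    abort_agebias(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "agebias_stage_error", parent = e)
  })
  if (verbose) {
    message(sprintf("[agebias] stage=%s elapsed=%.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run a full bias-adjustment experiment
#'
#' Executes the whole design: generate or load the cohort; split the
#' reference group into training and held-out test subsets; obtain
#' out-of-fold training predictions by k-fold cross-validation; fit the
#' offset models (delta-on-age and predicted-on-age) on those predictions
#' and freeze them; refit the regressor on the full training set; predict
#' all test groups; apply each requested adjustment arm; and evaluate
#' every arm (accuracy panel, per-group mean deltas with CIs, ANOVA with
#' Tukey HSD, Levene contrasts, Cohen's d, pairwise bootstrap MAE
#' comparisons between arms, and the covariate-adjusted group test).
#'
#' The offset models never see test data; they are fitted once on the
#' training cross-validation predictions and applied unchanged.
#'
#' @param config An [experiment_config()].
#' @return An object of class `agebias_experiment`; see
#'   [write_experiment()] and [reproduce_figures()].
#' @export
run_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config")) {
    abort_agebias("`config` must be created by experiment_config().",
                  "agebias_config_error")
  }
  seeds <- stage_seeds(config$seed)
  verbose <- config$verbose

  cohort <- with_stage("cohort", verbose, {
    if (!is.null(config$cohort_paths)) {
      dplyr::bind_rows(purrr::map(config$cohort_paths, read_cohort))
    } else {
      gen <- config$generator
      gen$seed <- seeds$generator
      generate_cohort(gen)
    }
  })

  split <- with_stage("split", verbose, {
    ref_rows <- which(cohort$group == config$reference)
    if (length(ref_rows) < 2L) {
      abort_agebias(sprintf("Reference group '%s' too small to split.",
                            config$reference), "agebias_input_error")
    }
    n_train <- floor(config$split_frac * length(ref_rows))
    train_rows <- withr::with_seed(seeds$split,
                                   sort(sample(ref_rows, n_train)))
    list(train = cohort[train_rows, , drop = FALSE],
         test = cohort[setdiff(seq_len(nrow(cohort)), train_rows), ,
                       drop = FALSE])
  })

  cv <- with_stage("cross_validation", verbose,
    cross_val_predict(split$train, k = config$k, seed = seeds$folds,
                      backend = config$backend))

  offsets <- with_stage("offset_fitting", verbose, {
    out <- list()
    if ("proposed" %in% config$schemes) {
      out$proposed <- fit_offset_model(cv, "proposed")
    }
    if ("cole" %in% config$schemes) {
      out$cole <- fit_offset_model(cv, "cole")
    }
    out
  })

  test_preds <- with_stage("final_model", verbose, {
    model <- fit_regressor(split$train, backend = config$backend)
    list(model = model,
         preds = predict(model, split$test, provenance = "independent_test"))
  })

  arms <- with_stage("adjustment_arms", verbose, {
    purrr::map(setNames(config$schemes, config$schemes), function(s) {
      adjust <- switch(s,
        none = function(p) dplyr::mutate(p,
          predicted_adjusted = .data$predicted_raw,
          delta_adjusted = .data$delta, scheme = "none"),
        proposed = function(p) apply_proposed(p, offsets$proposed),
        cole = function(p) apply_cole(p, offsets$cole,
                                      slope_floor = config$cole_slope_floor)
      )
      list(scheme = s, train = adjust(cv), test = adjust(test_preds$preds))
    })
  })

  report <- with_stage("evaluation", verbose, {
    purrr::map(arms, function(arm) {
      test_ref <- dplyr::filter(arm$test, .data$group == config$reference)
      groups_present <- unique(arm$test$group)
      list(
        scheme = arm$scheme,
        train_metrics = accuracy_metrics(arm$train,
                                         predicted = predicted_adjusted,
                                         n_boot = config$n_boot,
                                         seed = seeds$boot),
        test_metrics = accuracy_metrics(test_ref,
                                        predicted = predicted_adjusted,
                                        n_boot = config$n_boot,
                                        seed = seeds$boot + 1L),
        groups = if (length(groups_present) >= 2) {
          compare_groups(arm$test, delta = delta_adjusted,
                         reference = config$reference,
                         n_boot = config$n_boot, seed = seeds$boot + 2L)
        }
      )
    })
  })

  comparisons <- with_stage("arm_comparisons", verbose, {
    ref_err <- purrr::map(arms, function(arm) {
      t <- dplyr::filter(arm$test, .data$group == config$reference)
      abs(t$delta_adjusted)
    })
    pairs <- if (length(arms) >= 2) {
      utils::combn(names(arms), 2, simplify = FALSE)
    } else {
      list()
    }
    mae <- purrr::map(pairs, function(pr) {
      res <- bootstrap_mae_comparison(ref_err[[pr[1]]], ref_err[[pr[2]]],
                                      n_boot = config$n_boot,
                                      seed = seeds$boot + 3L)
      dplyr::mutate(res, arm_a = pr[1], arm_b = pr[2], .before = 1)
    })
    lev <- purrr::map(pairs, function(pr) {
      res <- levene_variance_test(arms[[pr[1]]]$train$delta_adjusted,
                                  arms[[pr[2]]]$train$delta_adjusted)
      dplyr::mutate(res, arm_a = pr[1], arm_b = pr[2], .before = 1)
    })
    list(mae = dplyr::bind_rows(mae), levene_train = dplyr::bind_rows(lev))
  })

  le <- with_stage("le_group_test", verbose, {
    if (length(unique(test_preds$preds$group)) >= 2) {
      le_group_test(test_preds$preds)
    }
  })

  structure(
    list(
      config = config, seeds = seeds,
      sizes = c(train = nrow(split$train), test = nrow(split$test)),
      offsets = offsets,
      arms = arms,
      evaluation = report,
      comparisons = comparisons,
      le = le
    ),
    class = "agebias_experiment"
  )
}

#' @export
print.agebias_experiment <- function(x, ...) {
  cat("<agebias_experiment>\n")
  cat(sprintf("  backend %s, arms: %s; train n = %d, test n = %d\n",
              x$config$backend, paste(names(x$arms), collapse = "/"),
              x$sizes[["train"]], x$sizes[["test"]]))
  for (nm in names(x$evaluation)) {
    m <- x$evaluation[[nm]]$test_metrics
    cat(sprintf("  [%s] test MAE %.2f, RMSE %.2f, R2 %.2f, delta-age r %.2f\n",
                nm, m$mae, m$rmse, m$r2, m$delta_age_r))
  }
  invisible(x)
}

#' Write an experiment report bundle to disk
#'
#' Emits a JSON summary (`report.json`), per-arm train/test prediction
#' CSVs, and the offset models as JSON, all under `dir`.
#'
#' @param experiment An `agebias_experiment` from [run_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(experiment$arms)) {
    write_predictions(experiment$arms[[nm]]$train,
                      file.path(dir, sprintf("train_%s.csv", nm)))
    write_predictions(experiment$arms[[nm]]$test,
                      file.path(dir, sprintf("test_%s.csv", nm)))
  }
  for (nm in names(experiment$offsets)) {
    write_offset_model(experiment$offsets[[nm]],
                       file.path(dir, sprintf("offset_%s.json", nm)))
  }
  summary <- list(
    seed = experiment$config$seed,
    backend = experiment$config$backend,
    sizes = as.list(experiment$sizes),
    arms = purrr::map(experiment$evaluation, function(ev) {
      list(
        train_metrics = as.list(ev$train_metrics),
        test_metrics = as.list(ev$test_metrics),
        group_means = if (!is.null(ev$groups)) ev$groups$group_means,
        anova = if (!is.null(ev$groups)) {
          list(f = ev$groups$anova$f, df = as.list(ev$groups$anova$df),
               p = ev$groups$anova$p)
        },
        contrasts = if (!is.null(ev$groups)) ev$groups$contrasts
      )
    }),
    mae_comparisons = experiment$comparisons$mae,
    levene_train = experiment$comparisons$levene_train,
    le_group_test = if (!is.null(experiment$le)) {
      list(f = experiment$le$f, df = as.list(experiment$le$df),
           p = experiment$le$p,
           adjusted_means = experiment$le$adjusted_means)
    }
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(dir)
}

scatter_table <- function(preds, value_col) {
  fit <- lm(stats::reformulate("age", value_col), data = preds)
  # predict.lm warns that in-sample prediction intervals refer to future
  # responses; that is exactly the band the figures display.
  band <- as.data.frame(suppressWarnings(
    predict(fit, interval = "prediction", level = 0.95)))
  tibble::tibble(
    age = preds$age,
    value = preds[[value_col]],
    fit = band$fit, lwr = band$lwr, upr = band$upr
  )
}

#' Scatter-data tables for figure reconstruction
#'
#' For each adjustment arm and each of the training and test prediction
#' sets, emits (age, predicted) and (age, delta) tables with the fitted
#' regression line and 95% prediction band, ready for plotting.
#'
#' @param experiment An `agebias_experiment` from [run_experiment()].
#' @return A tibble with columns `arm`, `set` (train/test), `panel`
#'   (predicted/delta), `age`, `value`, `fit`, `lwr`, `upr`.
#' @export
reproduce_figures <- function(experiment) {
  if (!inherits(experiment, "agebias_experiment") ||
      length(experiment$arms) == 0) {
    abort_agebias("`experiment` must be a complete agebias_experiment.",
                  "agebias_missing_section_error")
  }
  rows <- purrr::map(names(experiment$arms), function(nm) {
    arm <- experiment$arms[[nm]]
    purrr::map2(
      list(arm$train, arm$test), c("train", "test"),
      function(preds, set) {
        dplyr::bind_rows(
          dplyr::mutate(scatter_table(preds, "predicted_adjusted"),
                        panel = "predicted", .before = 1),
          dplyr::mutate(scatter_table(preds, "delta_adjusted"),
                        panel = "delta", .before = 1)
        ) |>
          dplyr::mutate(arm = nm, set = set, .before = 1)
      }
    ) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
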