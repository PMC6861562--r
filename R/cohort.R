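#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of subjects whose regional imaging features carry an
#' age signal plus measurement noise. Each subject has a chronological age
#' drawn uniformly from `[age_low, age_high]`, a latent brain age equal to
#' chronological age plus a group-specific acceleration, and feature values
#' that are linear in latent brain age with additive Gaussian noise. The
#' measurement noise is what induces regression dilution in any regressor
#' trained on the features, which is the phenomenon the bias-adjustment
#' schemes in this package exist to correct.
#'
#' Default feature parameters mimic regional FDG-PET SUVR values: baseline
#' near 1.25, a mild metabolic decline of about 0.003 SUVR per year of brain
#' age, and measurement noise of 0.05 SUVR. Default group offsets give
#' cognitively unimpaired (CN) subjects no acceleration, mild cognitive
#' impairment (MCI) +2.0 years and Alzheimer's disease (AD) +4.1 years.
#'
#' @param n_per_group Named integer vector: subjects per group label.
#' @param age_low,age_high Uniform sampling bounds for chronological age
#'   (years); `age_low < age_high`.
#' @param n_features Number of regional features.
#' @param feature_loadings Per-feature slope on latent brain age
#'   (feature-units per year); recycled to `n_features`.
#' @param feature_intercepts Per-feature baseline value; recycled.
#' @param feature_noise_sd Per-feature measurement-noise SD; recycled,
#'   all values must be >= 0.
#' @param group_offsets Named numeric vector mapping each group label to an
#'   additive brain-age acceleration in years; must cover every name in
#'   `n_per_group`.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate identical cohorts.
#'
#' @return An object of class `generator_config`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- generator_config(n_per_group = c(CN = 20), seed = 1)
#' generate_cohort(cfg)
generator_config <- function(n_per_group = c(CN = 750, MCI = 561, AD = 362),
                             age_low = 47,
                             age_high = 94,
                             n_features = 12,
                             feature_loadings = -0.003,
                             feature_intercepts = 1.25,
                             feature_noise_sd = 0.05,
                             group_offsets = c(CN = 0, MCI = 2.0, AD = 4.1),
                             seed = 1L) {
  if (length(n_per_group) < 1L || is.null(names(n_per_group)) ||
      any(!nzchar(names(n_per_group)))) {
    abort_agebias("`n_per_group` must be a named vector of group sizes.",
                  "agebias_config_error")
  }
  for (g in names(n_per_group)) assert_count(n_per_group[[g]], paste0("n_per_group[", g, "]"))
  assert_scalar_number(age_low, "age_low")
  assert_scalar_number(age_high, "age_high")
  if (!(age_low < age_high)) {
    abort_agebias("`age_low` must be strictly less than `age_high`.",
                  "agebias_config_error")
  }
  n_features <- assert_count(n_features, "n_features")
  recycle <- function(x, name) {
    if (!is.numeric(x) || !(length(x) %in% c(1L, n_features))) {
      abort_agebias(
        sprintf("`%s` must have length 1 or n_features (%d).", name, n_features),
        "agebias_config_error"
      )
    }
    rep_len(as.double(x), n_features)
  }
  feature_loadings <- recycle(feature_loadings, "feature_loadings")
  feature_intercepts <- recycle(feature_intercepts, "feature_intercepts")
  feature_noise_sd <- recycle(feature_noise_sd, "feature_noise_sd")
  if (any(feature_noise_sd < 0)) {
    abort_agebias("`feature_noise_sd` values must all be >= 0.",
                  "agebias_config_error")
  }
  missing_groups <- setdiff(names(n_per_group), names(group_offsets))
  if (length(missing_groups) > 0) {
    abort_agebias(
      sprintf("`group_offsets` is missing labels: %s.",
              paste(missing_groups, collapse = ", ")),
      "agebias_config_error"
    )
  }
  seed <- assert_count(seed, "seed", min = 0L)

  structure(
    list(
      n_per_group = vapply(n_per_group, as.integer, integer(1)),
      age_low = age_low, age_high = age_high,
      n_features = n_features,
      feature_loadings = feature_loadings,
      feature_intercepts = feature_intercepts,
      feature_noise_sd = feature_noise_sd,
      group_offsets = group_offsets,
      seed = seed
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  ages: U(%g, %g); features: %d; seed: %d\n",
              x$age_low, x$age_high, x$n_features, x$seed))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws one subject table from a [generator_config()]: chronological ages
#' uniform on the configured range, latent brain age = age + group offset,
#' and features linear in latent brain age with Gaussian measurement noise.
#' The same configuration and seed always reproduce the identical table.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `subject_id`, `age`, `group` and
#'   `feat_0001` ... `feat_<n>`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort_agebias("`config` must be created by generator_config().",
                  "agebias_config_error")
  }
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  withr::with_seed(config$seed, {
    age <- runif(n, config$age_low, config$age_high)
    latent <- age + unname(config$group_offsets[groups])
    feats <- vapply(seq_len(config$n_features), function(j) {
      config$feature_intercepts[j] + config$feature_loadings[j] * latent +
        rnorm(n, 0, config$feature_noise_sd[j])
    }, numeric(n))
  })
  feats <- matrix(feats, nrow = n)
  colnames(feats) <- sprintf("feat_%04d", seq_len(config$n_features))
  out <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age,
    group = groups
  )
  dplyr::bind_cols(out, tibble::as_tibble(feats))
}

#' Read and write cohort tables
#'
#' Cohort CSVs have a `subject_id,age,group,feat_0001,...` header, UTF-8
#' encoding and '.' as the decimal separator, one row per subject.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort_agebias(sprintf("Cohort file '%s' does not exist.", path),
                  "agebias_input_error")
  }
  out <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  )
  needed <- c("subject_id", "age", "group")
  if (!all(needed %in% names(out))) {
    abort_agebias(
      sprintf("Cohort file must contain columns %s.", paste(needed, collapse = ", ")),
      "agebias_input_error"
    )
  }
  out
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Keys match the argument names of [generator_config()] exactly; absent
#' keys fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(generator_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra) > 0) {
    abort_agebias(sprintf("Unknown generator config keys: %s.",
                          paste(extra, collapse = ", ")),
                  "agebias_config_error")
  }
  for (key in c("n_per_group", "group_offsets")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  do.call(generator_config, raw)
}
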