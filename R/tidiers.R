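#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an offset model
#'
#' @param x An `offset_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`slope`, `intercept`).
#' @method tidy offset_model
#' @export
tidy.offset_model <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    scheme = x$scheme
  )
}

#' @rdname tidy.offset_model
#' @return `glance()`: a one-row tibble with the fit's scheme, slope,
#'   intercept, Pearson r, training size and provenance.
#' @method glance offset_model
#' @export
glance.offset_model <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, slope = x$slope, intercept = x$intercept,
    r = x$r, n_train = x$n_train, fit_provenance = x$fit_provenance
  )
}

#' Tidy a group ANOVA
#'
#' @param x A `group_anova` from [group_anova_tukey()].
#' @param ... Unused.
#' @return `tidy()`: the Tukey HSD pairwise table; `glance()`: a one-row
#'   tibble with the omnibus F, df and p.
#' @method tidy group_anova
#' @export
tidy.group_anova <- function(x, ...) x$tukey

#' @rdname tidy.group_anova
#' @method glance group_anova
#' @export
glance.group_anova <- function(x, ...) {
  tibble::tibble(
    f = x$f, df_between = x$df[["between"]], df_within = x$df[["within"]],
    p = x$p, n = x$n
  )
}

#' Tidy a covariate-adjusted group test
#'
#' @param x An `le_group_test`.
#' @param ... Unused.
#' @return `tidy()`: the covariate-adjusted group means; `glance()`: the
#'   group-effect F, df and p.
#' @method tidy le_group_test
#' @export
tidy.le_group_test <- function(x, ...) x$adjusted_means

#' @rdname tidy.le_group_test
#' @method glance le_group_test
#' @export
glance.le_group_test <- function(x, ...) {
  tibble::tibble(
    f = x$f, df_between = x$df[["between"]], df_within = x$df[["within"]],
    p = x$p, n = x$n
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return `tidy()`: per-group mean deltas with CIs joined to the
#'   per-contrast Levene and Cohen's d results; `glance()`: the omnibus
#'   ANOVA summary.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::left_join(
    x$group_means,
    dplyr::mutate(x$contrasts,
                  group = sub(paste0("-", x$reference, "$"), "",
                              .data$contrast)),
    by = "group"
  )
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) glance(x$anova)
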