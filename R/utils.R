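#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats lm coef cor cor.test predict anova aov TukeyHSD sd var
#'   setNames runif rnorm pf
#' @importFrom utils head
NULL

# Stop with a classed condition so callers can test on the class, not the text.
abort_agebias <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "agebias_error"), ...)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_agebias(
      sprintf("`%s` must be a single finite number.", name),
      "agebias_config_error"
    )
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort_agebias(
      sprintf("`%s` must be a whole number >= %d.", name, min),
      "agebias_config_error"
    )
  }
  invisible(as.integer(x))
}

# Columns holding regional feature values follow the cohort CSV contract.
feature_columns <- function(data) {
  grep("^feat_", names(data), value = TRUE)
}

check_prediction_set <- function(predictions, arg = "predictions") {
  needed <- c("age", "predicted_raw", "delta")
  missing <- setdiff(needed, names(predictions))
  if (length(missing) > 0) {
    abort_agebias(
      sprintf(
        "`%s` must contain columns %s (missing: %s).",
        arg, paste(needed, collapse = ", "), paste(missing, collapse = ", ")
      ),
      "agebias_input_error"
    )
  }
  invisible(predictions)
}
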