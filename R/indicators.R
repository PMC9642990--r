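#' Declare a latent-class indicator
#'
#' An indicator is either ordinal (category codes `1..n_categories`) or
#' continuous. The ten canonical adolescent lifestyle indicators are returned
#' by [lifestyle_indicators()].
#'
#' @param name Column name in the cohort table.
#' @param kind `"ordinal"` or `"continuous"`.
#' @param n_categories Number of ordered categories (ordinal only, >= 2).
#' @param timepoint Optional label for the measurement wave (e.g. `"age 14"`).
#' @return A one-row tibble describing the indicator.
#' @export
#' @examples
#' indicator_spec("smoke17", "ordinal", 4, "age 17")
indicator_spec <- function(name, kind = c("ordinal", "continuous"),
                           n_categories = NULL, timepoint = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "ordinal") {
    n_categories <- check_count(n_categories, "n_categories", min = 2L)
  } else {
    n_categories <- NA_integer_
  }
  tibble::tibble(
    name = as.character(name), kind = kind,
    n_categories = n_categories, timepoint = as.character(timepoint)
  )
}

#' The ten adolescent lifestyle indicators
#'
#' Continuous BMI at ages 12/14/17, leisure-time physical activity at 12
#' (3 levels) and 14/17 (4 levels), smoking status and binge drinking at
#' 14/17 (4 levels each).
#'
#' @return A tibble with one row per indicator, ordered as used throughout
#'   the package.
#' @export
lifestyle_indicators <- function() {
  dplyr::bind_rows(
    indicator_spec("bmi12", "continuous", timepoint = "age 12"),
    indicator_spec("bmi14", "continuous", timepoint = "age 14"),
    indicator_spec("bmi17", "continuous", timepoint = "age 17"),
    indicator_spec("ltpa12", "ordinal", 3, "age 12"),
    indicator_spec("ltpa14", "ordinal", 4, "age 14"),
    indicator_spec("ltpa17", "ordinal", 4, "age 17"),
    indicator_spec("smoke14", "ordinal", 4, "age 14"),
    indicator_spec("smoke17", "ordinal", 4, "age 17"),
    indicator_spec("alc14", "ordinal", 4, "age 14"),
    indicator_spec("alc17", "ordinal", 4, "age 17")
  )
}

# validate an indicator-spec tibble
check_indicator_specs <- function(specs) {
  need <- c("name", "kind", "n_categories")
  if (!all(need %in% names(specs))) {
    abort("indicator specs need columns name, kind, n_categories")
  }
  if (anyDuplicated(specs$name)) abort("indicator names must be unique")
  if (!all(specs$kind %in% c("ordinal", "continuous"))) {
    abort("indicator kind must be 'ordinal' or 'continuous'")
  }
  ok <- specs$kind == "continuous" | (specs$n_categories >= 2L)
  if (!all(ok, na.rm = FALSE)) abort("ordinal indicators need n_categories >= 2")
  invisible(specs)
}
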