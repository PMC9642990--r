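#' Configure a synthetic twin cohort
#'
#' Builds and validates the full generating model for [generate_cohort()]:
#' zygosity composition, a liability-threshold latent class structure with a
#' heritable liability (monozygotic co-twins share the genetic liability
#' component completely, dizygotic co-twins share half of it),
#' class-conditional indicator distributions, AE-structured outcomes whose
#' additive-genetic part is partially shared with the class liability,
#' covariate effects, and missing-at-random item missingness.
#'
#' @param n_pairs Number of twin pairs (>= 2).
#' @param zygosity_probs Length-3 probability vector for (MZ, same-sex DZ,
#'   opposite-sex DZ) pairs; normalized internally.
#' @param class_props Latent class proportions (length K, sums to 1).
#' @param class_liability_h2 Fraction in `[0, 1]` of class-liability variance
#'   that is additive genetic.
#' @param sex_liability_shift Mean liability difference between the sexes
#'   (females get `+shift/2`, males `-shift/2`); `0` disables it.
#' @param indicator_params Named list, one entry per indicator. Ordinal
#'   entries are `list(kind = "ordinal", probs = <C x K matrix>)` with
#'   columns the per-class category probabilities; continuous entries are
#'   `list(kind = "continuous", means = <K-vector>, sds = <K-vector>)`.
#' @param outcome_params Named list, one entry per outcome:
#'   `list(class_means, a2, e2, shared_a_frac, resid_sd)`. `a2` and `e2` are
#'   shares of the residual (within-class) variance and must sum to 1;
#'   `resid_sd` scales the residual part to outcome units;
#'   `shared_a_frac` is the fraction of the outcome's additive-genetic
#'   variance carried by the class-liability genetic score.
#' @param covariate_effects Named list per outcome with elements
#'   `sex_female`, `age`, `pds` (regression coefficients in outcome units).
#' @param missing_rates Named list: `base` (named per-indicator marginal
#'   missingness probabilities), `sex_coef`, `age_coef` (logit coefficients
#'   on female sex and centred age; missingness never depends on the missing
#'   value itself, i.e. MAR).
#' @param outcome_pair_prob Probability that a twin pair enters the
#'   biological-aging subsample; `outcome_both_prob` is the probability that
#'   both members (rather than one) are measured given the pair is sampled.
#' @param outcome_both_prob See `outcome_pair_prob`.
#' @param pds_class_cor Correlation between the pubertal-development latent
#'   and the class liability.
#' @param seed Default integer seed used by [generate_cohort()] when none is
#'   given there.
#' @return An object of class `cohort_config`.
#' @seealso [default_lifestyle_config()] for the full ten-indicator,
#'   five-class configuration used throughout the documentation.
#' @export
cohort_config <- function(n_pairs,
                          zygosity_probs = c(0.34, 0.33, 0.33),
                          class_props,
                          class_liability_h2 = 0.7,
                          sex_liability_shift = 0.15,
                          indicator_params,
                          outcome_params = list(),
                          covariate_effects = NULL,
                          missing_rates = NULL,
                          outcome_pair_prob = 1,
                          outcome_both_prob = 1,
                          pds_class_cor = 0.25,
                          seed = 1L) {
  n_pairs <- check_count(n_pairs, "n_pairs", min = 2L)
  if (length(zygosity_probs) != 3L) abort("zygosity_probs must have length 3")
  zygosity_probs <- normalize_probs(zygosity_probs, "zygosity_probs")
  class_props <- normalize_probs(class_props, "class_props")
  K <- length(class_props)
  if (K < 1L) abort("need at least one class")
  if (!is_scalar_number(class_liability_h2) ||
      class_liability_h2 < 0 || class_liability_h2 > 1) {
    abort("class_liability_h2 must be in [0, 1]")
  }

  if (!is.list(indicator_params) || is.null(names(indicator_params))) {
    abort("indicator_params must be a named list")
  }
  indicator_params <- purrr::imap(indicator_params, function(p, nm) {
    if (identical(p$kind, "ordinal")) {
      pr <- as.matrix(p$probs)
      if (ncol(pr) != K) abort(sprintf("indicator '%s': probs needs %d columns", nm, K))
      p$probs <- apply(pr, 2L, normalize_probs,
                       what = sprintf("indicator '%s' category probabilities", nm))
      p
    } else if (identical(p$kind, "continuous")) {
      if (length(p$means) != K) abort(sprintf("indicator '%s': means needs length %d", nm, K))
      if (length(p$sds) == 1L) p$sds <- rep(p$sds, K)
      if (any(p$sds <= 0)) abort(sprintf("indicator '%s': sds must be > 0", nm))
      p
    } else {
      abort(sprintf("indicator '%s': kind must be 'ordinal' or 'continuous'", nm))
    }
  })

  outcome_params <- purrr::imap(outcome_params, function(p, nm) {
    p$resid_sd <- p$resid_sd %||% 1
    p$shared_a_frac <- p$shared_a_frac %||% 0
    if (length(p$class_means) != K) {
      abort(sprintf("outcome '%s': class_means needs length %d", nm, K))
    }
    if (abs(p$a2 + p$e2 - 1) > 1e-8) {
      abort(sprintf("outcome '%s': a2 + e2 must equal 1", nm))
    }
    if (p$a2 < 0 || p$e2 < 0) abort(sprintf("outcome '%s': a2, e2 must be >= 0", nm))
    if (p$shared_a_frac < 0 || p$shared_a_frac > 1) {
      abort(sprintf("outcome '%s': shared_a_frac must be in [0, 1]", nm))
    }
    if (p$resid_sd <= 0) abort(sprintf("outcome '%s': resid_sd must be > 0", nm))
    p
  })

  covariate_effects <- covariate_effects %||%
    purrr::map(outcome_params, ~ list(sex_female = 0, age = 0, pds = 0))
  covariate_effects <- purrr::map(covariate_effects, function(ce) {
    modifyList(list(sex_female = 0, age = 0, pds = 0), ce)
  })

  missing_rates <- missing_rates %||%
    list(base = setNames(rep(0, length(indicator_params)), names(indicator_params)),
         sex_coef = 0, age_coef = 0)
  missing_rates$sex_coef <- missing_rates$sex_coef %||% 0
  missing_rates$age_coef <- missing_rates$age_coef %||% 0
  mb <- missing_rates$base
  if (is.null(names(mb)) || !all(names(mb) %in% names(indicator_params))) {
    abort("missing_rates$base must be named after indicators")
  }
  if (any(mb < 0 | mb >= 1)) abort("missing rates must be in [0, 1)")

  structure(
    list(
      n_pairs = n_pairs, zygosity_probs = zygosity_probs,
      K = K, class_props = class_props,
      class_liability_h2 = class_liability_h2,
      sex_liability_shift = sex_liability_shift,
      indicator_params = indicator_params,
      outcome_params = outcome_params,
      covariate_effects = covariate_effects,
      missing_rates = missing_rates,
      outcome_pair_prob = outcome_pair_prob,
      outcome_both_prob = outcome_both_prob,
      pds_class_cor = pds_class_cor,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d pairs, %d classes, %d indicators, %d outcomes\n",
    x$n_pairs, x$K, length(x$indicator_params), length(x$outcome_params)
  ))
  cat("class proportions:", paste(sprintf("%.3f", x$class_props), collapse = " "), "\n")
  invisible(x)
}

# Five-class class-conditional indicator profiles used as the default
# generating model. Continuous BMI: class means in kg/m^2; within-class SDs
# follow a constant coefficient of variation (BMI dispersion grows with its
# level), calibrated so the mixture reproduces the overall SDs
# (2.6, 2.7, 3.0) given the class means and proportions. Ordinal: per-class
# category probabilities (columns C1..C5), renormalized to sum to 1.
default_indicator_profiles <- function() {
  om <- function(...) {
    m <- matrix(c(...), ncol = 5L)
    m
  }
  bmi <- function(means, cv) list(kind = "continuous", means = means,
                                  sds = cv * means)
  list(
    bmi12 = bmi(c(16.8, 15.2, 19.1, 22.7, 17.2), 0.0872),
    bmi14 = bmi(c(18.6, 16.7, 20.9, 24.8, 18.9), 0.0778),
    bmi17 = bmi(c(20.8, 18.8, 22.6, 27.1, 20.6), 0.0932),
    ltpa12 = list(kind = "ordinal", probs = om(
      0.29, 0.54, 0.17,
      0.45, 0.46, 0.09,
      0.35, 0.52, 0.14,
      0.44, 0.47, 0.10,
      0.44, 0.46, 0.11)),
    ltpa14 = list(kind = "ordinal", probs = om(
      0.08, 0.14, 0.52, 0.27,
      0.17, 0.20, 0.45, 0.18,
      0.14, 0.16, 0.51, 0.19,
      0.18, 0.23, 0.43, 0.17,
      0.27, 0.20, 0.40, 0.14)),
    ltpa17 = list(kind = "ordinal", probs = om(
      0.10, 0.15, 0.50, 0.26,
      0.19, 0.18, 0.45, 0.18,
      0.13, 0.15, 0.53, 0.20,
      0.27, 0.18, 0.44, 0.11,
      0.35, 0.19, 0.36, 0.10)),
    smoke14 = list(kind = "ordinal", probs = om(
      0.99, 0.01, 0.001, 0.001,
      0.98, 0.02, 0.01, 0.002,
      0.97, 0.02, 0.004, 0.002,
      0.83, 0.09, 0.04, 0.04,
      0.33, 0.29, 0.13, 0.25)),
    smoke17 = list(kind = "ordinal", probs = om(
      0.69, 0.12, 0.06, 0.13,
      0.73, 0.09, 0.04, 0.14,
      0.68, 0.12, 0.04, 0.17,
      0.50, 0.11, 0.05, 0.34,
      0.03, 0.15, 0.07, 0.74)),
    alc14 = list(kind = "ordinal", probs = om(
      0.88, 0.11, 0.01, 0.002,
      0.94, 0.05, 0.02, 0.002,
      0.84, 0.13, 0.03, 0.002,
      0.76, 0.18, 0.05, 0.005,
      0.23, 0.46, 0.27, 0.04)),
    alc17 = list(kind = "ordinal", probs = om(
      0.21, 0.48, 0.28, 0.03,
      0.33, 0.45, 0.18, 0.04,
      0.22, 0.46, 0.28, 0.03,
      0.23, 0.41, 0.29, 0.08,
      0.01, 0.26, 0.51, 0.22))
  )
}

# default outcome generating parameters: class means (C1 reference 0) in
# outcome units, AE residual shares, residual SD derived from the overall
# outcome SD net of between-class variance, and the a-priori calibrated
# fraction of outcome genetic variance shared with the class liability.
default_outcome_profiles <- function() {
  list(
    AA_Pheno = list(class_means = c(0, -0.55, 1.04, 1.97, -0.36),
                    a2 = 0.65, e2 = 0.35, resid_sd = 5.19, shared_a_frac = 0.65),
    AA_Grim = list(class_means = c(0, -0.57, 0.97, 1.83, 2.70),
                   a2 = 0.73, e2 = 0.27, resid_sd = 3.04, shared_a_frac = 0.06),
    DunedinPoAm = list(class_means = c(0, -0.01, 0.00, 0.05, 0.04),
                       a2 = 0.62, e2 = 0.38, resid_sd = 0.0669, shared_a_frac = 0.20),
    DunedinPACE = list(class_means = c(0, -0.03, 0.02, 0.07, 0.03),
                       a2 = 0.68, e2 = 0.32, resid_sd = 0.0959, shared_a_frac = 0.22)
  )
}

#' Default five-class lifestyle cohort configuration
#'
#' The ten-indicator, five-class generating model used throughout the
#' package: class proportions (0.320, 0.199, 0.228, 0.095, 0.159) for the
#' healthiest-lifestyle, low-normal-BMI, high-normal-BMI, high-BMI and
#' unhealthiest-lifestyle classes, class-conditional indicator profiles
#' matching a large adolescent twin cohort, AE-structured epigenetic aging
#' outcomes (GrimAge/PhenoAge age acceleration and two pace-of-aging
#' measures), and item missingness rising from ~2-4% at age 12 to ~18% at
#' age 17.
#'
#' @param n_pairs Number of twin pairs (default 2557, i.e. 5114 individuals).
#' @param outcome_pair_prob,outcome_both_prob Subsampling of the
#'   biological-aging outcomes; the defaults yield roughly 800 measured
#'   individuals of whom about 730 form complete pairs.
#' @param with_missing Apply the default item missingness (set `FALSE` for
#'   fully observed indicators).
#' @param seed Default seed passed on to [generate_cohort()].
#' @return A [cohort_config()] object.
#' @export
#' @examples
#' cfg <- default_lifestyle_config(n_pairs = 200, seed = 7)
#' cohort <- generate_cohort(cfg)
#' dplyr::count(cohort, zygosity)
default_lifestyle_config <- function(n_pairs = 2557,
                                     outcome_pair_prob = 0.18,
                                     outcome_both_prob = 0.795,
                                     with_missing = TRUE,
                                     seed = 1L) {
  miss <- if (with_missing) {
    list(base = c(bmi12 = 0.039, bmi14 = 0.125, bmi17 = 0.187,
                  ltpa12 = 0.015, ltpa14 = 0.102, ltpa17 = 0.177,
                  smoke14 = 0.106, smoke17 = 0.181,
                  alc14 = 0.107, alc17 = 0.175),
         sex_coef = 0.2, age_coef = 0.05)
  } else {
    NULL
  }
  co <- purrr::map(default_outcome_profiles(), function(p) {
    list(sex_female = 0.15 * p$resid_sd, age = 0, pds = 0.1 * p$resid_sd)
  })
  cohort_config(
    n_pairs = n_pairs,
    class_props = c(0.320, 0.199, 0.228, 0.095, 0.159),
    indicator_params = default_indicator_profiles(),
    outcome_params = default_outcome_profiles(),
    covariate_effects = co,
    missing_rates = miss,
    outcome_pair_prob = outcome_pair_prob,
    outcome_both_prob = outcome_both_prob,
    seed = seed
  )
}
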