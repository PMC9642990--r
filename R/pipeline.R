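#' Read a cohort table
#'
#' Reads a TSV/CSV cohort file with the documented schema (`family_id`,
#' `member_index`, `zygosity`, `sex`, `age`, `pds`, indicator and outcome
#' columns). Empty cells and `"NA"` are missing. Ordinal indicator codes
#' are validated against the supplied specs and duplicate
#' `(family_id, member_index)` rows are rejected.
#'
#' @param path File path (`.tsv` or `.csv` by extension).
#' @param specs Indicator specs used for validation (default
#'   [lifestyle_indicators()]); pass `NULL` to skip indicator validation.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, specs = lifestyle_indicators()) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  dat <- reader(path, na = c("", "NA"), show_col_types = FALSE)
  if (anyDuplicated(dat[c("family_id", "member_index")])) {
    abort("duplicate (family_id, member_index) rows")
  }
  if (!is.null(specs)) {
    specs <- specs[specs$name %in% names(dat), ]
    for (j in which(specs$kind == "ordinal")) {
      v <- dat[[specs$name[j]]]
      bad <- !is.na(v) & (v < 1 | v > specs$n_categories[j] | v != round(v))
      if (any(bad)) {
        abort(sprintf("column '%s': invalid ordinal code in row %d",
                      specs$name[j], which(bad)[1]))
      }
    }
  }
  dat
}

#' Write a cohort table (and optional truth sidecar)
#'
#' Writes the cohort as TSV with `NA` for missing values. Hidden-truth
#' columns (names starting with `.`) are never written to the primary
#' file; when `truth_path` is given they go to a JSON sidecar instead.
#'
#' @param cohort Cohort tibble, e.g. from [generate_cohort()].
#' @param path Output TSV path.
#' @param truth_path Optional JSON path for the hidden-truth columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  hidden <- grep("^\\.", names(cohort), value = TRUE)
  readr::write_tsv(cohort[setdiff(names(cohort), hidden)], path, na = "NA")
  if (!is.null(truth_path)) {
    truth <- c(
      list(family_id = cohort$family_id, member_index = cohort$member_index),
      as.list(cohort[hidden])
    )
    jsonlite::write_json(truth, truth_path, digits = NA)
  }
  invisible(path)
}

#' Run the full analysis pipeline on a twin cohort
#'
#' One-command reproduction of the analytic chain: class enumeration over
#' `k_range` (information criteria, VLMR/LMR, AvePP), the chosen-K latent
#' class fit, BCH distal-outcome models for every outcome (covariate
#' adjusted, optionally with an extra adulthood-BMI-style covariate as a
#' second model), twin ICCs, the biometric model sequence on
#' covariate-adjusted outcomes, and the shared-variance decomposition.
#' All randomness flows from `seed`; rerunning with the same inputs and
#' seed reproduces every number.
#'
#' @param cohort Cohort tibble (e.g. [generate_cohort()] or
#'   [read_cohort()]).
#' @param specs Indicator specs (default [lifestyle_indicators()]).
#' @param outcomes Character vector of outcome columns; defaults to the
#'   standard epigenetic aging measures present in the cohort.
#' @param k Number of classes for the final model; `NULL` picks the K in
#'   `k_range` preferred by aBIC among solutions with min AvePP >= 0.7.
#' @param k_range Range for class enumeration (default `1:6`).
#' @param covariates Covariate columns for the distal models; the default
#'   builds female sex, standardized age and raw PDS from the cohort.
#' @param biometric_models Model sequence (default ACE, ADE, AE, CE, E).
#' @param decomposition_model Family used for total and residual biometric
#'   fits in the decomposition (default AE).
#' @param weight_type `"bch"` (default) or `"posterior"` rows for the
#'   residual scores.
#' @param n_starts,seed Passed to the LCA fits.
#' @param outlier_k SD multiplier for outcome outlier screening (default 5).
#' @return A list of class `pipeline_result`: `selection`, `lca`,
#'   `distal` (tibble with fit list-column per outcome), `icc`,
#'   `biometrics`, `decomposition`, `settings`.
#' @export
run_pipeline <- function(cohort,
                         specs = lifestyle_indicators(),
                         outcomes = NULL,
                         k = NULL, k_range = 1:6,
                         covariates = NULL,
                         biometric_models = c("ACE", "ADE", "AE", "CE", "E"),
                         decomposition_model = "AE",
                         weight_type = c("bch", "posterior"),
                         n_starts = 20, seed = 1L,
                         outlier_k = 5) {
  weight_type <- match.arg(weight_type)
  outcomes <- outcomes %||% intersect(
    c("AA_Horvath", "AA_Hannum", "AA_Pheno", "AA_Grim",
      "DunedinPoAm", "DunedinPACE"),
    names(cohort)
  )
  if (!length(outcomes)) abort("no outcome columns found")

  # covariate columns: female sex, within-sample standardized age, raw PDS
  cohort$sex_female <- as.numeric(cohort$sex == "female")
  cohort$age_std <- as.vector(scale(cohort$age))
  covariates <- covariates %||% c("sex_female", "age_std", "pds")

  # outcome preprocessing: single-pass >k SD outlier screen
  screen_counts <- integer(0)
  for (oc in outcomes) {
    v <- screen_outliers(cohort[[oc]], k = outlier_k)
    screen_counts[oc] <- attr(v, "n_recoded")
    cohort[[oc]] <- as.vector(v)
  }

  # 1. class enumeration + measurement model
  selection <- lca_select(cohort, specs, k_range = k_range,
                          n_starts = n_starts, seed = seed)
  if (is.null(k)) {
    cand <- selection[selection$min_avepp >= 0.7 & selection$converged, ]
    k <- if (nrow(cand)) cand$k[which.min(cand$aBIC)] else
      selection$k[which.min(selection$aBIC)]
  }
  lca <- selection$fit[[match(k, selection$k)]]

  # 2. BCH weights from the measurement model
  post <- class_posterior(lca, cohort)
  modal <- max.col(post, ties.method = "first")
  D <- classification_error_matrix(post, modal)
  bw <- bch_weights(D, modal)
  weights <- if (weight_type == "bch") bw$weights else post

  # 3. distal-outcome models (M1: covariates; class means without
  # covariates feed the decomposition)
  distal <- purrr::map_dfr(outcomes, function(oc) {
    f1 <- fit_distal(cohort, oc, weights, covariates = covariates)
    tibble::tibble(outcome = oc, model = "M1",
                   wald_p = f1$wald$p.value, fit = list(f1))
  })

  # 4. twin ICCs per outcome
  icc <- purrr::map_dfr(outcomes, function(oc) {
    dplyr::mutate(twin_icc(cohort, oc), outcome = oc, .before = 1)
  })

  # 5. biometric model sequence on covariate-adjusted outcomes
  biometrics <- purrr::map_dfr(outcomes, function(oc) {
    adj <- cohort
    adj[[oc]] <- adjust_outcome(cohort[[oc]], cohort[covariates])
    tp <- twin_pairs(adj, oc)
    fits <- purrr::map(biometric_models, ~ fit_biometric(tp, .x))
    dplyr::mutate(compare_models(fits, tp), outcome = oc, .before = 1)
  })

  # 6. shared-variance decomposition
  decomposition <- purrr::map_dfr(outcomes, function(oc) {
    adj <- cohort
    adj[[oc]] <- adjust_outcome(cohort[[oc]], cohort[covariates])
    f0 <- fit_distal(adj, oc, weights, covariates = character())
    adj$.resid <- residual_scores(adj[[oc]], weights, f0$class_means)
    tot <- fit_biometric(twin_pairs(adj, oc), decomposition_model)
    res <- fit_biometric(twin_pairs(adj, ".resid"), decomposition_model)
    dplyr::mutate(decompose_shared(tot, res), outcome = oc, .before = 1)
  })

  structure(
    list(
      selection = dplyr::select(selection, -"fit"),
      lca = lca, classification_error = D, bch = bw,
      distal = distal, icc = icc,
      biometrics = biometrics, decomposition = decomposition,
      settings = list(k = k, k_range = k_range, covariates = covariates,
                      weight_type = weight_type, n_starts = n_starts,
                      seed = seed, outlier_recoded = screen_counts)
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> K = %d; outcomes: %s\n",
              x$settings$k, paste(x$distal$outcome, collapse = ", ")))
  print(x$decomposition[c("outcome", "shared_genetic", "shared_environment",
                          "unique_genetic", "unique_environment")])
  invisible(x)
}
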