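# shared fixtures: all built in code at test time

# compact two-class twin configuration with moderately separated
# indicators (classification entropy around 0.8) and one AE outcome
two_class_config <- function(shared_a_frac = 0.5,
                             class_mean_gap = 0.8,
                             h2 = 0.7,
                             n_pairs = 365,
                             class_props = c(0.6, 0.4),
                             a2 = 0.7, e2 = 1 - a2,
                             seed = 1L) {
  om <- function(...) matrix(c(...), ncol = 2)
  cohort_config(
    n_pairs = n_pairs,
    zygosity_probs = c(0.42, 0.29, 0.29), # ~154 MZ / 211 DZ complete pairs
    class_props = class_props,
    class_liability_h2 = h2,
    sex_liability_shift = 0,
    pds_class_cor = 0,
    indicator_params = list(
      x1 = list(kind = "ordinal", probs = om(0.70, 0.20, 0.10, 0.10, 0.30, 0.60)),
      x2 = list(kind = "ordinal", probs = om(0.70, 0.20, 0.10, 0.10, 0.30, 0.60)),
      x3 = list(kind = "ordinal", probs = om(0.60, 0.30, 0.10, 0.15, 0.35, 0.50)),
      x4 = list(kind = "ordinal", probs = om(0.60, 0.30, 0.10, 0.15, 0.35, 0.50)),
      z1 = list(kind = "continuous", means = c(0, 1.2), sds = c(1, 1))
    ),
    outcome_params = list(
      bioage = list(class_means = c(0, class_mean_gap),
                    a2 = a2, e2 = e2, shared_a_frac = shared_a_frac)
    ),
    seed = seed
  )
}

two_class_specs <- function() {
  dplyr::bind_rows(
    indicator_spec("x1", "ordinal", 3),
    indicator_spec("x2", "ordinal", 3),
    indicator_spec("x3", "ordinal", 3),
    indicator_spec("x4", "ordinal", 3),
    indicator_spec("z1", "continuous")
  )
}

# one pass of the estimation chain from a generated cohort to the
# shared-variance decomposition (no covariates)
run_shared_variance_chain <- function(cohort, specs, k = 2, n_starts = 5,
                                      seed = 1L) {
  fit <- fit_lca(cohort, specs, k = k, n_starts = n_starts, seed = seed)
  post <- class_posterior(fit, cohort)
  modal <- max.col(post, ties.method = "first")
  bw <- bch_weights(classification_error_matrix(post, modal), modal)
  d0 <- fit_distal(cohort, "bioage", bw$weights)
  cohort$.res <- residual_scores(cohort$bioage, bw$weights, d0$class_means)
  tot <- fit_biometric(twin_pairs(cohort, "bioage"), "AE")
  res <- fit_biometric(twin_pairs(cohort, ".res"), "AE")
  suppressWarnings(decompose_shared(tot, res))
}
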