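#' Residual scores of an outcome net of the latent class structure
#'
#' `r_i = y_i - sum_k w_ik mu_k`, the outcome minus its class-structure
#' expectation under the individual's BCH weight row (or, optionally,
#' posterior row). Missing outcomes give missing residuals.
#'
#' @param outcome Numeric outcome vector (pre-adjusted for covariates when
#'   mirroring the published workflow).
#' @param weights `n x K` matrix of BCH weight rows (default choice) or
#'   posterior rows.
#' @param class_means K-vector of class means from a no-covariate distal
#'   fit.
#' @return Residual vector, same length as `outcome`.
#' @export
residual_scores <- function(outcome, weights, class_means) {
  W <- as.matrix(weights)
  if (nrow(W) != length(outcome)) abort("weights not aligned with outcome")
  if (ncol(W) != length(class_means)) abort("class_means has the wrong length")
  outcome - as.vector(W %*% class_means)
}

#' Bundle raw variance components for the shared-variance decomposition
#'
#' A lightweight constructor accepted by [decompose_shared()] alongside
#' full [fit_biometric()] objects — useful for worked examples where the
#' components are known rather than estimated.
#'
#' @param a2,e2 Raw (unstandardized) additive-genetic and nonshared
#'   environmental variance components.
#' @param c2 Optional shared-environment component (ACE-style).
#' @param model Model label.
#' @return A minimal `biometric_fit`-compatible list.
#' @export
biometric_components <- function(a2, e2, c2 = NULL, model = if (is.null(c2)) "AE" else "ACE") {
  comps <- if (is.null(c2)) c(a2 = a2, e2 = e2) else c(a2 = a2, c2 = c2, e2 = e2)
  structure(
    list(model = model, components = comps, total = sum(comps)),
    class = "biometric_fit"
  )
}

#' Shared genetic and environmental variance with the latent classes
#'
#' Combines the biometric fit of the total outcome with the biometric fit
#' of its class-structure residuals into the decomposition of total
#' variance: `shared_genetic = (a2_tot - a2_res) / var_tot`,
#' `shared_environment = (e2_tot - e2_res) / var_tot`, with the unique
#' proportions `a2_res / var_tot` and `e2_res / var_tot`. `var_tot` is the
#' total-fit model-implied variance, so the four proportions sum to 1
#' exactly. Sampling can make a residual component exceed its total
#' counterpart; negative shared estimates are reported as-is with a warning
#' unless `clamp_zero = TRUE`.
#'
#' @param total_fit,resid_fit [fit_biometric()] (or
#'   [biometric_components()]) objects of the same model family, fitted to
#'   the outcome and to its [residual_scores()] on the same individuals.
#' @param clamp_zero Clamp negative shared proportions to zero
#'   (presentation style); default `FALSE` to keep the estimator unbiased.
#' @return A one-row tibble matching [true_shared_proportions()] (columns
#'   `var_tot`, `var_model`, `var_res`, `a2_tot`, `e2_tot`, `a2_res`,
#'   `e2_res`, `shared_genetic`, `shared_environment`, `unique_genetic`,
#'   `unique_environment`).
#' @export
#' @examples
#' # printed-style worked example: total model share 16.8%, genetic 13.1%
#' tot <- biometric_components(a2 = 0.600, e2 = 0.400)
#' res <- biometric_components(a2 = 0.469, e2 = 0.363)
#' decompose_shared(tot, res)$shared_environment # 0.037
decompose_shared <- function(total_fit, resid_fit, clamp_zero = FALSE) {
  stopifnot(inherits(total_fit, "biometric_fit"),
            inherits(resid_fit, "biometric_fit"))
  if (!identical(total_fit$model, resid_fit$model)) {
    abort("total and residual fits must use the same model family")
  }
  ct <- total_fit$components
  cr <- resid_fit$components
  var_tot <- total_fit$total
  var_res <- resid_fit$total
  a_tot <- if ("a2" %in% names(ct)) ct[["a2"]] else 0
  a_res <- if ("a2" %in% names(cr)) cr[["a2"]] else 0
  # environment pooled as c2 + e2 when an ACE family is used
  e_tot <- sum(ct[setdiff(names(ct), "a2")])
  e_res <- sum(cr[setdiff(names(cr), "a2")])

  sg <- (a_tot - a_res) / var_tot
  se_ <- (e_tot - e_res) / var_tot
  if (!clamp_zero && (sg < 0 || se_ < 0)) {
    warn("negative shared variance estimate (sampling variability); reported as-is")
  }
  if (clamp_zero) {
    sg <- max(sg, 0)
    se_ <- max(se_, 0)
  }
  tibble::tibble(
    var_tot = var_tot,
    var_model = var_tot - var_res,
    var_res = var_res,
    a2_tot = a_tot, e2_tot = e_tot,
    a2_res = a_res, e2_res = e_res,
    shared_genetic = sg,
    shared_environment = se_,
    unique_genetic = a_res / var_tot,
    unique_environment = e_res / var_tot
  )
}
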