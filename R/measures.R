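#' Methylation beta value from probe intensities
#'
#' `beta = M / (M + U + offset)`, the standard offset-regularised ratio of
#' methylated to total probe intensity.
#'
#' @param M,U Methylated and unmethylated intensities (non-negative,
#'   vectorised).
#' @param offset Regularising constant added to the denominator (default 100).
#' @return Beta values in `[0, 1)`.
#' @export
#' @examples
#' beta_value(900, 0) # 0.9
beta_value <- function(M, U, offset = 100) {
  if (any(!is.finite(M)) || any(!is.finite(U))) abort("intensities must be finite")
  if (any(M < 0) || any(U < 0)) abort("intensities must be non-negative")
  M / (M + U + offset)
}

#' Epigenetic age acceleration
#'
#' Residuals from the ordinary least-squares regression of epigenetic age on
#' chronological age. Positive values mean biologically older than expected
#' for one's chronological age. Missing values in either input propagate as
#' `NA` residuals; the regression is fit on the complete cases.
#'
#' @param epigenetic_age,chronological_age Numeric vectors of equal length
#'   (at least 3 complete cases; chronological age must vary).
#' @return Residual vector (years), same length as the input.
#' @export
age_acceleration <- function(epigenetic_age, chronological_age) {
  if (length(epigenetic_age) != length(chronological_age)) {
    abort("age vectors must have equal length")
  }
  ok <- complete.cases(epigenetic_age, chronological_age)
  if (sum(ok) < 3) abort("need at least 3 complete cases")
  if (sd(chronological_age[ok]) == 0) {
    abort("chronological age is constant; regression is singular")
  }
  out <- rep(NA_real_, length(epigenetic_age))
  fit <- lm(epigenetic_age[ok] ~ chronological_age[ok])
  out[ok] <- resid(fit)
  out
}

#' Recode extreme values as missing
#'
#' Single-pass outlier screen: values more than `k` standard deviations from
#' the mean (both computed once, over the non-missing values) are recoded as
#' `NA`. A zero standard deviation yields no recodes.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @param k SD multiplier (default 5).
#' @return The recoded vector, with attribute `n_recoded` giving the number
#'   of values set to missing.
#' @export
#' @examples
#' x <- screen_outliers(c(rnorm(50), 25))
#' attr(x, "n_recoded")
screen_outliers <- function(values, k = 5) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) abort("need at least 2 non-missing values")
  m <- mean(obs); s <- sd(obs)
  out <- values
  bad <- !is.na(values) & s > 0 & abs(values - m) > k * s
  out[bad] <- NA
  attr(out, "n_recoded") <- sum(bad)
  out
}

#' Pubertal development score
#'
#' Mean of the five pubertal-development items. Items use codes 1 (not
#' begun), 2 (barely started), 3 (definitely underway); the fifth item
#' (menarche or an equivalent dichotomous milestone) takes codes 1 or 3.
#' Higher scores indicate more advanced pubertal development.
#'
#' @param items A length-5 vector, or a matrix / data frame with 5 columns
#'   (one row per respondent).
#' @return The mean score(s) in `[1, 3]`.
#' @export
#' @examples
#' pds_score(c(1, 2, 3, 3, 1)) # 2
pds_score <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1L) else as.matrix(items)
  if (ncol(m) != 5L) abort("exactly five items are required")
  if (any(!m[, 1:4] %in% c(1, 2, 3), na.rm = TRUE)) {
    abort("items 1-4 must use codes 1, 2, 3")
  }
  if (any(!m[, 5] %in% c(1, 3), na.rm = TRUE)) {
    abort("the dichotomous fifth item must use codes 1 or 3")
  }
  out <- rowMeans(m)
  if (is.null(dim(items))) out[[1]] else out
}

#' Adjust an outcome for covariates
#'
#' OLS residuals of `outcome` on an intercept plus the given covariate
#' columns. Rows with any missing covariate or outcome get `NA` residuals
#' (listwise within the regression). Residuals have mean zero and are
#' orthogonal to every covariate.
#'
#' @param outcome Numeric vector.
#' @param covariates Data frame or matrix of covariate columns (numeric;
#'   recode factors first). Must be full rank after adding an intercept.
#' @return Residual vector, same length as `outcome`.
#' @export
adjust_outcome <- function(outcome, covariates) {
  X <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(X)) abort("covariates must be numeric")
  if (nrow(X) != length(outcome)) abort("outcome and covariates differ in length")
  ok <- complete.cases(outcome, X)
  Xc <- cbind(1, X[ok, , drop = FALSE])
  if (qr(Xc)$rank < ncol(Xc)) abort("rank-deficient covariate design")
  out <- rep(NA_real_, length(outcome))
  fit <- lm.fit(Xc, outcome[ok])
  out[ok] <- fit$residuals
  out
}

#' Twin intraclass correlations by zygosity
#'
#' ICC of an outcome within MZ and within DZ twin pairs, computed on
#' complete pairs. The default point estimate is the pairwise (double-entry)
#' Pearson correlation; `method = "anova"` gives the one-way random-effects
#' ANOVA ICC. Confidence intervals use the Fisher z transform with the
#' number of pairs as the effective sample size.
#'
#' @param data Cohort tibble with `family_id`, `zygosity` and the outcome
#'   column; `zygosity` values starting with `"DZ"` are pooled.
#' @param outcome Outcome column name.
#' @param method `"pairwise"` (default) or `"anova"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per zygosity: `zygosity`, `n_pairs`,
#'   `icc`, `conf_low`, `conf_high`.
#' @export
twin_icc <- function(data, outcome, method = c("pairwise", "anova"),
                     conf_level = 0.95) {
  method <- match.arg(method)
  pairs <- twin_pairs(data, outcome)
  z <- qnorm(1 - (1 - conf_level) / 2)
  one <- function(m, label) {
    m <- m[complete.cases(m), , drop = FALSE]
    n <- nrow(m)
    if (n < 3) abort(sprintf("fewer than 3 complete %s pairs", label))
    if (method == "pairwise") {
      icc <- cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
    } else {
      gm <- mean(m)
      msb <- 2 * sum((rowMeans(m) - gm)^2) / (n - 1)
      msw <- sum((m[, 1] - m[, 2])^2 / 2) / n
      icc <- (msb - msw) / (msb + msw)
    }
    icc <- max(min(icc, 1), -1)
    fz <- atanh(max(min(icc, 1 - 1e-12), -1 + 1e-12))
    se <- 1 / sqrt(n - 3)
    tibble::tibble(
      zygosity = label, n_pairs = n, icc = icc,
      conf_low = tanh(fz - z * se), conf_high = tanh(fz + z * se)
    )
  }
  dplyr::bind_rows(one(pairs$mz, "MZ"), one(pairs$dz, "DZ"))
}
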