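#' Assemble zygosity pair matrices from a cohort
#'
#' Pivots per-individual rows into per-family pairs of outcome values, one
#' matrix per zygosity. Opposite-sex DZ pairs are pooled with same-sex DZ
#' pairs. Pairs with both members missing are dropped; pairs with one
#' observed member are kept (they contribute their univariate marginal
#' under FIML).
#'
#' @param data Cohort tibble with `family_id`, `member_index`, `zygosity`
#'   and the outcome column.
#' @param outcome Outcome column name.
#' @return A list of class `zygosity_pairs`: `mz` and `dz` (each an
#'   `n_pairs x 2` matrix, `NA` allowed) and `outcome`.
#' @export
twin_pairs <- function(data, outcome) {
  if (is.null(data[[outcome]])) abort(sprintf("no column '%s'", outcome))
  wide <- data |>
    dplyr::select(dplyr::all_of(c("family_id", "member_index", "zygosity", outcome))) |>
    tidyr::pivot_wider(names_from = "member_index",
                       values_from = dplyr::all_of(outcome),
                       names_prefix = "y")
  if (!all(c("y1", "y2") %in% names(wide))) {
    abort("each family needs member_index values 1 and 2")
  }
  keep <- !(is.na(wide$y1) & is.na(wide$y2))
  wide <- wide[keep, ]
  is_mz <- wide$zygosity == "MZ"
  structure(
    list(mz = cbind(wide$y1[is_mz], wide$y2[is_mz]),
         dz = cbind(wide$y1[!is_mz], wide$y2[!is_mz]),
         outcome = outcome),
    class = "zygosity_pairs"
  )
}

# FIML log-likelihood of one zygosity group under an exchangeable
# bivariate normal with mean m, variance v, within-pair covariance c
pair_group_loglik <- function(P, m, v, c) {
  if (v <= 0 || abs(c) >= v) return(-Inf)
  ll <- 0
  cc <- complete.cases(P)
  if (any(cc)) {
    d1 <- P[cc, 1] - m; d2 <- P[cc, 2] - m
    det2 <- v^2 - c^2
    q <- (v * (sum(d1^2) + sum(d2^2)) - 2 * c * sum(d1 * d2)) / det2
    ll <- ll - sum(cc) * log(2 * pi) - sum(cc) / 2 * log(det2) - q / 2
  }
  singles <- c(P[!cc, 1], P[!cc, 2])
  singles <- singles[!is.na(singles)]
  if (length(singles)) {
    ll <- ll + sum(dnorm(singles, m, sqrt(v), log = TRUE))
  }
  ll
}

# map model parameters to implied (variance, covMZ, covDZ)
biometric_structure <- function(model, comps) {
  switch(model,
    ACE = list(v = sum(comps), c_mz = comps[1] + comps[2],
               c_dz = 0.5 * comps[1] + comps[2],
               names = c("a2", "c2", "e2")),
    ADE = list(v = sum(comps), c_mz = comps[1] + comps[2],
               c_dz = 0.5 * comps[1] + 0.25 * comps[2],
               names = c("a2", "d2", "e2")),
    AE = list(v = sum(comps), c_mz = comps[1], c_dz = 0.5 * comps[1],
              names = c("a2", "e2")),
    CE = list(v = sum(comps), c_mz = comps[1], c_dz = comps[1],
              names = c("c2", "e2")),
    E = list(v = comps[1], c_mz = 0, c_dz = 0, names = "e2"),
    abort(sprintf("unknown model '%s'", model))
  )
}

biometric_loglik <- function(th, model, pairs) {
  m <- th[1]
  st <- biometric_structure(model, th[-1])
  pair_group_loglik(pairs$mz, m, st$v, st$c_mz) +
    pair_group_loglik(pairs$dz, m, st$v, st$c_dz)
}

#' Fit a univariate twin variance-component model
#'
#' Maximum-likelihood ACE / ADE / AE / CE / E models on MZ and DZ pair
#' data. The likelihood is the two-group exchangeable bivariate normal with
#' a common grand mean; expected within-pair covariances are
#' `a2 + c2` (MZ) and `a2/2 + c2` (DZ) for ACE, `a2 + d2` and
#' `a2/2 + d2/4` for ADE. Incomplete pairs contribute their univariate
#' marginal (FIML). Variance components are unconstrained (negative
#' estimates allowed); standardized shares and their delta-method
#' confidence intervals are computed from the unconstrained solution. The
#' DE model is not offered (dominance without additive effects is
#' implausible).
#'
#' @param pairs A [twin_pairs()] object, or a cohort tibble (then give
#'   `outcome`).
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param outcome Outcome column when `pairs` is a cohort tibble.
#' @param n_starts Jittered optimizer starts (default 5).
#' @param conf_level Confidence level for the share CIs.
#' @return An object of class `biometric_fit`: `model`, `mean`,
#'   `components` (named raw variance components), `shares` (standardized,
#'   with `conf_low`/`conf_high`), `total`, `total_ci`, `loglik`,
#'   `n_params`, `n_pairs`, `n_individuals`, `convergence`, `vcov`.
#'   Supports [tidy()] and [glance()].
#' @export
#' @examples
#' tp <- simulate_twin_pairs(200, 250, a2 = 0.7, e2 = 0.3, seed = 1)
#' fit_biometric(tp, "AE")
fit_biometric <- function(pairs, model = c("ACE", "ADE", "AE", "CE", "E"),
                          outcome = NULL, n_starts = 5, conf_level = 0.95) {
  model <- match.arg(model)
  if (is.data.frame(pairs)) {
    if (is.null(outcome)) abort("give `outcome` when passing a cohort tibble")
    pairs <- twin_pairs(pairs, outcome)
  }
  stopifnot(inherits(pairs, "zygosity_pairs"))
  n_mz <- nrow(pairs$mz); n_dz <- nrow(pairs$dz)
  if (n_mz < 10 || n_dz < 10) abort("need at least 10 pairs per zygosity")

  allv <- c(pairs$mz, pairs$dz)
  v0 <- var(allv, na.rm = TRUE)
  m0 <- mean(allv, na.rm = TRUE)
  ncomp <- length(biometric_structure(model, rep(v0, 3))$names)

  nll <- function(th) {
    ll <- biometric_loglik(th, model, pairs)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  # deterministic start spread over component splits (no RNG use: callers
  # may be mid-simulation)
  splits <- list(rep(1, ncomp), seq_len(ncomp), rev(seq_len(ncomp)),
                 c(3, rep(1, ncomp - 1)), c(rep(1, ncomp - 1), 3))
  for (s in seq_len(min(n_starts, length(splits)))) {
    w <- splits[[s]][seq_len(ncomp)]
    st <- c(m0, v0 * w / sum(w))
    fit <- optim(st, nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))
    fit <- optim(fit$par, nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  th <- best$par
  comps <- th[-1]
  st <- biometric_structure(model, comps)
  names(comps) <- st$names
  total <- st$v
  shares <- comps / total

  # delta-method CIs on shares and total from the observed information
  H <- try(optimHess(th, nll), silent = TRUE)
  se_shares <- rep(NA_real_, length(comps))
  se_total <- NA_real_
  hess_ok <- FALSE
  if (!inherits(H, "try-error")) {
    Vth <- try(solve(H), silent = TRUE)
    if (!inherits(Vth, "try-error") && all(diag(Vth) > 0)) {
      hess_ok <- TRUE
      Vc <- Vth[-1, -1, drop = FALSE]
      grad_share <- function(i) {
        g <- -comps[i] / total^2 * rep(1, length(comps))
        g[i] <- g[i] + 1 / total
        g
      }
      se_shares <- vapply(seq_along(comps), function(i) {
        g <- grad_share(i)
        sqrt(max(t(g) %*% Vc %*% g, 0))
      }, numeric(1))
      se_total <- sqrt(max(sum(Vc), 0))
    }
  }
  if (!hess_ok) warn("observed information not positive definite; CIs are NA")
  z <- qnorm(1 - (1 - conf_level) / 2)

  structure(
    list(
      model = model, mean = th[1],
      components = comps,
      shares = tibble::tibble(
        component = names(comps), estimate = unname(shares),
        conf_low = if (hess_ok) unname(shares - z * se_shares) else NA_real_,
        conf_high = if (hess_ok) unname(shares + z * se_shares) else NA_real_
      ),
      total = total,
      total_ci = c(total - z * se_total, total + z * se_total),
      loglik = -best$value, n_params = length(th),
      n_pairs = c(MZ = n_mz, DZ = n_dz),
      n_individuals = sum(!is.na(allv)),
      convergence = best$convergence == 0,
      outcome = pairs$outcome %||% NA_character_
    ),
    class = "biometric_fit"
  )
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("<biometric_fit> %s model, logLik = %.2f (MZ %d / DZ %d pairs)\n",
              x$model, x$loglik, x$n_pairs[["MZ"]], x$n_pairs[["DZ"]]))
  sh <- x$shares
  cat(paste(sprintf("%s = %.3f", sh$component, sh$estimate), collapse = ", "),
      sprintf("; total = %.3f\n", x$total))
  invisible(x)
}

# saturated model: per group free mean, variance and covariance (FIML)
saturated_loglik <- function(pairs) {
  one <- function(P) {
    f <- function(th) {
      ll <- pair_group_loglik(P, th[1], exp(th[2]), tanh(th[3]) * exp(th[2]))
      if (!is.finite(ll)) 1e10 else -ll
    }
    m0 <- mean(P, na.rm = TRUE)
    v0 <- var(as.vector(P), na.rm = TRUE)
    cc <- P[complete.cases(P), , drop = FALSE]
    r0 <- if (nrow(cc) > 2) cor(cc[, 1], cc[, 2]) else 0
    fit <- optim(c(m0, log(v0), atanh(min(max(r0, -0.99), 0.99))), f,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))
    list(loglik = -fit$value,
         mean = fit$par[1], v = exp(fit$par[2]),
         c = tanh(fit$par[3]) * exp(fit$par[2]))
  }
  mz <- one(pairs$mz); dz <- one(pairs$dz)
  # twins are exchangeable: 3 moments per zygosity group
  list(loglik = mz$loglik + dz$loglik, mz = mz, dz = dz, n_params = 6L)
}

# independence baseline: one common mean and variance, zero covariance
baseline_loglik <- function(pairs) {
  x <- c(pairs$mz, pairs$dz)
  x <- x[!is.na(x)]
  m <- mean(x); v <- mean((x - m)^2)
  list(loglik = sum(dnorm(x, m, sqrt(v), log = TRUE)), n_params = 2L)
}

#' Goodness-of-fit indices for a twin model
#'
#' Normal-theory ML chi-square against the two-group saturated model
#' (free mean, variance and within-pair covariance per zygosity — twins are
#' exchangeable, so six observed moments),
#' CFI and TLI against the independence baseline (common mean and variance,
#' zero within-pair covariance), multigroup RMSEA, SRMR over the
#' standardized moment residuals, and BIC on the number of individuals.
#' Conventional adequacy thresholds: non-significant chi-square, CFI/TLI
#' near 0.95, RMSEA below 0.06, SRMR below 0.08.
#'
#' @param fit A [fit_biometric()] object.
#' @param pairs The [twin_pairs()] data the model was fitted to.
#' @return A one-row tibble: `chisq`, `df`, `p.value`, `CFI`, `TLI`,
#'   `RMSEA`, `SRMR`, `BIC`.
#' @export
fit_indices <- function(fit, pairs) {
  stopifnot(inherits(fit, "biometric_fit"), inherits(pairs, "zygosity_pairs"))
  sat <- saturated_loglik(pairs)
  base <- baseline_loglik(pairs)
  n <- fit$n_individuals
  chisq <- max(2 * (sat$loglik - fit$loglik), 0)
  df <- sat$n_params - fit$n_params
  chisq_b <- max(2 * (sat$loglik - base$loglik), 0)
  df_b <- sat$n_params - base$n_params

  num <- max(chisq - df, 0)
  cfi <- 1 - num / max(chisq_b - df_b, num, .Machine$double.eps)
  tli_raw <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1)
  } else 1
  tli <- min(max(tli_raw, 0), 1.1)
  rmsea <- if (df > 0) sqrt(2) * sqrt(num / (df * n)) else 0

  # SRMR: standardized residuals of the six moments (mean, variance and
  # within-pair covariance per group) against the saturated estimates
  st <- biometric_structure(fit$model, fit$components)
  res_one <- function(g, c_imp) {
    sdv <- sqrt(g$v)
    c((g$mean - fit$mean) / sdv,
      (g$v - st$v) / g$v,
      (g$c - c_imp) / g$v)
  }
  resid_std <- c(res_one(sat$mz, st$c_mz), res_one(sat$dz, st$c_dz))
  srmr <- sqrt(mean(resid_std^2))

  tibble::tibble(
    chisq = chisq, df = df,
    p.value = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    CFI = cfi, TLI = tli, RMSEA = rmsea, SRMR = srmr,
    BIC = -2 * fit$loglik + fit$n_params * log(n)
  )
}

#' Compare a sequence of twin models
#'
#' Tabulates fit statistics for a list of [fit_biometric()] objects fitted
#' to the same pairs and flags the preferred model: the most parsimonious
#' one (fewest parameters, then lower BIC) whose chi-square p-value exceeds
#' 0.05 and whose CFI, RMSEA and SRMR pass the conventional thresholds; if
#' none qualifies, the lowest-BIC model is flagged.
#'
#' @param fits List of `biometric_fit` objects.
#' @param pairs The shared [twin_pairs()] data.
#' @return A tibble, one row per model, with fit indices, shares and a
#'   logical `preferred` column.
#' @export
compare_models <- function(fits, pairs) {
  rows <- purrr::map_dfr(fits, function(f) {
    dplyr::bind_cols(
      tibble::tibble(model = f$model, n_params = f$n_params,
                     loglik = f$loglik),
      fit_indices(f, pairs),
      tibble::tibble(shares = list(setNames(f$shares$estimate,
                                            f$shares$component)))
    )
  })
  adequate <- rows$p.value > 0.05 & rows$CFI >= 0.9 &
    rows$RMSEA <= 0.08 & rows$SRMR <= 0.1
  adequate[is.na(adequate)] <- FALSE
  pick <- if (any(adequate)) {
    cand <- which(adequate)
    cand[order(rows$n_params[cand], rows$BIC[cand])][1]
  } else {
    which.min(rows$BIC)
  }
  rows$preferred <- seq_len(nrow(rows)) == pick
  rows
}

#' Simulate twin pairs under a biometric generating model
#'
#' Draws complete MZ and DZ pairs from the exchangeable bivariate normal
#' implied by the requested variance components (shares of `total`).
#'
#' @param n_mz,n_dz Pair counts.
#' @param a2,c2,d2,e2 Variance-component shares (any subset; they are taken
#'   as given, e.g. `a2 = 0.73, e2 = 0.27` for an AE model).
#' @param total Total variance (default 1).
#' @param mean Grand mean (default 0).
#' @param seed Optional seed.
#' @return A `zygosity_pairs` object with complete pairs.
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, a2 = 0, c2 = 0, d2 = 0, e2 = 1,
                                total = 1, mean = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, r_a, r_d) {
    a <- twin_genetic_scores(n, r_a) * sqrt(a2 * total)
    cc <- matrix(rep(rnorm(n), 2), ncol = 2) * sqrt(c2 * total)
    d <- twin_genetic_scores(n, r_d) * sqrt(d2 * total)
    e <- matrix(rnorm(2 * n), ncol = 2) * sqrt(e2 * total)
    mean + a + cc + d + e
  }
  structure(
    list(mz = draw(n_mz, 1, 1), dz = draw(n_dz, 0.5, 0.25), outcome = NULL),
    class = "zygosity_pairs"
  )
}
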