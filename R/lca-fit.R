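# ---- internal data preparation ---------------------------------------------

# split a cohort tibble into an ordinal integer matrix and a continuous
# matrix following the indicator specs; drop rows with every indicator
# missing (they carry no likelihood information)
prepare_lca_data <- function(data, specs) {
  check_indicator_specs(specs)
  missing_cols <- setdiff(specs$name, names(data))
  if (length(missing_cols)) {
    abort(paste("missing indicator columns:", paste(missing_cols, collapse = ", ")))
  }
  ord_specs <- specs[specs$kind == "ordinal", ]
  cont_specs <- specs[specs$kind == "continuous", ]
  O <- if (nrow(ord_specs)) {
    m <- as.matrix(data[ord_specs$name])
    storage.mode(m) <- "integer"
    for (j in seq_len(ncol(m))) {
      bad <- !is.na(m[, j]) & (m[, j] < 1L | m[, j] > ord_specs$n_categories[j])
      if (any(bad)) {
        abort(sprintf("indicator '%s': code out of range 1..%d (first bad row %d)",
                      ord_specs$name[j], ord_specs$n_categories[j], which(bad)[1]))
      }
    }
    m
  } else matrix(integer(), nrow(data), 0)
  Cn <- if (nrow(cont_specs)) as.matrix(data[cont_specs$name]) else
    matrix(numeric(), nrow(data), 0)
  n_obs <- rowSums(!is.na(O)) + rowSums(!is.na(Cn))
  keep <- n_obs > 0
  list(
    ord = O[keep, , drop = FALSE],
    cont = Cn[keep, , drop = FALSE],
    ord_ncat = ord_specs$n_categories,
    ord_names = ord_specs$name,
    cont_names = cont_specs$name,
    keep = keep,
    n = sum(keep)
  )
}

# per-class log-densities (n x K), FIML: missing items drop out of the sum
lca_logdens <- function(pd, pars) {
  n <- nrow(pd$ord)
  if (!n) n <- nrow(pd$cont)
  K <- length(pars$pi)
  ll <- matrix(0, n, K)
  for (j in seq_along(pd$ord_names)) {
    idx <- pd$ord[, j]
    obs <- !is.na(idx)
    LP <- log(pmax(pars$ordinal[[j]], 1e-300))
    ll[obs, ] <- ll[obs, ] + LP[idx[obs], , drop = FALSE]
  }
  for (j in seq_along(pd$cont_names)) {
    y <- pd$cont[, j]
    obs <- !is.na(y)
    mu <- pars$cont_mean[j, ]
    sdv <- sqrt(pars$cont_var[j, ])
    ll[obs, ] <- ll[obs, ] + vapply(
      seq_len(K), function(k) dnorm(y[obs], mu[k], sdv[k], log = TRUE),
      numeric(sum(obs))
    )
  }
  ll
}

lca_estep <- function(pd, pars) {
  ll <- sweep(lca_logdens(pd, pars), 2L, log(pars$pi), `+`)
  lse <- row_logsumexp(ll)
  list(z = exp(ll - lse), loglik = sum(lse))
}

lca_mstep <- function(pd, z, prev, var_floor) {
  K <- ncol(z)
  n <- nrow(z)
  pars <- prev
  pars$pi <- pmax(colSums(z), 1e-12) / n
  pars$pi <- pars$pi / sum(pars$pi)
  for (j in seq_along(pd$ord_names)) {
    idx <- pd$ord[, j]
    obs <- !is.na(idx)
    zo <- z[obs, , drop = FALSE]
    denom <- colSums(zo)
    counts <- matrix(0, pd$ord_ncat[j], K)
    rs <- rowsum(zo, group = idx[obs])
    counts[as.integer(rownames(rs)), ] <- rs
    ok <- denom > 1e-10
    P <- prev$ordinal[[j]]
    P[, ok] <- sweep(counts[, ok, drop = FALSE], 2L, denom[ok], `/`)
    pars$ordinal[[j]] <- P
  }
  floored <- FALSE
  for (j in seq_along(pd$cont_names)) {
    y <- pd$cont[, j]
    obs <- !is.na(y)
    zo <- z[obs, , drop = FALSE]
    sw <- colSums(zo)
    ok <- sw > 1e-10
    mu <- prev$cont_mean[j, ]
    v <- prev$cont_var[j, ]
    mu[ok] <- colSums(zo[, ok, drop = FALSE] * y[obs]) / sw[ok]
    dev2 <- (matrix(y[obs], sum(obs), K) -
               matrix(mu, sum(obs), K, byrow = TRUE))^2
    v[ok] <- colSums(zo[, ok, drop = FALSE] * dev2[, ok, drop = FALSE]) / sw[ok]
    if (any(v[ok] < var_floor[j])) floored <- TRUE
    v <- pmax(v, var_floor[j])
    pars$cont_mean[j, ] <- mu
    pars$cont_var[j, ] <- v
  }
  pars$floored <- floored
  pars
}

# run EM from a given responsibility matrix until convergence
lca_em_run <- function(pd, z0, K, tol, max_iter, var_floor) {
  pars <- list(
    pi = rep(1 / K, K),
    ordinal = purrr::map(seq_along(pd$ord_names),
                         ~ matrix(1 / pd$ord_ncat[.x], pd$ord_ncat[.x], K)),
    cont_mean = matrix(0, length(pd$cont_names), K),
    cont_var = matrix(1, length(pd$cont_names), K)
  )
  pars <- lca_mstep(pd, z0, pars, var_floor)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  any_floor <- FALSE
  for (it in seq_len(max_iter)) {
    es <- lca_estep(pd, pars)
    trace <- c(trace, es$loglik)
    if (es$loglik - ll_old < tol && it > 1L) {
      converged <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
    pars <- lca_mstep(pd, es$z, pars, var_floor)
    any_floor <- any_floor || isTRUE(pars$floored)
  }
  list(pars = pars, loglik = ll_old, trace = trace,
       converged = converged, floored = any_floor, z = es$z)
}

# ---- user-facing fitting ----------------------------------------------------

#' Fit a latent class model to mixed ordinal and continuous indicators
#'
#' Maximises the observed-data log-likelihood
#' `sum_i log sum_k pi_k prod_{j in obs(i)} f_jk(y_ij)` by EM under local
#' independence. Missing items drop out of each individual's product, which
#' is full-information maximum likelihood under missingness at random;
#' individuals with every indicator missing are excluded. Ordinal
#' indicators get unconstrained class-specific category probabilities;
#' continuous indicators get class-specific means and variances (variances
#' floored at `1e-4` times the marginal variance). The best of `n_starts`
#' random initialisations is kept: every start runs a short burn-in and the
#' most promising candidates are polished to convergence. Classes are
#' relabelled to a canonical order (descending class proportion, ties by
#' ascending mean of the last continuous indicator).
#'
#' @param data Cohort tibble containing the indicator columns.
#' @param specs Indicator specification tibble, e.g.
#'   [lifestyle_indicators()].
#' @param k Number of latent classes (>= 1).
#' @param n_starts Random starts (default 50).
#' @param tol Absolute log-likelihood increment declaring convergence.
#' @param max_iter Maximum EM iterations per polished start.
#' @param burn_iter Burn-in iterations for the multistart screening stage.
#' @param n_polish Number of screened starts polished to convergence.
#' @param seed Optional integer seed for the random starts.
#' @return An object of class `lca_fit` with elements `k`, `pi`,
#'   `ordinal_params`, `cont_params`, `loglik`, `n_params`, `converged`,
#'   `n_effective`, `loglik_trace`, and flags `degenerate` /
#'   `variance_floored`. Supports [tidy()], [glance()], [autoplot()],
#'   [class_posterior()].
#' @export
#' @examples
#' cfg <- default_lifestyle_config(n_pairs = 150)
#' cohort <- generate_cohort(cfg)
#' fit <- fit_lca(cohort, lifestyle_indicators(), k = 2, n_starts = 5, seed = 1)
#' glance(fit)
fit_lca <- function(data, specs = lifestyle_indicators(), k,
                    n_starts = 50, tol = 1e-6, max_iter = 2000,
                    burn_iter = 40, n_polish = 5, seed = NULL) {
  k <- check_count(k, "k")
  n_starts <- check_count(n_starts, "n_starts")
  if (!is.null(seed)) set.seed(seed)
  pd <- prepare_lca_data(data, specs)
  n <- pd$n
  if (n < k) abort("fewer informative individuals than classes")
  var_floor <- vapply(seq_along(pd$cont_names), function(j) {
    1e-4 * var(pd$cont[, j], na.rm = TRUE)
  }, numeric(1))

  if (k == 1L) {
    z0 <- matrix(1, n, 1)
    runs <- list(lca_em_run(pd, z0, 1L, tol, max_iter, var_floor))
  } else {
    starts <- purrr::map(seq_len(n_starts), function(s) {
      z <- matrix(-log(runif(n * k)), n, k) # Dirichlet(1) responsibilities
      z / rowSums(z)
    })
    burns <- purrr::map(starts, function(z0) {
      lca_em_run(pd, z0, k, tol, burn_iter, var_floor)
    })
    ord <- order(vapply(burns, `[[`, numeric(1), "loglik"), decreasing = TRUE)
    polish <- head(ord, max(1L, n_polish))
    runs <- purrr::map(polish, function(i) {
      r0 <- burns[[i]]
      r <- lca_em_run(pd, r0$z, k, tol, max_iter, var_floor)
      r$trace <- c(r0$trace, r$trace)
      r$floored <- r$floored || r0$floored
      r
    })
  }
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]

  # canonical class ordering: descending proportion, ties by ascending mean
  # of the last continuous indicator (BMI at the oldest age in the default
  # lifestyle specs)
  pars <- best$pars
  tie_key <- if (length(pd$cont_names)) {
    pars$cont_mean[length(pd$cont_names), ]
  } else {
    rep(0, k)
  }
  o <- order(-round(pars$pi, 8), tie_key)
  pars$pi <- pars$pi[o]
  pars$ordinal <- purrr::map(pars$ordinal, ~ .x[, o, drop = FALSE])
  pars$cont_mean <- pars$cont_mean[, o, drop = FALSE]
  pars$cont_var <- pars$cont_var[, o, drop = FALSE]

  n_cat <- pd$ord_ncat
  n_params <- (k - 1L) + sum(k * (n_cat - 1L)) + 2L * k * length(pd$cont_names)

  ordinal_params <- setNames(pars$ordinal, pd$ord_names)
  cont_params <- setNames(
    purrr::map(seq_along(pd$cont_names), function(j) {
      list(mean = pars$cont_mean[j, ], var = pars$cont_var[j, ])
    }),
    pd$cont_names
  )

  structure(
    list(
      k = k, pi = pars$pi,
      ordinal_params = ordinal_params, cont_params = cont_params,
      loglik = best$loglik, n_params = n_params,
      converged = best$converged, n_effective = n,
      loglik_trace = best$trace,
      degenerate = any(pars$pi < 1 / n),
      variance_floored = best$floored,
      specs = specs, .pars = pars, .data = pd
    ),
    class = "lca_fit"
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> K = %d, logLik = %.2f, n = %d, %s\n",
              x$k, x$loglik, x$n_effective,
              if (x$converged) "converged" else "NOT converged"))
  cat("class proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Bayes posteriors given each individual's observed indicators. Rows with
#' every indicator missing receive the prior (the mixing proportions).
#'
#' @param fit An [fit_lca()] object.
#' @param data Optional new cohort tibble; defaults to the fitting data
#'   (excluding the all-missing rows dropped at fit time).
#' @return An `n x K` matrix with rows summing to 1.
#' @export
class_posterior <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "lca_fit"))
  if (is.null(data)) {
    pd <- fit$.data
  } else {
    pd <- prepare_lca_data(data, fit$specs)
    if (!all(pd$keep)) { # re-insert all-missing rows: posterior = prior
      full <- matrix(rep(fit$pi, each = length(pd$keep)), ncol = fit$k)
      sub <- class_posterior_pd(fit, pd)
      full[pd$keep, ] <- sub
      return(full)
    }
  }
  class_posterior_pd(fit, pd)
}

class_posterior_pd <- function(fit, pd) {
  ll <- sweep(lca_logdens(pd, fit$.pars), 2L, log(fit$pi), `+`)
  exp(ll - row_logsumexp(ll))
}

#' Information criteria for a latent class fit
#'
#' `AIC = -2L + 2p`, `BIC = -2L + p log(n)`,
#' `aBIC = -2L + p log((n + 2) / 24)` (the sample-size-adjusted BIC).
#' Lower values indicate better fit.
#'
#' @param fit An [fit_lca()] object.
#' @param n Sample size (defaults to the number of individuals contributing
#'   to the likelihood).
#' @return A one-row tibble: `k`, `loglik`, `n_params`, `AIC`, `BIC`, `aBIC`.
#' @export
information_criteria <- function(fit, n = fit$n_effective) {
  if (n < 1) abort("n must be >= 1")
  L <- fit$loglik; p <- fit$n_params
  tibble::tibble(
    k = fit$k, loglik = L, n_params = p,
    AIC = -2 * L + 2 * p,
    BIC = -2 * L + p * log(n),
    aBIC = -2 * L + p * log((n + 2) / 24)
  )
}

#' Lo-Mendell-Rubin class-enumeration tests
#'
#' Compares a K-class fit against the (K-1)-class fit on the same data.
#' The VLMR p-value refers `2 (L_K - L_{K-1})` to a chi-square with degrees
#' of freedom equal to the parameter-count difference; the LMR (adjusted)
#' p-value applies the parameter-difference and sample-size based scaling
#' `1 / (1 + 1 / (dp * log n))` to the statistic before the same reference.
#' A low p-value indicates the smaller model should be rejected.
#'
#' @param fit_k,fit_km1 [fit_lca()] objects with `fit_k$k == fit_km1$k + 1`.
#' @param n Sample size (default: individuals contributing to `fit_k`).
#' @return A one-row tibble: `statistic`, `df`, `vlmr_p`, `lmr_p`.
#' @export
lmr_tests <- function(fit_k, fit_km1, n = fit_k$n_effective) {
  if (fit_k$k != fit_km1$k + 1L) {
    abort("fit_km1 must have exactly one class fewer than fit_k")
  }
  if (fit_k$loglik < fit_km1$loglik - 1e-8) {
    abort(paste("the larger model has a lower log-likelihood;",
                "increase n_starts and refit"))
  }
  stat <- max(2 * (fit_k$loglik - fit_km1$loglik), 0)
  df <- fit_k$n_params - fit_km1$n_params
  scl <- 1 / (1 + 1 / (df * log(n)))
  tibble::tibble(
    statistic = stat, df = df,
    vlmr_p = pchisq(stat, df, lower.tail = FALSE),
    lmr_p = pchisq(stat * scl, df, lower.tail = FALSE)
  )
}

#' Average posterior probability of modal class membership
#'
#' For each class, the mean posterior probability of that class among the
#' individuals modally assigned to it (ties go to the lowest class index).
#' Values close to 1 indicate clear classification; entries for empty modal
#' classes are `NA` with a warning.
#'
#' @param posterior An `n x K` posterior matrix (rows sum to 1), e.g. from
#'   [class_posterior()].
#' @return A length-K numeric vector.
#' @export
avepp <- function(posterior) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  modal <- max.col(posterior, ties.method = "first")
  out <- vapply(seq_len(K), function(k) {
    sel <- modal == k
    if (!any(sel)) NA_real_ else mean(posterior[sel, k])
  }, numeric(1))
  if (anyNA(out)) warn("some classes have no modally assigned individuals")
  out
}

#' Fit and compare latent class models over a range of K
#'
#' Fits `fit_lca()` for each K and assembles the class-enumeration report:
#' information criteria, VLMR/LMR tests against the (K-1)-class model,
#' class sizes and AvePP diagnostics.
#'
#' @param data,specs As in [fit_lca()].
#' @param k_range Integer vector of class counts (e.g. `1:8`).
#' @param seed Integer seed; each K gets a deterministic sub-seed.
#' @param ... Passed to [fit_lca()] (`n_starts`, `tol`, ...).
#' @return A tibble with one row per K and a `fit` list-column.
#' @export
lca_select <- function(data, specs = lifestyle_indicators(), k_range = 1:6,
                       seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  fits <- purrr::map(k_range, function(k) {
    fit_lca(data, specs, k = k, seed = child_seed(seed, k), ...)
  })
  rows <- purrr::map2(fits, seq_along(fits), function(f, i) {
    ic <- information_criteria(f)
    post <- class_posterior(f)
    ap <- suppressWarnings(avepp(post))
    lr <- if (i > 1L) lmr_tests(f, fits[[i - 1L]]) else
      tibble::tibble(statistic = NA_real_, df = NA_integer_,
                     vlmr_p = NA_real_, lmr_p = NA_real_)
    dplyr::bind_cols(
      ic,
      tibble::tibble(vlmr_p = lr$vlmr_p, lmr_p = lr$lmr_p,
                     class_sizes = list(f$pi), avepp = list(ap),
                     min_avepp = suppressWarnings(min(ap, na.rm = TRUE)),
                     converged = f$converged, fit = list(f))
    )
  })
  dplyr::bind_rows(rows)
}
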