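# construct balanced complete pair data with EXACT sample moments
# (pooled-mean 0, unit variances, given within-pair correlations)
exact_moment_pairs <- function(n_mz, n_dz, r_mz, r_dz, seed = 1) {
  set.seed(seed)
  shape <- function(n, r) {
    z <- matrix(rnorm(2 * n), ncol = 2)
    z <- scale(z, scale = FALSE)
    S <- crossprod(z) / n
    z <- z %*% solve(chol(S)) # whiten to exact identity moments
    z %*% chol(matrix(c(1, r, r, 1), 2))
  }
  structure(list(mz = shape(n_mz, r_mz), dz = shape(n_dz, r_dz),
                 outcome = NULL),
            class = "zygosity_pairs")
}

test_that("the E model reduces to a zero-covariance normal", {
  tp <- exact_moment_pairs(100, 120, 0.6, 0.3)
  fe <- fit_biometric(tp, "E")
  allv <- c(tp$mz, tp$dz)
  expect_equal(unname(fe$components[["e2"]]), mean((allv - mean(allv))^2),
               tolerance = 1e-4)
  expect_equal(fe$shares$estimate, 1, tolerance = 1e-8)
})

test_that("AE maximum likelihood matches an independent grid search", {
  tp <- exact_moment_pairs(150, 150, 0.8, 0.4)
  fit <- fit_biometric(tp, "AE")
  # sample moments rMZ = 0.8 = 2 rDZ: AE fits exactly, a2 = 0.8
  expect_equal(unname(fit$components[["a2"]]), 0.8, tolerance = 0.01)
  expect_equal(fit$shares$estimate[1], 0.8, tolerance = 0.01)

  # independent dense grid over (a2, e2) evaluating the same two-group
  # normal likelihood written out directly
  grid_ll <- function(va, ve) {
    m <- mean(c(tp$mz, tp$dz))
    ll_g <- function(P, cc) {
      S <- matrix(c(va + ve, cc, cc, va + ve), 2)
      if (det(S) <= 0) return(-Inf)
      Si <- solve(S)
      d <- cbind(P[, 1] - m, P[, 2] - m)
      -nrow(P) * log(2 * pi) - nrow(P) / 2 * log(det(S)) -
        sum((d %*% Si) * d) / 2
    }
    ll_g(tp$mz, va) + ll_g(tp$dz, va / 2)
  }
  g <- expand.grid(va = seq(0.5, 1.1, by = 0.005),
                   ve = seq(0.05, 0.6, by = 0.005))
  lls <- mapply(grid_ll, g$va, g$ve)
  top <- g[which.max(lls), ]
  expect_lt(abs(fit$components[["a2"]] - top$va), 0.0051)
  expect_lt(abs(fit$components[["e2"]] - top$ve), 0.0051)
  expect_gte(fit$loglik + 1e-6, max(lls))
})

test_that("model nesting orders the maximised likelihoods", {
  tp <- exact_moment_pairs(120, 150, 0.7, 0.35, seed = 4)
  ll <- vapply(c("ACE", "AE", "CE", "E"),
               function(m) fit_biometric(tp, m)$loglik, numeric(1))
  expect_gte(ll[["ACE"]] + 1e-6, ll[["AE"]])
  expect_gte(ll[["AE"]], ll[["E"]])
  expect_gte(ll[["CE"]], ll[["E"]])
})

test_that("FIML uses incomplete pairs", {
  set.seed(9)
  tp <- simulate_twin_pairs(400, 500, a2 = 0.7, e2 = 0.3, seed = 2)
  # delete one member at random in 30% of pairs
  maim <- function(m) {
    drop <- runif(nrow(m)) < 0.3
    which_m <- sample(1:2, nrow(m), replace = TRUE)
    m[cbind(which(drop), which_m[drop])] <- NA
    m
  }
  tp$mz <- maim(tp$mz); tp$dz <- maim(tp$dz)
  fit <- fit_biometric(tp, "AE")
  expect_equal(fit$shares$estimate[1], 0.7, tolerance = 0.1)
  expect_identical(fit$n_individuals, sum(!is.na(c(tp$mz, tp$dz))))
})

test_that("saturated fit gives zero chi-square and perfect indices", {
  tp <- exact_moment_pairs(100, 110, 0.75, 0.3, seed = 6)
  sat <- twinaging:::saturated_loglik(tp)
  # a model with as many parameters as moments: compare saturated to itself
  fake <- structure(list(model = "AE", loglik = sat$loglik, n_params = 6L,
                         mean = 0,
                         components = c(a2 = 0.75, e2 = 0.25),
                         n_individuals = 420L),
                    class = "biometric_fit")
  idx <- fit_indices(fake, tp)
  expect_equal(idx$chisq, 0, tolerance = 1e-6)
  expect_equal(idx$CFI, 1)
  expect_equal(idx$RMSEA, 0)
})

test_that("chi-square is calibrated when the AE model is true", {
  stats <- vapply(1:60, function(r) {
    tp <- simulate_twin_pairs(300, 300, a2 = 0.6, e2 = 0.4, seed = 300 + r)
    fit <- fit_biometric(tp, "AE")
    idx <- fit_indices(fit, tp)
    expect_identical(idx$df, 3L)
    idx$chisq
  }, numeric(1))
  # the mean statistic should sit near its df (3), within Monte-Carlo noise
  expect_lt(abs(mean(stats) - 3), 1)
})

test_that("a pure-E fit on strongly twin-correlated data is rejected", {
  tp <- exact_moment_pairs(154, 211, 0.73, 0.37, seed = 8)
  fe <- fit_biometric(tp, "E")
  idx <- fit_indices(fe, tp)
  expect_lt(idx$p.value, 0.001)
  expect_lt(idx$CFI, 0.5)
  expect_gt(idx$RMSEA, 0.1)
})

test_that("model comparison prefers the generating family", {
  set.seed(33)
  picks <- vapply(1:25, function(r) {
    tp <- simulate_twin_pairs(154, 211, a2 = 0.73, e2 = 0.27, seed = 700 + r)
    fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) fit_biometric(tp, m))
    cmp <- compare_models(fits, tp)
    cmp$model[cmp$preferred]
  }, character(1))
  expect_gt(mean(picks == "AE"), 0.6)
  # and E is essentially never chosen
  expect_lt(mean(picks == "E"), 0.05)
})

test_that("twin_pairs pools DZ and applies FIML retention rules", {
  co <- generate_cohort(default_lifestyle_config(n_pairs = 300, seed = 14))
  tp <- twin_pairs(co, "AA_Grim")
  expect_true(all(rowSums(!is.na(tp$mz)) >= 1))
  n_dz_rows <- sum(co$zygosity != "MZ" & co$member_index == 1)
  expect_lte(nrow(tp$dz), n_dz_rows)
  expect_error(twin_pairs(co, "nope"), "no column")
})
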