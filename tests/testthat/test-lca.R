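# small mixed-data generator for LCA unit tests
binary_mixture <- function(n, pi1, p1, p2, seed) {
  set.seed(seed)
  cls <- 1 + (runif(n) > pi1)
  P <- rbind(p1, p2)
  dat <- sapply(seq_along(p1), function(j) {
    1L + (runif(n) < P[cls, j]) # code 2 with class-specific probability
  })
  out <- tibble::as_tibble(as.data.frame(dat))
  names(out) <- paste0("b", seq_along(p1))
  out
}

binary_specs <- function(J) {
  dplyr::bind_rows(lapply(seq_len(J), function(j) {
    indicator_spec(paste0("b", j), "ordinal", 2)
  }))
}

test_that("a one-class fit reduces to marginal frequencies and moments", {
  cfg <- two_class_config(n_pairs = 150)
  co <- generate_cohort(cfg)
  f1 <- fit_lca(co, two_class_specs(), k = 1)
  expect_equal(f1$pi, 1)
  expect_equal(as.vector(f1$ordinal_params$x1),
               as.vector(table(co$x1) / nrow(co)))
  expect_equal(f1$cont_params$z1$mean[1], mean(co$z1))
  expect_equal(f1$cont_params$z1$var[1],
               mean((co$z1 - mean(co$z1))^2))
  # loglik is the sum of independent marginal log-likelihoods
  ll_manual <- sum(log((table(co$x1) / nrow(co))[co$x1])) +
    sum(log((table(co$x2) / nrow(co))[co$x2])) +
    sum(log((table(co$x3) / nrow(co))[co$x3])) +
    sum(log((table(co$x4) / nrow(co))[co$x4])) +
    sum(dnorm(co$z1, mean(co$z1),
              sqrt(mean((co$z1 - mean(co$z1))^2)), log = TRUE))
  expect_equal(f1$loglik, ll_manual, tolerance = 1e-8)
  expect_true(all(class_posterior(f1) == 1))
})

test_that("EM attains the brute-force optimum on a small binary problem", {
  dat <- binary_mixture(500, 0.6, p1 = c(0.8, 0.8, 0.75, 0.7),
                        p2 = c(0.2, 0.25, 0.2, 0.3), seed = 2)
  specs <- binary_specs(4)
  fit <- fit_lca(dat, specs, k = 2, n_starts = 10, tol = 1e-10,
                 max_iter = 10000, seed = 1)

  # independent oracle: direct numerical maximization of the 9-parameter
  # observed-data log-likelihood on the logit scale
  Y <- as.matrix(dat) - 1L # 0/1
  negll <- function(th) {
    pi1 <- plogis(th[1])
    P <- matrix(plogis(th[-1]), nrow = 2, byrow = TRUE) # P(code 2 | class)
    l1 <- Y %*% log(P[1, ]) + (1 - Y) %*% log(1 - P[1, ])
    l2 <- Y %*% log(P[2, ]) + (1 - Y) %*% log(1 - P[2, ])
    m <- pmax(l1, l2)
    -sum(m + log(pi1 * exp(l1 - m) + (1 - pi1) * exp(l2 - m)))
  }
  set.seed(3)
  best <- Inf
  for (s in 1:20) {
    r <- optim(rnorm(9), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    r <- optim(r$par, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  expect_lt(abs(fit$loglik - (-best)), 1e-6)
})

test_that("EM log-likelihood never decreases across iterations", {
  cfg <- two_class_config(n_pairs = 200)
  co <- generate_cohort(cfg)
  fit <- fit_lca(co, two_class_specs(), k = 3, n_starts = 4, seed = 5)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("relabelling leaves loglik, criteria and AvePP multiset unchanged", {
  cfg <- two_class_config(n_pairs = 250)
  co <- generate_cohort(cfg)
  f_a <- fit_lca(co, two_class_specs(), k = 2, n_starts = 6, seed = 1)
  f_b <- fit_lca(co, two_class_specs(), k = 2, n_starts = 6, seed = 99)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-6)
  expect_equal(f_a$pi, f_b$pi, tolerance = 1e-4)
  expect_equal(information_criteria(f_a)$BIC, information_criteria(f_b)$BIC,
               tolerance = 1e-6)
  # canonical order: descending proportion
  expect_true(all(diff(f_a$pi) <= 1e-8))
})

test_that("parameter count follows the mixed-indicator accounting", {
  cfg <- two_class_config(n_pairs = 150)
  co <- generate_cohort(cfg)
  specs <- two_class_specs()
  # 4 ordinal with 3 categories + 1 continuous:
  # p(K) = (K-1) + K * 4 * 2 + 2K
  for (k in 1:3) {
    f <- fit_lca(co, specs, k = k, n_starts = 3, seed = 2, burn_iter = 10)
    expect_identical(f$n_params, (k - 1L) + k * 8L + 2L * k)
  }
  # ten-indicator lifestyle battery: each class adds 1 + 20 + 6 parameters,
  # matching the degrees-of-freedom progression of the enumeration table
  co2 <- generate_cohort(default_lifestyle_config(n_pairs = 100))
  f1 <- fit_lca(co2, k = 1)
  f2 <- fit_lca(co2, k = 2, n_starts = 3, burn_iter = 10, seed = 1)
  expect_identical(f1$n_params, 26L)
  expect_identical(f2$n_params - f1$n_params, 27L)
})

test_that("posterior rows are Bayes updates of the mixing proportions", {
  cfg <- two_class_config(n_pairs = 150)
  co <- generate_cohort(cfg)
  fit <- fit_lca(co, two_class_specs(), k = 2, n_starts = 5, seed = 3)
  post <- class_posterior(fit, co)
  expect_equal(rowSums(post), rep(1, nrow(co)))

  # hand Bayes oracle on a 3-row toy using the fitted parameters
  toy <- co[1:3, ]
  lik <- sapply(1:2, function(k) {
    sapply(1:3, function(i) {
      v <- 1
      for (nm in c("x1", "x2", "x3", "x4")) {
        v <- v * fit$ordinal_params[[nm]][toy[[nm]][i], k]
      }
      v * dnorm(toy$z1[i], fit$cont_params$z1$mean[k],
                sqrt(fit$cont_params$z1$var[k]))
    })
  })
  num <- sweep(lik, 2, fit$pi, `*`)
  expect_equal(class_posterior(fit, toy), num / rowSums(num),
               tolerance = 1e-10)

  # all-missing individual gets the prior
  toy_na <- toy
  toy_na[1, c("x1", "x2", "x3", "x4", "z1")] <-
    tibble::tibble(x1 = NA_integer_, x2 = NA_integer_, x3 = NA_integer_,
                   x4 = NA_integer_, z1 = NA_real_)
  post_na <- class_posterior(fit, toy_na)
  expect_equal(post_na[1, ], fit$pi)
})

test_that("FIML under MAR recovers the complete-data parameters", {
  cfg <- two_class_config(n_pairs = 4000, seed = 31)
  cfg$missing_rates <- list(base = c(x1 = 0.15, x2 = 0.2, x3 = 0.1,
                                     x4 = 0.25, z1 = 0.2),
                            sex_coef = 0.3, age_coef = 0.1)
  co <- generate_cohort(cfg)
  fit <- fit_lca(co, two_class_specs(), k = 2, n_starts = 6, seed = 7)
  expect_lt(abs(fit$pi[1] - 0.6), 0.03)
  expect_lt(abs(fit$cont_params$z1$mean[2] - 1.2), 0.08)
  expect_lt(max(abs(fit$ordinal_params$x1[, 1] - c(0.70, 0.20, 0.10))), 0.04)
})

test_that("information criteria follow their closed forms", {
  fake <- structure(list(k = 2L, loglik = -1000, n_params = 10L,
                         n_effective = 100L),
                    class = "lca_fit")
  ic <- information_criteria(fake, n = 100)
  expect_equal(ic$AIC, 2020)
  expect_equal(ic$BIC, 2000 + 10 * log(100))
  expect_equal(ic$aBIC, 2000 + 10 * log(102 / 24))
  expect_equal(ic$aBIC, 2014.47, tolerance = 1e-4)
  expect_error(information_criteria(fake, n = 0), "n must be")
})

test_that("identical fits give enumeration p-values near 1", {
  f_small <- structure(list(k = 2L, loglik = -500, n_params = 9L,
                            n_effective = 200L), class = "lca_fit")
  f_big <- structure(list(k = 3L, loglik = -500, n_params = 14L,
                          n_effective = 200L), class = "lca_fit")
  lr <- lmr_tests(f_big, f_small)
  expect_equal(lr$vlmr_p, 1)
  expect_equal(lr$lmr_p, 1)
  expect_gt(lmr_tests(f_big, f_small)$lmr_p, 0)
  # adding classes must not lower the likelihood
  f_bad <- f_big; f_bad$loglik <- -510
  expect_error(lmr_tests(f_bad, f_small), "starts")
})

test_that("the enumeration test is conservative under the null", {
  # data from a one-class model; K = 2 vs 1 rejections at alpha = 0.05
  specs <- binary_specs(4)
  # near the null the EM surface is flat; a generous but capped iteration
  # budget leaves the statistic essentially converged (and any shortfall
  # only makes the test more conservative, which is the property checked)
  rej <- vapply(1:200, function(r) {
    dat <- binary_mixture(1000, 1, p1 = c(0.6, 0.4, 0.5, 0.3),
                          p2 = c(0.6, 0.4, 0.5, 0.3), seed = 5000 + r)
    f1 <- fit_lca(dat, specs, k = 1)
    f2 <- fit_lca(dat, specs, k = 2, n_starts = 3, burn_iter = 15,
                  n_polish = 1, max_iter = 150, tol = 1e-4, seed = r)
    lmr_tests(f2, f1)$vlmr_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 0.02)
})

test_that("AvePP summarises modal-class posterior quality", {
  # identity-like posteriors
  expect_equal(avepp(diag(3)[c(1, 2, 3, 1), ]), c(1, 1, 1))
  # uniform posteriors: ties go to class 1, the empty class is flagged
  u <- matrix(0.5, 4, 2)
  expect_warning(ap <- avepp(u), "no modally assigned")
  expect_equal(ap[1], 0.5)
  expect_true(is.na(ap[2]))
  # 4-row hand oracle
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7), c(0.2, 0.8))
  expect_equal(avepp(p), c(0.75, 0.75))
})

test_that("class enumeration report has coherent structure", {
  cfg <- two_class_config(n_pairs = 250, seed = 12)
  co <- generate_cohort(cfg)
  sel <- lca_select(co, two_class_specs(), k_range = 1:3, n_starts = 4,
                    burn_iter = 15, seed = 4)
  expect_identical(sel$k, 1:3)
  expect_true(all(diff(sel$loglik) > 0))
  expect_true(is.na(sel$vlmr_p[1]) && all(!is.na(sel$vlmr_p[-1])))
  expect_true(all(vapply(sel$class_sizes, sum, numeric(1)) - 1 < 1e-8))
  # the generating model has two classes: aBIC should prefer K = 2
  expect_equal(sel$k[which.min(sel$aBIC)], 2L)
})
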