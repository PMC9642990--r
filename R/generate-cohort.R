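# draw a pair of standard-normal genetic scores with twin correlation r
# (r = 1 duplicates the draw, r = 0.5 mixes in an independent component)
twin_genetic_scores <- function(n, r) {
  g1 <- rnorm(n)
  g2 <- r * g1 + sqrt(1 - r^2) * rnorm(n)
  cbind(g1, g2)
}

# liability thresholds putting mass `props` in ordered intervals of N(0,1)
class_thresholds <- function(props) {
  qnorm(cumsum(props)[-length(props)])
}

#' Generate a synthetic twin cohort
#'
#' Simulates one individual-level twin cohort from a [cohort_config()]
#' generating model. Latent class membership is the threshold discretisation
#' of a normal liability whose genetic part is correlated 1 within MZ and
#' 0.5 within DZ pairs; indicators are drawn independently given class
#' (local independence); outcomes are class mean + covariate effects + an
#' AE residual whose additive-genetic part is partially the class-liability
#' genetic score; item missingness is missing-at-random, depending only on
#' fully observed sex and age.
#'
#' @param config A [cohort_config()].
#' @param keep_truth If `TRUE`, append hidden-truth columns `.true_class`,
#'   `.liability` and `.genetic_score` (never written to the primary cohort
#'   file by [write_cohort()]; they go to the truth sidecar).
#' @param seed Integer seed; defaults to `config$seed`. Output is
#'   deterministic given the seed.
#' @return A tibble with two rows per `family_id` (columns: `family_id`,
#'   `member_index`, `zygosity`, `sex`, `age`, `pds`, one column per
#'   indicator and per outcome).
#' @export
#' @examples
#' cfg <- default_lifestyle_config(n_pairs = 100)
#' generate_cohort(cfg, keep_truth = TRUE)
generate_cohort <- function(config, keep_truth = FALSE, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed %||% config$seed)
  np <- config$n_pairs
  K <- config$K

  zyg <- sample(c("MZ", "DZ_ss", "DZ_os"), np, replace = TRUE,
                prob = config$zygosity_probs)
  # sexes: same-sex pairs share one draw, opposite-sex pairs get one of each
  sex1 <- ifelse(runif(np) < 0.5, "female", "male")
  sex2 <- ifelse(zyg == "DZ_os",
                 ifelse(sex1 == "female", "male", "female"), sex1)
  age <- rnorm(np, 22.4, 0.7) # blood-draw age, shared within pair

  # class liability: shared genetic score G (r = 1 MZ, 0.5 DZ) plus
  # individual environment, plus a centred sex shift
  r_g <- ifelse(zyg == "MZ", 1, 0.5)
  g1 <- rnorm(np)
  g <- cbind(g1, r_g * g1 + sqrt(1 - r_g^2) * rnorm(np))
  h2 <- config$class_liability_h2
  shift <- config$sex_liability_shift
  sex_shift <- function(s) ifelse(s == "female", +shift / 2, -shift / 2)
  liab <- sqrt(h2) * g + sqrt(1 - h2) * matrix(rnorm(2 * np), ncol = 2) +
    cbind(sex_shift(sex1), sex_shift(sex2))
  thr <- class_thresholds(config$class_props)
  cls <- matrix(findInterval(liab, thr) + 1L, ncol = 2)

  # pubertal development: five ordinal items loading on a maturation latent
  # correlated with the class liability
  rho <- config$pds_class_cor
  mat <- rho * liab + sqrt(1 - rho^2) * matrix(rnorm(2 * np), ncol = 2)
  pds <- matrix(NA_real_, np, 2)
  for (m in 1:2) {
    items <- sapply(1:5, function(j) {
      z <- 0.7 * mat[, m] + sqrt(1 - 0.49) * rnorm(np)
      if (j < 5) {
        cut_pts <- qnorm(c(0.55, 0.85))
        findInterval(z, cut_pts) + 1
      } else {
        ifelse(z > qnorm(0.75), 3, 1) # dichotomous item, codes {1, 3}
      }
    })
    pds[, m] <- pds_score(items)
  }

  # long per-individual frame
  dat <- tibble::tibble(
    family_id = rep(seq_len(np), each = 2L),
    member_index = rep(1:2, np),
    zygosity = rep(zyg, each = 2L),
    sex = as.vector(rbind(sex1, sex2)),
    age = rep(age, each = 2L),
    pds = as.vector(t(pds))
  )
  cls_v <- as.vector(t(cls))
  g_v <- as.vector(t(g))
  n <- nrow(dat)

  # indicators given class (local independence)
  for (nm in names(config$indicator_params)) {
    p <- config$indicator_params[[nm]]
    if (p$kind == "ordinal") {
      C <- nrow(p$probs)
      u <- runif(n)
      cum <- apply(p$probs, 2L, cumsum)
      dat[[nm]] <- sapply(seq_len(n), function(i) {
        findInterval(u[i], cum[, cls_v[i]], left.open = TRUE) + 1L
      })
    } else {
      dat[[nm]] <- rnorm(n, p$means[cls_v], p$sds[cls_v])
    }
  }

  # outcomes: class mean + covariate effects + AE residual
  female <- as.numeric(dat$sex == "female")
  for (nm in names(config$outcome_params)) {
    p <- config$outcome_params[[nm]]
    ce <- config$covariate_effects[[nm]]
    gu1 <- rnorm(np)
    gu <- cbind(gu1, r_g * gu1 + sqrt(1 - r_g^2) * rnorm(np))
    a_part <- sqrt(p$shared_a_frac * p$a2) * g_v +
      sqrt((1 - p$shared_a_frac) * p$a2) * as.vector(t(gu))
    e_part <- sqrt(p$e2) * rnorm(n)
    dat[[nm]] <- p$class_means[cls_v] +
      ce$sex_female * female + ce$age * (dat$age - 22.4) +
      ce$pds * (dat$pds - 1.58) +
      p$resid_sd * (a_part + e_part)
  }

  # outcome subsample: whole pairs enter; within a sampled pair possibly
  # only one member is measured
  if (length(config$outcome_params) &&
      (config$outcome_pair_prob < 1 || config$outcome_both_prob < 1)) {
    pair_in <- runif(np) < config$outcome_pair_prob
    both <- runif(np) < config$outcome_both_prob
    which_one <- sample(1:2, np, replace = TRUE)
    keep <- rep(FALSE, n)
    idx1 <- seq(1, n, by = 2); idx2 <- idx1 + 1L
    keep[idx1] <- pair_in & (both | which_one == 1L)
    keep[idx2] <- pair_in & (both | which_one == 2L)
    for (nm in names(config$outcome_params)) {
      dat[[nm]][!keep] <- NA_real_
    }
  }

  # MAR item missingness: logit depends only on sex and age
  mr <- config$missing_rates
  for (nm in names(mr$base)) {
    b <- mr$base[[nm]]
    if (b > 0) {
      lp <- qlogis(b) + mr$sex_coef * (female - 0.5) +
        mr$age_coef * (dat$age - 22.4)
      dat[[nm]][runif(n) < plogis(lp)] <- NA
    }
  }

  if (keep_truth) {
    dat$.true_class <- cls_v
    dat$.liability <- as.vector(t(liab))
    dat$.genetic_score <- g_v
  }
  dat
}

# population-level AE projection: minimize the multigroup normal ML
# discrepancy of the AE-implied covariance against empirical pair moments
ae_project <- function(s_mz, s_dz, w_mz) {
  sig <- function(va, ve, r) {
    v <- va + ve
    matrix(c(v, r * va, r * va, v), 2)
  }
  fdisc <- function(th) {
    va <- th[1]; ve <- th[2]
    smz <- sig(va, ve, 1); sdz <- sig(va, ve, 0.5)
    if (ve <= 0 || va + ve <= 0 ||
        det(smz) <= 0 || det(sdz) <= 0) return(1e10)
    w_mz * (log(det(smz)) + sum(diag(s_mz %*% solve(smz)))) +
      (1 - w_mz) * (log(det(sdz)) + sum(diag(s_dz %*% solve(sdz))))
  }
  v0 <- (s_mz[1, 1] + s_dz[1, 1]) / 2
  a0 <- max(2 * (s_mz[1, 2] - s_dz[1, 2]), 0.05 * v0)
  fit <- optim(c(a0, max(v0 - a0, 0.05 * v0)), fdisc,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  c(va = fit$par[1], ve = fit$par[2])
}

#' Generating-model truth for the shared-variance decomposition
#'
#' Computes, by large-sample simulation of the latent variables of a
#' [cohort_config()], the population values that the end-to-end pipeline
#' estimates: total outcome variance, variance explained by the class
#' structure, and the genetic/environmental proportions of total variance
#' shared with (and unique to) the latent classes. The AE variance
#' components are obtained by projecting the simulated pair moments onto
#' the AE covariance structure (a population-level discrepancy
#' minimisation, independent of the package's likelihood fitting code).
#'
#' Covariate effects and missingness are not part of the truth: the oracle
#' describes the covariate-free outcome, matching a pipeline run on
#' covariate-adjusted values.
#'
#' @param config A [cohort_config()] with at least one outcome.
#' @param outcome Outcome name (default: first configured outcome).
#' @param n_pairs_sim Number of simulated twin pairs (>= 5e5 by default, i.e.
#'   over a million individuals).
#' @param seed Seed for the oracle simulation.
#' @return A one-row tibble: `var_tot`, `var_model`, `var_res`, `a2_tot`,
#'   `e2_tot`, `a2_res`, `e2_res`, `shared_genetic`, `shared_environment`,
#'   `unique_genetic`, `unique_environment` (the last four as proportions of
#'   `var_tot`).
#' @export
true_shared_proportions <- function(config, outcome = NULL,
                                    n_pairs_sim = 5e5, seed = 2026L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!length(config$outcome_params)) abort("config has no outcomes")
  outcome <- outcome %||% names(config$outcome_params)[1]
  p <- config$outcome_params[[outcome]]
  set.seed(seed)

  w_mz <- config$zygosity_probs[1]
  n_mz <- round(n_pairs_sim * w_mz)
  n_dz <- n_pairs_sim - n_mz
  h2 <- config$class_liability_h2
  thr <- class_thresholds(config$class_props)
  shift <- config$sex_liability_shift

  sim_group <- function(n, r) {
    g <- twin_genetic_scores(n, r)
    sexf <- runif(n) < 0.5 # family-level sex for same-sex logic; DZ_os pooled
    sshift <- ifelse(sexf, +shift / 2, -shift / 2)
    liab <- sqrt(h2) * g + sqrt(1 - h2) * matrix(rnorm(2 * n), ncol = 2) +
      cbind(sshift, sshift)
    cls <- matrix(findInterval(liab, thr) + 1L, ncol = 2)
    gu <- twin_genetic_scores(n, r)
    a <- sqrt(p$shared_a_frac * p$a2) * g +
      sqrt((1 - p$shared_a_frac) * p$a2) * gu
    e <- sqrt(p$e2) * matrix(rnorm(2 * n), ncol = 2)
    y <- matrix(p$class_means[cls], ncol = 2) + p$resid_sd * (a + e)
    list(y = y, cls = cls)
  }
  mz <- sim_group(n_mz, 1)
  dz <- sim_group(n_dz, 0.5)

  # the class structure explains the full conditional outcome mean per
  # class (nominal class effect plus the class-linked part of the shared
  # genetic score), so residuals subtract empirical conditional means
  cls_all <- c(mz$cls, dz$cls)
  y_all <- c(mz$y, dz$y)
  mu_cond <- vapply(seq_len(config$K),
                    function(k) mean(y_all[cls_all == k]), numeric(1))
  mz$r <- mz$y - matrix(mu_cond[mz$cls], ncol = 2)
  dz$r <- dz$y - matrix(mu_cond[dz$cls], ncol = 2)

  cov_c <- function(m) { # 2x2 moment matrix around the pooled mean
    mu <- mean(m)
    d <- m - mu
    crossprod(d) / nrow(d)
  }
  tot <- ae_project(cov_c(mz$y), cov_c(dz$y), w_mz)
  res <- ae_project(cov_c(mz$r), cov_c(dz$r), w_mz)
  var_model <- var(mu_cond[cls_all])
  var_tot <- sum(tot)

  tibble::tibble(
    outcome = outcome,
    var_tot = var_tot,
    var_model = var_model,
    var_res = sum(res),
    a2_tot = tot[["va"]], e2_tot = tot[["ve"]],
    a2_res = res[["va"]], e2_res = res[["ve"]],
    shared_genetic = (tot[["va"]] - res[["va"]]) / var_tot,
    shared_environment = (tot[["ve"]] - res[["ve"]]) / var_tot,
    unique_genetic = res[["va"]] / var_tot,
    unique_environment = res[["ve"]] / var_tot
  )
}
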