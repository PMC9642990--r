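#' Classification-error matrix of a modal assignment
#'
#' `D[k, s] = sum_i p_ik 1(w_i = s) / sum_i p_ik`: the estimated probability
#' of being modally assigned to class `s` given true class `k`. Rows sum
#' to 1.
#'
#' @param posterior An `n x K` posterior matrix.
#' @param modal Optional modal assignment vector (defaults to the row-wise
#'   argmax, ties to the lowest index); ignored for
#'   `assignment = "proportional"`.
#' @param assignment `"modal"` (the common default) replaces the inner
#'   indicator with the hard modal assignment; `"proportional"` uses the
#'   posterior itself, `D[k, s] = sum_i p_ik p_is / sum_i p_ik`.
#' @return The `K x K` matrix `D`.
#' @export
classification_error_matrix <- function(posterior, modal = NULL,
                                        assignment = c("modal", "proportional")) {
  assignment <- match.arg(assignment)
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  denom <- colSums(posterior)
  if (any(denom < 1e-10)) abort("a class has (near) zero total posterior mass")
  if (assignment == "modal") {
    modal <- modal %||% max.col(posterior, ties.method = "first")
    if (length(modal) != nrow(posterior)) abort("modal has the wrong length")
    D <- vapply(seq_len(K), function(s) {
      colSums(posterior[modal == s, , drop = FALSE])
    }, numeric(K)) / denom
  } else {
    D <- crossprod(posterior) / denom
  }
  dimnames(D) <- list(true = seq_len(K), modal = seq_len(K))
  D
}

#' BCH weights from a classification-error matrix
#'
#' Inverts `D` to obtain `H = D^{-1}`; individual `i` modally assigned to
#' class `w_i` receives weight row `H[w_i, ]`. Weight rows sum to 1 and may
#' contain negative entries (a documented property of the
#' Bolck-Croon-Hagenaars correction).
#'
#' @param D `K x K` classification-error matrix (rows sum to 1).
#' @param modal Optional modal assignment vector; if given, the
#'   per-individual weight matrix is returned as well.
#' @return A list with `H`, the condition number `kappa`, and (if `modal`
#'   was supplied) the `n x K` matrix `weights`.
#' @export
bch_weights <- function(D, modal = NULL) {
  D <- as.matrix(D)
  kappa <- kappa(D, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e8) {
    abort(paste("classification-error matrix is (near) singular -",
                "entropy too low; refit with fewer classes or more starts"))
  }
  H <- solve(D)
  out <- list(H = H, kappa = kappa)
  if (!is.null(modal)) out$weights <- H[modal, , drop = FALSE]
  out
}

# cluster-robust (sandwich) covariance for WLS with possibly negative
# weights: bread = (X'WX)^-1, meat = sum over clusters of the outer product
# of the cluster score X'W r
cluster_sandwich <- function(X, w, r, cluster) {
  Xw <- X * w
  bread <- solve(crossprod(Xw, X))
  sc <- rowsum(Xw * r, group = cluster)
  meat <- crossprod(sc)
  V <- bread %*% meat %*% bread
  (V + t(V)) / 2
}

#' BCH distal-outcome model
#'
#' Third step of the Bolck-Croon-Hagenaars approach: weighted least squares
#' of a continuous distal outcome on K class-indicator columns (no global
#' intercept) plus shared covariate columns, using the BCH weight rows, with
#' family-clustered sandwich standard errors. Reports covariate-adjusted
#' class means, the overall Wald test of equal class means (chi-square
#' reference with K-1 df), and all pairwise class contrasts with 95% and
#' 99% confidence intervals and standardized mean differences (contrast
#' divided by the whole-sample SD of the outcome).
#'
#' @param data Cohort tibble (used for the outcome, covariates and cluster
#'   ids).
#' @param outcome Outcome column name.
#' @param weights `n x K` matrix of BCH weight rows aligned with `data`
#'   (e.g. `bch_weights(D, modal)$weights`); one-hot rows reproduce
#'   per-class OLS. Rows with a missing outcome or covariate are dropped.
#' @param covariates Character vector of covariate column names (possibly
#'   empty). The paper-style adjustment set is
#'   `c("sex_female", "age_std", "pds")`; any numeric columns work.
#' @param cluster Column name of the clustering unit (default
#'   `"family_id"`).
#' @param smd_sd SD used for standardized mean differences; default the
#'   whole-sample SD of the observed outcome.
#' @return An object of class `distal_fit`: `class_means`, `coef`, `vcov`,
#'   `wald` (statistic, df, p), `contrasts` tibble (diff, se, conf.low/high
#'   at 95 and 99%, smd), `n`, `n_clusters`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_distal <- function(data, outcome, weights, covariates = character(),
                       cluster = "family_id", smd_sd = NULL) {
  y_all <- data[[outcome]]
  if (is.null(y_all)) abort(sprintf("no column '%s'", outcome))
  W <- as.matrix(weights)
  K <- ncol(W)
  if (nrow(W) != nrow(data)) abort("weights not aligned with data")
  Xc <- if (length(covariates)) as.matrix(data[covariates]) else
    matrix(numeric(), nrow(data), 0)
  ok <- complete.cases(y_all, Xc)
  y <- y_all[ok]
  Xc <- Xc[ok, , drop = FALSE]
  W <- W[ok, , drop = FALSE]
  cl <- data[[cluster]][ok]
  n <- length(y)
  if (n < K + ncol(Xc) + 1) abort("too few complete observations")
  smd_sd <- smd_sd %||% sd(y)
  if (smd_sd <= 0) abort("outcome SD must be positive")

  # stacked BCH regression: individual i contributes one row per class k
  # with weight W[i, k]; covariate effects are shared across classes
  Xs <- cbind(kronecker(diag(K), rep(1, n)),
              kronecker(rep(1, K), Xc))
  colnames(Xs) <- c(paste0("class", seq_len(K)), colnames(Xc))
  ys <- rep(y, K)
  ws <- as.vector(W)
  cls <- rep(cl, K)

  XtWX <- crossprod(Xs * ws, Xs)
  if (rcond(XtWX) < 1e-12) {
    abort("weighted cross-product is near singular (collinear covariates?)")
  }
  beta <- solve(XtWX, crossprod(Xs * ws, ys))
  r <- ys - Xs %*% beta
  V <- cluster_sandwich(Xs, ws, as.vector(r), cls)
  dimnames(V) <- list(colnames(Xs), colnames(Xs))
  beta <- setNames(as.vector(beta), colnames(Xs))

  mu <- beta[seq_len(K)]
  Vmu <- V[seq_len(K), seq_len(K)]
  # overall Wald test of equal class means
  Cmat <- cbind(diag(K - 1), 0) - cbind(0, diag(K - 1))
  d <- Cmat %*% mu
  wald_stat <- as.numeric(t(d) %*% solve(Cmat %*% Vmu %*% t(Cmat), d))
  wald <- tibble::tibble(statistic = wald_stat, df = K - 1L,
                         p.value = pchisq(wald_stat, K - 1L, lower.tail = FALSE))

  prs <- utils::combn(K, 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    a <- prs[2, i]; b <- prs[1, i] # higher class vs lower (C5 vs C1 style)
    diff <- mu[a] - mu[b]
    se <- sqrt(Vmu[a, a] + Vmu[b, b] - 2 * Vmu[a, b])
    tibble::tibble(
      contrast = sprintf("C%d vs. C%d", a, b),
      diff = diff, se = se,
      conf.low95 = diff - qnorm(0.975) * se,
      conf.high95 = diff + qnorm(0.975) * se,
      conf.low99 = diff - qnorm(0.995) * se,
      conf.high99 = diff + qnorm(0.995) * se,
      smd = smd(diff, smd_sd)
    )
  })

  structure(
    list(
      outcome = outcome, class_means = mu, coef = beta, vcov = V,
      wald = wald, contrasts = contrasts, smd_sd = smd_sd,
      n = n, n_clusters = length(unique(cl)), covariates = covariates
    ),
    class = "distal_fit"
  )
}

#' @export
print.distal_fit <- function(x, ...) {
  cat(sprintf("<distal_fit> %s: %d obs in %d families\n",
              x$outcome, x$n, x$n_clusters))
  cat("class means:", paste(sprintf("%.3f", x$class_means), collapse = " "), "\n")
  cat(sprintf("Wald chi2(%d) = %.2f, p = %.3g\n",
              x$wald$df, x$wald$statistic, x$wald$p.value))
  invisible(x)
}

#' Standardized mean difference
#'
#' A mean contrast divided by the outcome's whole-sample standard
#' deviation.
#'
#' @param diff Mean difference (outcome units).
#' @param sd Whole-sample SD of the outcome (> 0).
#' @return `diff / sd`.
#' @export
#' @examples
#' smd(2.70, 3.24) # 0.83
smd <- function(diff, sd) {
  if (any(sd <= 0)) abort("sd must be > 0")
  diff / sd
}

#' Simulate a classified sample with known posteriors
#'
#' Draws true classes from `class_props` and a noisy class signal with
#' accuracy `accuracy` (probability the signal equals the true class, the
#' rest spread evenly); returns the exact Bayes posterior rows given the
#' signal. Useful for validating classify-analyze corrections under a
#' controlled entropy without fitting a mixture.
#'
#' @param n Individuals.
#' @param class_props True class proportions.
#' @param accuracy Signal accuracy in `(1/K, 1]`.
#' @return A list: `true_class`, `signal`, `posterior` (n x K), `entropy`
#'   (relative entropy of the posterior matrix).
#' @export
simulate_classified <- function(n, class_props, accuracy = 0.85) {
  class_props <- normalize_probs(class_props, "class_props")
  K <- length(class_props)
  if (accuracy <= 1 / K || accuracy > 1) abort("accuracy must be in (1/K, 1]")
  M <- matrix((1 - accuracy) / (K - 1), K, K)
  diag(M) <- accuracy
  tc <- sample.int(K, n, replace = TRUE, prob = class_props)
  sig <- vapply(tc, function(k) sample.int(K, 1L, prob = M[k, ]), integer(1))
  # posterior given signal s: pi_k M[k, s] / sum
  post_by_signal <- vapply(seq_len(K), function(s) {
    p <- class_props * M[, s]
    p / sum(p)
  }, numeric(K)) # K x K, columns indexed by signal
  post <- t(post_by_signal)[sig, , drop = FALSE]
  ent <- 1 - sum(-post * log(pmax(post, 1e-300))) / (n * log(K))
  list(true_class = tc, signal = sig, posterior = post, entropy = ent)
}
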