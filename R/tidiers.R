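#' Tidy a latent class fit
#'
#' One row per parameter: mixing proportions, ordinal category
#' probabilities and continuous means/variances, with class labels.
#'
#' @param x An [fit_lca()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `indicator`, `class`, `category`,
#'   `estimate`.
#' @method tidy lca_fit
#' @export
tidy.lca_fit <- function(x, ...) {
  pi_rows <- tibble::tibble(
    term = "pi", indicator = NA_character_,
    class = seq_len(x$k), category = NA_integer_, estimate = x$pi
  )
  ord_rows <- purrr::imap_dfr(x$ordinal_params, function(P, nm) {
    tidyr::expand_grid(category = seq_len(nrow(P)), class = seq_len(ncol(P))) |>
      dplyr::mutate(term = "prob", indicator = nm,
                    estimate = P[cbind(.data$category, .data$class)]) |>
      dplyr::select("term", "indicator", "class", "category", "estimate")
  })
  cont_rows <- purrr::imap_dfr(x$cont_params, function(p, nm) {
    dplyr::bind_rows(
      tibble::tibble(term = "mean", indicator = nm, class = seq_len(x$k),
                     category = NA_integer_, estimate = p$mean),
      tibble::tibble(term = "variance", indicator = nm, class = seq_len(x$k),
                     category = NA_integer_, estimate = p$var)
    )
  })
  dplyr::bind_rows(pi_rows, ord_rows, cont_rows)
}

#' @rdname tidy.lca_fit
#' @method glance lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  post <- class_posterior(x)
  ap <- suppressWarnings(avepp(post))
  ic <- information_criteria(x)
  dplyr::mutate(ic,
                min_avepp = suppressWarnings(min(ap, na.rm = TRUE)),
                entropy = 1 - sum(-post * log(pmax(post, 1e-300))) /
                  (nrow(post) * log(max(x$k, 2))),
                converged = x$converged, n = x$n_effective)
}

#' Tidy a BCH distal fit
#'
#' @param x A [fit_distal()] object.
#' @param ... Unused.
#' @return Pairwise class contrasts: `contrast`, `diff`, `se`, 95% and 99%
#'   confidence bounds, `smd`.
#' @method tidy distal_fit
#' @export
tidy.distal_fit <- function(x, ...) x$contrasts

#' @rdname tidy.distal_fit
#' @method glance distal_fit
#' @export
glance.distal_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(outcome = x$outcome, n = x$n, n_clusters = x$n_clusters),
    x$wald
  )
}

#' Tidy a twin biometric fit
#'
#' @param x A [fit_biometric()] object.
#' @param ... Unused.
#' @return Standardized variance shares with confidence intervals, plus the
#'   total variance row.
#' @method tidy biometric_fit
#' @export
tidy.biometric_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$shares,
    tibble::tibble(component = "total", estimate = x$total,
                   conf_low = x$total_ci[1], conf_high = x$total_ci[2])
  )
}

#' @rdname tidy.biometric_fit
#' @method glance biometric_fit
#' @export
glance.biometric_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, loglik = x$loglik, n_params = x$n_params,
    n_pairs_mz = x$n_pairs[["MZ"]], n_pairs_dz = x$n_pairs[["DZ"]],
    converged = x$convergence
  )
}
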