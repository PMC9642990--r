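#' Profile plot of a latent class solution
#'
#' Continuous indicators as class-mean lines, ordinal indicators as the
#' probability of the highest category, faceted by indicator.
#'
#' @param object An [fit_lca()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lca_fit
#' @export
autoplot.lca_fit <- function(object, ...) {
  td <- tidy(object)
  top_cat <- td |>
    dplyr::filter(.data$term == "prob") |>
    dplyr::group_by(.data$indicator) |>
    dplyr::filter(.data$category == max(.data$category)) |>
    dplyr::ungroup() |>
    dplyr::mutate(value = .data$estimate, panel = "P(top category)")
  means <- td |>
    dplyr::filter(.data$term == "mean") |>
    dplyr::mutate(value = .data$estimate, panel = "class mean")
  dat <- dplyr::bind_rows(top_cat, means) |>
    dplyr::mutate(class = factor(paste0("C", .data$class)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$indicator, y = .data$value,
                                    colour = .data$class,
                                    group = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Class-contrast plot for a distal outcome
#'
#' Pairwise covariate-adjusted mean differences with 95% intervals.
#'
#' @param object A [fit_distal()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distal_fit
#' @export
autoplot.distal_fit <- function(object, ...) {
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(x = .data$diff, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low95,
                                          xmax = .data$conf.high95)) +
    ggplot2::labs(x = sprintf("difference in %s", object$outcome), y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked shared/unique variance decomposition plot
#'
#' Displays, per outcome, the proportions of total outcome variance that
#' are genetic or environmental, shared with or unique to the latent
#' lifestyle classes.
#'
#' @param decomposition Tibble from `run_pipeline()$decomposition` or
#'   rows of [decompose_shared()] with an `outcome` column.
#' @param clamp_zero Clamp small negative shares to zero for display.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition, clamp_zero = TRUE) {
  long <- decomposition |>
    dplyr::select("outcome", "shared_genetic", "shared_environment",
                  "unique_genetic", "unique_environment") |>
    tidyr::pivot_longer(-"outcome", names_to = "component",
                        values_to = "proportion")
  if (clamp_zero) long$proportion <- pmax(long$proportion, 0)
  long$component <- factor(
    long$component,
    levels = c("shared_genetic", "shared_environment",
               "unique_genetic", "unique_environment")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$proportion,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Paired") +
    ggplot2::labs(x = NULL, y = "proportion of total variance") +
    ggplot2::theme_minimal()
}
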