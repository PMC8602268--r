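#' Plot a mutation context spectrum
#'
#' Bar chart of per-context counts in catalog order; SBS96 panels are
#' coloured by substitution type as is conventional for signature plots.
#'
#' @param mat Spectrum matrix (contexts x clones) from
#'   [build_spectrum_matrix()].
#' @param var_class Variant class of the catalog.
#' @param clones Optional subset of clone columns to show.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(mat, var_class = "SBS", clones = NULL) {
  tbl <- spectrum_as_tibble(mat, var_class)
  if (!is.null(clones)) tbl <- filter(tbl, .data$clone_id %in% clones)
  tbl$context <- factor(tbl$context, levels = rownames(mat))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$context,
                                         y = .data$count)) +
    ggplot2::facet_wrap(~clone_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 4.5,
                                                       vjust = 0.5))
  if (var_class == "SBS") {
    tbl$sub <- substr(as.character(tbl$context), 3, 5)
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$sub),
                               data = tbl, show.legend = TRUE) +
      ggplot2::labs(fill = "substitution")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p
}

#' Plot relative signature contributions as stacked bars
#'
#' @param fits Tibble from [fit_signatures()].
#' @return A ggplot object (clones on x, stacked relative contributions).
#' @export
plot_signature_contributions <- function(fits) {
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$clone_id,
                                     y = .data$relative,
                                     fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative contribution",
                  fill = "signature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot burden regressions against age
#'
#' Draws per-clone mutation counts against donor age with each group's
#' zero-intercept regression line.
#'
#' @param object A `burden_fit` or list of them.
#' @param data Tibble with `count`, `age`, `group` used for the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_fit
#' @export
autoplot.burden_fit <- function(object, data = NULL, ...) {
  fits <- if (inherits(object, "burden_fit")) list(object) else object
  lines <- purrr::map(fits, function(f) {
    tibble(group = f$group, slope = f$m)
  }) |> bind_rows()
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope, intercept = 0,
                                      colour = .data$group)) +
    ggplot2::labs(x = "age (years)", y = "mutations",
                  colour = "group") +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$age, y = .data$count, colour = .data$group)
    )
  }
  p
}

#' Plot a simulated power curve
#'
#' @param power_tbl Tibble from [power_simulation()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(power_tbl) {
  ggplot2::ggplot(power_tbl, ggplot2::aes(x = .data$multiplier,
                                          y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = power_tbl$alpha[1], linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "slope multiplier (effect size)",
                  y = "rejection fraction") +
    ggplot2::theme_minimal()
}
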