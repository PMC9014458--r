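#' Plot a population-weighted conformer table
#'
#' Bars show the equilibrium fraction of each conformer; points show its
#' vertical detachment energy on a secondary axis, with the
#' population-weighted VDE as a dashed line.
#'
#' @param object A [build_thermo_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thermo_table
#' @export
autoplot.thermo_table <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$label <- factor(df$label, levels = df$label[order(-df$x_m)])
  wvde <- attr(object, "weighted_vde")
  scale <- max(df$x_m) / max(df$vde)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$x_m), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$vde * scale), colour = "firebrick") +
    ggplot2::geom_hline(
      yintercept = wvde * scale,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(
      name = "equilibrium fraction x_m",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "VDE (eV)")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the per-water binding energy vs VDE-shift regression
#'
#' @param object An [ols_fit()], e.g. from [wbe_vde_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ols_fit
#' @export
autoplot.ols_fit <- function(object, ...) {
  d <- object$data
  xl <- if ("shift" %in% names(d)) "incremental VDE shift (eV)" else "x"
  yl <- if ("wbe_per_water" %in% names(d)) "WBE per water (kcal/mol)" else "y"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    ) +
    ggplot2::annotate("text",
      x = min(d$x), y = max(d$y), hjust = 0,
      label = sprintf("R^2 == %.3f", object$r_squared), parse = TRUE
    ) +
    ggplot2::labs(x = xl, y = yl) +
    ggplot2::theme_minimal()
}

#' Plot hydration-site occupancies
#'
#' @param occ A [site_occupancy()] result (or a named list of them, one per
#'   cluster size).
#' @return A ggplot object.
#' @export
plot_site_occupancy <- function(occ) {
  if (!inherits(occ, "data.frame")) {
    occ <- purrr::imap_dfr(occ, ~ dplyr::mutate(.x, n_waters = .y))
  }
  p <- ggplot2::ggplot(
    occ,
    ggplot2::aes(
      x = factor(.data$site, levels = HYDRATION_SITES),
      y = .data$weighted_count
    )
  ) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "hydration site", y = "population-weighted waters") +
    ggplot2::theme_minimal()
  if ("n_waters" %in% names(occ)) {
    p <- p + ggplot2::facet_wrap(~n_waters, labeller = ggplot2::label_both)
  }
  p
}
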