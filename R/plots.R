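#' Plot the accumulation-permeability regression
#'
#' Scatter of `ln(accumulation)` against `ln(percent of glycine)` with
#' the fitted regression line, coloured by net charge when available.
#'
#' @param object A `porin_loglog` from [loglog_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.porin_loglog <- function(object, ...) {
  df <- dplyr::mutate(
    object$data,
    log_percent = log(.data$percent),
    log_accumulation = log(.data$accumulation)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$log_percent,
                                        .data$log_accumulation))
  if ("net_charge" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$net_charge)), alpha = 0.8
    ) + ggplot2::labs(colour = "net charge (e)")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, linewidth = 0.7) +
    ggplot2::labs(
      x = "ln predicted permeability (% of glycine)",
      y = "ln accumulation (nmol per 1e12 CFUs)",
      title = sprintf("R = %.2f (n = %d, p = %.2g)", object$r, object$n,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.porin_loglog
#' @export
autoplot.porin_report <- function(object, ...) {
  if (is.null(object$regression)) {
    abort("report has no fitted regression to plot")
  }
  autoplot(object$regression, ...)
}

#' Descriptor distributions by category
#'
#' Boxplots of the four permeation descriptors (net charge, total and
#' transversal dipole, minimal projection area) grouped by accumulation
#' or predicted-permeability category.
#'
#' @param records Scored, categorised compound tibble (e.g.
#'   `report$per_compound`).
#' @param group Grouping column: `"accumulation_category"` or
#'   `"category"` (predicted permeability).
#' @return A ggplot object.
#' @export
plot_descriptor_distributions <- function(records,
                                          group = c("accumulation_category",
                                                    "category")) {
  group <- match.arg(group)
  if (!group %in% names(records)) {
    abort(paste0("records lack the grouping column ", group))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(records, dplyr::all_of(group), "net_charge",
                  "total_dipole", "transversal_dipole", "mpa_mean"),
    cols = -dplyr::all_of(group),
    names_to = "descriptor", values_to = "value"
  )
  long$descriptor <- factor(
    long$descriptor,
    levels = c("net_charge", "total_dipole", "transversal_dipole",
               "mpa_mean"),
    labels = c("net charge (e)", "total dipole (D)",
               "transversal dipole (D)", "minimal projection area (A^2)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[group]], .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
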