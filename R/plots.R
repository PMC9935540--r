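#' Plot a functional space with its functional triangles
#'
#' PC1-PC2 scatter of all simulations, coloured by load scenario, with
#' per-specimen triangles drawn as closed polygons and the quadrant axes
#' as reference lines (low-stress simulations sit left of the vertical
#' axis by the ordination's sign convention).
#'
#' @param object a `functional_space` from [ordinate()].
#' @param triangles optionally, the result of [functional_triangles()];
#'   computed from `object` when `TRUE` (default).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot functional_space
#' @export
autoplot.functional_space <- function(object, triangles = TRUE, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50")
  if (isTRUE(triangles) || is.list(triangles)) {
    if (isTRUE(triangles)) triangles <- functional_triangles(object)
    poly <- dplyr::bind_rows(lapply(triangles, function(tr)
      tibble::tibble(specimen_id = as.character(tr$specimen_id),
                     pc1 = tr$vertices[, 1L], pc2 = tr$vertices[, 2L])))
    p <- p + ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(group = .data$specimen_id),
      fill = NA, colour = "grey30", linewidth = 0.3)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$scenario), size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2L]),
      colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Volume-weighted stress histogram of a field
#'
#' @param object a [stress_field()].
#' @param bins number of bins.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot stress_field
#' @export
autoplot.stress_field <- function(object, bins = 50, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$vm_mpa,
                               weight = .data$volume_mm3)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "von Mises stress (MPa)",
                  y = "volume (mm³)") +
    ggplot2::theme_minimal()
}

#' Scatter and fitted line of an OLS regression result
#'
#' @param object a `regression_result` from [regress_ols()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot regression_result
#' @export
autoplot.regression_result <- function(object, ...) {
  df <- attr(object, "model_frame")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = object$x_label, y = object$y_label,
      subtitle = sprintf("R² = %.3f, p = %.3g, n = %d",
                         object$r_squared, object$p_value, object$n)) +
    ggplot2::theme_minimal()
}
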