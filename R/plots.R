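## ggplot2 views of the main result types.

image_raster_layer <- function(image) {
  d <- dim(image)
  ggplot2::annotation_raster(grDevices::as.raster(image),
                             xmin = 0, xmax = d[2], ymin = -d[1], ymax = 0)
}

#' Plot a slide with its annotations
#'
#' Image raster with ground-truth polygons coloured by class; y runs down
#' as in pixel coordinates.
#'
#' @param object a [generate_slide()] bundle.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gt_bundle
#' @export
autoplot.gt_bundle <- function(object, ...) {
  d <- dim(object$image)
  polys <- purrr::imap_dfr(object$annotations$polygon, function(p, i) {
    tibble::tibble(x = p[, 1], y = p[, 2], id = i,
                   label = object$annotations$label[i])
  })
  gg <- ggplot2::ggplot() +
    image_raster_layer(object$image) +
    ggplot2::coord_fixed(xlim = c(0, d[2]), ylim = c(-d[1], 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px, down)", colour = "class") +
    ggplot2::theme_minimal()
  if (nrow(polys) > 0) {
    gg <- gg + ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(x = .data$x, y = -.data$y, group = .data$id,
                   colour = .data$label),
      fill = NA, linewidth = 0.4)
  }
  gg
}

#' Plot candidates over a slide
#'
#' @param image RGB array.
#' @param candidates candidate tibble (uses `contextual_score`).
#' @return a ggplot.
#' @export
plot_candidates <- function(image, candidates) {
  d <- dim(image)
  ggplot2::ggplot() +
    image_raster_layer(image) +
    ggplot2::geom_point(
      data = candidates,
      ggplot2::aes(x = .data$x, y = -.data$y, size = .data$contextual_score),
      shape = 1, colour = "red", stroke = 1) +
    ggplot2::coord_fixed(xlim = c(0, d[2]), ylim = c(-d[1], 0), expand = FALSE) +
    ggplot2::scale_size_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "x (px)", y = "y (px, down)", size = "score") +
    ggplot2::theme_minimal()
}

#' Plot ranked set scores of a case
#'
#' @param object an [build_image_sets()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot image_sets
#' @export
autoplot.image_sets <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$set_rank),
                                       y = .data$set_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "set rank", y = "set AI score") +
    ggplot2::theme_minimal()
}

#' Plot cohort consultation statistics
#'
#' Per-observer consultation rates and the exactly-k cross-observer
#' distribution.
#'
#' @param object a [consultation_statistics()] report.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  cross <- object$cross_observer
  ggplot2::ggplot(cross, ggplot2::aes(x = factor(.data$k),
                                      y = .data$n_cases_exactly_k)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "observers requiring consultation (exactly k)",
                  y = "cases") +
    ggplot2::theme_minimal()
}
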