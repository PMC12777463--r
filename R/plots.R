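#' Plot a spatial slide
#'
#' Cells coloured by type; marker-positive cells drawn on top as black
#' open circles. Useful for eyeballing planted enrichment.
#'
#' @param slide A slide tibble.
#' @param point_size Point size for the background cells.
#' @return A ggplot.
#' @export
plot_slide <- function(slide, point_size = 0.3) {
  pos <- slide[which(as.logical(slide$positive %||% FALSE)), , drop = FALSE]
  ggplot2::ggplot(slide, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$cell_type)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::geom_point(data = pos, shape = 21, size = 3, stroke = 1,
                        colour = "black", fill = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "cell type") +
    ggplot2::theme_minimal()
}
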