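# Plot methods for the remaining result types.

#' Abundance-distribution plot of a tag library
#'
#' @param object A `tag_library`.
#' @param ... Unused.
#' @return A ggplot of the percentage of distinct tags and total tag mass
#'   per copy-number bin.
#' @exportS3Method ggplot2::autoplot
autoplot.tag_library <- function(object, ...) {
  abundance_distribution(object) |>
    tidyr::pivot_longer(c("distinct_pct", "total_pct"),
                        names_to = "measure", values_to = "pct") |>
    mutate(bin = factor(.data$bin, levels = c("2-5", "5-100", ">100"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin, y = .data$pct,
                                 fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tag copy number", y = "% of tags", fill = NULL)
}

#' Category-composition plot of a mapping result
#'
#' @param object A `mapping_result`.
#' @param ... Unused.
#' @return A ggplot of tag mass and distinct tags per mapping category.
#' @exportS3Method ggplot2::autoplot
autoplot.mapping_result <- function(object, ...) {
  object$category_summary |>
    tidyr::pivot_longer(c("total", "distinct"), names_to = "measure",
                        values_to = "n") |>
    mutate(category = factor(.data$category, levels = MAP_CATEGORIES)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$category, y = .data$n,
                                 fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "tags", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Saturation-curve plot
#'
#' @param curve Output of [saturation_curve()].
#' @return A ggplot of detected genes against subsampling depth, with the
#'   plateau depth marked when present.
#' @export
plot_saturation <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth,
                                           y = .data$detected_genes)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sequenced tags", y = "detected genes")
  plateau <- attr(curve, "plateau_depth")
  if (!is.na(plateau %||% NA)) {
    p <- p + ggplot2::geom_vline(xintercept = plateau, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
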