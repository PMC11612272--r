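#' Plot a tissue label map
#'
#' Raster plot with a fixed anatomical palette (epithelium pinks, lamina
#' propria peach, lumen pale, muscle gray, artifact black).
#'
#' @param map A [label_map()].
#' @return A ggplot.
#' @export
plot_label_map <- function(map) {
  legend <- map_legend(map)
  pal <- c(
    background = "#ffffff", villous_epithelium = "#c94f7c",
    crypt_epithelium = "#7b2d5e", crypt_lumen = "#f3e6d8",
    lamina_propria = "#f2b880", blood_vessel = "#d0312d",
    muscularis_mucosa = "#9a8c98", other_tissue = "#cdb4db",
    artifact = "#222222"
  )
  df <- tibble::tibble(
    x = as.vector(col(map)), y = as.vector(row(map)),
    class = factor(names(legend)[match(as.vector(map), legend)],
                   levels = names(legend))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = pal, drop = TRUE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tissue class") +
    ggplot2::theme_void()
}

#' Plot one HIF against the modified Marsh grade
#'
#' Box plot with jittered per-slide points, the standard view for ordinal
#' grade correlation.
#'
#' @param hif_table Feature tibble (one row per slide).
#' @param metadata Tibble with `slide_id` and `grade`.
#' @param feature Feature column name.
#' @return A ggplot.
#' @export
plot_feature_vs_grade <- function(hif_table, metadata, feature) {
  stopifnot(feature %in% names(hif_table))
  df <- tibble::tibble(
    grade = factor(align_metadata(hif_table, metadata, "grade"),
                   levels = marsh_levels()),
    value = hif_table[[feature]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = "modified Marsh grade", y = feature) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hif_correlations <- function(object, ...) {
  df <- object[!is.na(object$rho), , drop = FALSE]
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Spearman rho vs. Marsh grade", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dawid_skene <- function(object, ...) {
  df <- tidy.dawid_skene(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emitted_class,
                                   y = .data$true_class,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#7b2d5e",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~labeler_id) +
    ggplot2::labs(x = "emitted label", y = "consensus class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
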