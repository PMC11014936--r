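#' Dot plot of per-well Actin scores by role
#'
#' The validation-plate view: one point per well, grouped by well role, so
#' the separation between DMSO and positive-control wells (the assay
#' window behind CV and Z') is visible at a glance.
#'
#' @param measurements Measurement tibble.
#' @return A ggplot.
#' @export
plot_plate_scores <- function(measurements) {
  ggplot2::ggplot(
    measurements %>% filter(is.finite(.data$actin_score)),
    ggplot2::aes(x = .data$kind, y = .data$actin_score, colour = .data$kind)
  ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Actin score") +
    ggplot2::theme_minimal()
}

#' Plate-map heatmap of Actin scores
#'
#' @param measurements Measurement tibble for one plate.
#' @return A ggplot (16 x 24 tile map).
#' @export
plot_platemap <- function(measurements) {
  d <- measurements %>%
    mutate(row = substr(.data$well, 1, 1),
           col = as.integer(substr(.data$well, 2, 3)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$actin_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(LETTERS[1:16])) +
    ggplot2::labs(x = "column", y = "row", fill = "Actin score") +
    ggplot2::theme_minimal()
}

#' @method autoplot hit_list
#' @export
autoplot.hit_list <- function(object, ...) {
  stats <- attr(object, "plate_stats")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$plate_id, y = .data$actin_score)) +
    ggplot2::geom_jitter(width = 0.1, colour = "firebrick", alpha = 0.7) +
    ggplot2::geom_point(data = stats,
                        ggplot2::aes(y = .data$threshold),
                        shape = 95, size = 8, colour = "black") +
    ggplot2::labs(x = NULL, y = "Actin score",
                  title = "Hits below the plate-wise mean − k·SD threshold") +
    ggplot2::theme_minimal()
}

#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  ggplot2::ggplot(object$tiers,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$tier),
                               y = .data$n_selected)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_selected), vjust = -0.3) +
    ggplot2::labs(x = "screening tier", y = "compounds selected") +
    ggplot2::theme_minimal()
}

#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot volcano_result
#' @export
autoplot.volcano_result <- function(object, p_cut = 0.05, fc_cut = 1, ...) {
  d <- as_tibble(object) %>%
    mutate(status = dplyr::case_when(
      .data$p_value < p_cut & .data$log2_fc <= -fc_cut ~ "down",
      .data$p_value < p_cut & .data$log2_fc >= fc_cut ~ "up",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(down = "steelblue", ns = "grey70",
                                            up = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  r <- object$cor_matrix
  d <- as_tibble(r, rownames = "item1") %>%
    tidyr::pivot_longer(-"item1", names_to = "item2", values_to = "r")
  ord <- object$order
  d$item1 <- factor(d$item1, levels = ord)
  d$item2 <- factor(d$item2, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$item1, y = .data$item2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Marker fold-change heatmap of the tertiary panel
#'
#' @param expr Tibble `compound_id`, `dose_nM`, `gene`, `fold_change`.
#' @return A ggplot tile map, compounds by (gene, dose), log2 colour
#'   scale centred on the DMSO value of 1.
#' @export
plot_marker_heatmap <- function(expr) {
  ggplot2::ggplot(
    expr %>% mutate(cell = paste0(.data$gene, "\n", .data$dose_nM, " nM")),
    ggplot2::aes(x = .data$cell, y = .data$compound_id,
                 fill = log2(.data$fold_change))
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 fold\nvs DMSO") +
    ggplot2::theme_minimal()
}
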