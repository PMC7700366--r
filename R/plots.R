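#' Heatmap of mean copy-number scores
#'
#' Genes on the y axis (registry order, top first), cancers on the x axis in
#' ascending median-overall-survival order, diverging fill from deletion
#' (blue) through diploid (white) to amplification (red).
#'
#' @param heatmap Wide gene-by-cancer tibble from [gistic_heatmap()].
#' @return A ggplot object.
#' @export
plot_gistic_heatmap <- function(heatmap) {
  long <- tidyr::pivot_longer(heatmap, -"gene", names_to = "cancer",
                              values_to = "mean_call")
  long$gene <- factor(long$gene, levels = rev(heatmap$gene))
  long$cancer <- factor(long$cancer, levels = names(heatmap)[-1])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cancer, y = .data$gene,
                                     fill = .data$mean_call)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-2, 2),
                                  name = "mean call") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Mean thresholded copy-number score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn de_map Tile map of up/down/ns calls (red = up in tumor,
#'   green = down, white = not significant).
#' @param object,x An `aars_de_map`.
#' @param ... Unused.
#' @exportS3Method
autoplot.aars_de_map <- function(object, ...) {
  res <- object$results
  res$gene <- factor(res$gene, levels = rev(unique(res$gene)))
  res$cancer <- factor(res$cancer, levels = object$cancer_order)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$cancer, y = .data$gene,
                                    fill = .data$call)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(values = c(up = "#B2182B", down = "#1B7837",
                                          ns = "white"), name = NULL) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tumor vs normal differential expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn survival_map Tile map of log2 hazard ratios; significant
#'   cells (q below the map threshold) are outlined in black.
#' @param object,x An `aars_surv_map`.
#' @param ... Unused.
#' @exportS3Method
autoplot.aars_surv_map <- function(object, ...) {
  res <- object$results
  res$gene <- factor(res$gene, levels = rev(unique(res$gene)))
  res$cancer <- factor(res$cancer, levels = object$cancer_order)
  res$log2_hr <- log2(res$hazard_ratio)
  res$signif <- res$direction != "ns"
  ggplot2::ggplot(res, ggplot2::aes(x = .data$cancer, y = .data$gene)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log2_hr), color = "grey85") +
    ggplot2::geom_tile(data = res[res$signif, ], fill = NA,
                       color = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "log2 HR",
                                  na.value = "grey92") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Expression-stratified survival map") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn composite_rank Bar chart of composite scores by rank
#'   (most favorable gene first).
#' @param object,x An `aars_ranking`.
#' @param ... Unused.
#' @exportS3Method
autoplot.aars_ranking <- function(object, ...) {
  s <- object$scores
  s$gene <- factor(s$gene, levels = s$gene)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$gene, y = .data$composite,
                                  fill = .data$composite)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient2(low = "#1B7837", mid = "grey85",
                                  high = "#B2182B", midpoint = 0.5,
                                  guide = "none") +
    ggplot2::labs(x = NULL, y = "composite score",
                  title = "Gene ranking: cancer-inhibiting to cancer-promoting") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
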