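# ggplot2 views of the main result types.

#' Plot a ROC curve
#'
#' @param labels 0/1 or `"active"`/`"inactive"` labels.
#' @param scores Numeric scores.
#' @return A ggplot object showing the ROC curve with the AUC in the
#'   subtitle.
#' @export
plot_roc <- function(labels, scores) {
  x <- check_labels_scores(labels, scores)
  ord <- order(x$scores, decreasing = TRUE)
  tpr <- cumsum(x$labels[ord] == 1) / sum(x$labels == 1)
  fpr <- cumsum(x$labels[ord] == 0) / sum(x$labels == 0)
  d <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "ROC curve",
                  subtitle = sprintf("ROC-AUC = %.3f",
                                     roc_auc(x$labels, x$scores))) +
    ggplot2::theme_minimal()
}

#' @describeIn run_grid Heatmap of validation ROC-AUC over the grid, with
#'   the best cell marked.
#' @param object A `pcm_grid`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pcm_grid <- function(object, ...) {
  best <- attr(object, "best")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = factor(.data$n_per_target),
                                    y = factor(.data$train_fraction),
                                    fill = .data$roc_auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "ROC-AUC") +
    ggplot2::labs(x = "Oversampling per target", y = "Train fraction",
                  title = "Validation ROC-AUC over the evaluation grid") +
    ggplot2::theme_minimal()
  if (!is.null(best)) {
    p <- p + ggplot2::geom_tile(
      data = best,
      ggplot2::aes(x = factor(.data$n_per_target),
                   y = factor(.data$train_fraction)),
      fill = NA, colour = "red", linewidth = 1)
  }
  p
}

#' @describeIn build_network Chemical-space network plot: compounds as
#'   nodes colored by best-scoring target, matched pairs as edges.
#' @param object A `csn_network`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.csn_network <- function(object, ...) {
  set.seed(1)  # layout only; results are unaffected
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes
  nodes$x <- lay[match(nodes$id, igraph::V(object$graph)$name), 1]
  nodes$y <- lay[match(nodes$id, igraph::V(object$graph)$name), 2]
  edges <- object$edges
  seg <- tibble(
    x = nodes$x[match(edges$compound_a, nodes$id)],
    y = nodes$y[match(edges$compound_a, nodes$id)],
    xend = nodes$x[match(edges$compound_b, nodes$id)],
    yend = nodes$y[match(edges$compound_b, nodes$id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$best_target,
                                     size = .data$best_score)) +
    ggplot2::scale_size_continuous(range = c(0.5, 3), name = "best score") +
    ggplot2::labs(colour = "best target",
                  title = "Matched-molecular-pair chemical space") +
    ggplot2::theme_void()
}
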