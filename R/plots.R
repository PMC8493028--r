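#' Plot ROC curves of a multiclass AUC result
#'
#' One-vs-rest ROC per class with the pooled micro-averaged curve emphasized.
#'
#' @param object An [multiclass_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.auc_result <- function(object, ...) {
  roc <- object$roc
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    color = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::geom_step(
      data = roc[roc$class == "micro", ],
      linewidth = 1
    ) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Micro-averaged AUC = %.3f", object$micro_auc),
      color = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of clustered expression profiles
#'
#' Specimens follow the canonical dendrogram leaf order; values are per-gene
#' centered delta-Ct (red over-expressed, blue under-expressed relative to
#' the gene mean).
#'
#' @param object An [cluster_expression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_clustering <- function(object, ...) {
  m <- object$centered[object$order, , drop = FALSE]
  long <- tibble(
    specimen = factor(rep(rownames(m), times = ncol(m)),
                      levels = rownames(m)),
    gene = rep(colnames(m), each = nrow(m)),
    value = as.numeric(m)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$specimen, y = .data$gene,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Centered\ndelta-Ct") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
}

#' Bar chart of the calibrated similarity scores of one specimen
#'
#' @param scores Long score tibble from [score_specimens()].
#' @param specimen Specimen id to plot; defaults to the first.
#' @return A ggplot.
#' @export
plot_similarity_scores <- function(scores, specimen = NULL) {
  specimen <- specimen %||% scores$specimen_id[1]
  one <- scores[scores$specimen_id == specimen, ]
  if (nrow(one) == 0) abort(sprintf("Specimen '%s' not in scores.", specimen))
  one$class <- stats::reorder(one$class, one$score)
  ggplot2::ggplot(one, ggplot2::aes(x = .data$score, y = .data$class)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Similarity score (all classes sum to 100)", y = NULL,
      title = sprintf("Specimen %s", specimen)
    ) +
    ggplot2::theme_minimal()
}
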