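#' Volcano plot of a differential-expression table
#'
#' @param object A [fit_moderated_de()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.methdx_de <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$adj_p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold-change (case - control)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Delta-beta distribution with pooled decile thresholds
#'
#' @param object A [call_dmgs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.methdx_dm <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta, fill = .data$call)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(hyper = "firebrick", hypo = "steelblue",
                                          none = "grey60")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(case - control)"), y = "genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' AUC versus number of genes for an incremental classifier
#'
#' @param object A [incremental_selection()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.methdx_classifier <- function(object, ...) {
  ggplot2::ggplot(object$auc_by_k, ggplot2::aes(x = .data$k, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "number of genes (by importance rank)",
                  y = "leave-one-out AUC",
                  title = sprintf("%s view: best k = %d (AUC %.3f)",
                                  object$kind, object$best_k, object$auc)) +
    ggplot2::theme_minimal()
}

#' ROC curve for a set of out-of-fold scores
#'
#' @param scores A [loo_scores()] tibble (or anything [roc_points()]
#'   accepts).
#' @param case Positive-class label.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, case = "case") {
  pts <- roc_points(scores, case = case)
  a <- roc_auc(scores, case = case)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f, p = %.2g)", a$auc, a$p_value)) +
    ggplot2::theme_minimal()
}

#' Region-distribution bar plot of the four integration groups
#'
#' @param object A [region_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.methdx_region_dist <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"group",
                              names_to = "region", values_to = "n_genes")
  long$region <- factor(long$region, levels = region_levels())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$n_genes,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
}
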