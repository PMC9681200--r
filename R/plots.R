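#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_col
#'   geom_violin facet_wrap labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' ROC curve of an evaluation
#'
#' @param object A `depnet_evaluation` with per-gene scores.
#' @param ... Unused.
#' @return A ggplot: the ROC polyline with the chance diagonal, titled with
#'   the AUC.
#' @export
autoplot.depnet_evaluation <- function(object, ...) {
  if (isTRUE(object$empty)) {
    stopf("cannot plot an empty evaluation", class = "depnet_argument_error")
  }
  roc <- roc_points(object$scores$likelihood, object$scores$label)
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#c0392b", linewidth = 0.8) +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f, n = %d)", object$auc, object$n_test)
    ) +
    theme_minimal()
}

#' Leave-one-feature-out importance plot
#'
#' @param object A `depnet_importance` table from [feature_importance_loo()].
#' @param ... Unused.
#' @return A ggplot bar chart of the validation accuracy drop per omitted
#'   feature, sorted.
#' @export
autoplot.depnet_importance <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$accuracy_drop)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot(df, aes(x = .data$feature, y = .data$accuracy_drop)) +
    geom_col(fill = "#2c3e50") +
    coord_flip() +
    labs(x = NULL, y = "Decrease in validation accuracy when omitted",
         title = "Leave-one-feature-out importance") +
    theme_minimal()
}

#' Class-conditional feature distributions
#'
#' Violin plots of each topology feature split by essentiality label — the
#' visual check of which features separate essential from non-essential
#' genes.
#'
#' @param features A (normalized) feature table.
#' @param labels Named binary vector (names = gene IDs).
#' @return A faceted ggplot.
#' @export
plot_feature_distributions <- function(features, labels) {
  features <- as_tibble(features)
  df <- features |>
    dplyr::filter(.data$gene_id %in% names(labels)) |>
    dplyr::mutate(class = ifelse(labels[.data$gene_id] == 1,
                                 "essential", "non-essential")) |>
    tidyr::pivot_longer(dplyr::all_of(intersect(DEPNET_FEATURES,
                                                names(features))),
                        names_to = "feature", values_to = "value")
  ggplot(df, aes(x = .data$class, y = .data$value, fill = .data$class)) +
    geom_violin(scale = "width", show.legend = FALSE) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = "Feature value (normalized)") +
    theme_minimal()
}
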