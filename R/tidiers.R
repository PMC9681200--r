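#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dependency classifier
#'
#' Returns the forest's internal per-feature importance (mean decrease in
#' Gini impurity) as one row per feature.
#'
#' @param x A `depnet_classifier`.
#' @param ... Unused.
#' @return A tibble with `feature` and `gini_importance`.
#' @export
tidy.depnet_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp), gini_importance = unname(imp[, 1L])) |>
    dplyr::arrange(dplyr::desc(.data$gini_importance))
}

#' @rdname tidy.depnet_classifier
#' @return For `glance()`: a one-row tibble with the fit's provenance
#'   (cell line, trees, `mtry`, training size, validation AUC, seed).
#' @export
glance.depnet_classifier <- function(x, ...) {
  tibble(
    cell_line_id = x$provenance$cell_line_id,
    ntree = x$provenance$ntree,
    mtry = x$provenance$mtry,
    n_train = length(x$training_genes),
    validation_auc = x$provenance$validation_auc,
    seed = x$provenance$seed
  )
}

#' Tidy an evaluation report
#'
#' @param x A `depnet_evaluation` from [cross_evaluate()].
#' @param ... Unused.
#' @return For `tidy()`: the per-gene scores (gene, likelihood, label); for
#'   `glance()`: a one-row summary (AUC, test size, overlap removed,
#'   stratum, train/test cell lines).
#' @export
tidy.depnet_evaluation <- function(x, ...) x$scores

#' @rdname tidy.depnet_evaluation
#' @export
glance.depnet_evaluation <- function(x, ...) {
  tibble(
    auc = x$auc, n_test = x$n_test, n_removed = x$n_removed,
    empty = isTRUE(x$empty), stratum = x$stratum,
    train_cell_line = as.character(x$train_cell_line %||% NA),
    test_cell_line = as.character(x$test_cell_line %||% NA)
  )
}

#' Tidy a screen concordance result
#'
#' @param x A `depnet_concordance` from [screen_concordance()].
#' @param ... Unused.
#' @return For `tidy()`: one row per confusion cell; for `glance()`: a
#'   one-row tibble of the headline metrics and helper counts.
#' @export
tidy.depnet_concordance <- function(x, ...) {
  tibble(
    predicted = c("essential", "essential", "non-essential", "non-essential"),
    experimental = c("essential", "non-essential", "essential", "non-essential"),
    n = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' @rdname tidy.depnet_concordance
#' @export
glance.depnet_concordance <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, sensitivity = x$sensitivity, fdr = x$fdr,
    n_classified = x$n_classified, n_unclassified = x$n_unclassified,
    top_k_negative_z = x$top_k_negative_z, n_below_z = x$n_below_z,
    below_z_and_predicted = x$below_z_and_predicted
  )
}
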