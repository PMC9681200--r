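#' Train a random-forest dependency classifier
#'
#' Fits a random forest on the balanced training partition of one cell line
#' (or a super training set), with the number of candidate features per
#' split tuned on the validation partition only. The test partition is never
#' touched during training or tuning.
#'
#' @param features A *normalized* feature table ([normalize_features()]).
#' @param split A balanced [balanced_split()] object.
#' @param hyperparams List with elements `ntree` (default 500) and
#'   `mtry_grid` (default `c(2, 3, 4)`; `sqrt(12) ~ 3.5` sits mid-grid). The
#'   grid is searched by validation AUC.
#' @param seed Integer seed; forests and tuning are reproducible.
#' @return An object of class `depnet_classifier` holding the fitted forest,
#'   the ordered feature-name list, the training gene set (for later overlap
#'   removal) and full provenance.
#' @export
train_dependency_classifier <- function(features, split,
                                        hyperparams = list(), seed = 1L) {
  stopifnot(inherits(split, "depnet_split"))
  if (!isTRUE(split$balanced)) {
    stopf("`split` must be class-balanced", class = "depnet_argument_error")
  }
  if (!isTRUE(attr(features, "normalized"))) {
    stopf("`features` must be min-max normalized before training",
          class = "depnet_argument_error")
  }
  hp <- modifyList(list(ntree = 500L, mtry_grid = c(2L, 3L, 4L)), hyperparams)
  xy_train <- feature_matrix(features, split$train, split$labels)
  xy_val <- feature_matrix(features, split$validation, split$labels)

  tune <- purrr::map_dbl(hp$mtry_grid, function(m) {
    fit <- with_seed(seed, randomForest::randomForest(
      x = xy_train$x, y = xy_train$y, ntree = hp$ntree, mtry = m
    ))
    votes <- predict(fit, xy_val$x, type = "prob")[, "1"]
    auc_rank(votes, xy_val$y == "1")
  })
  best_mtry <- hp$mtry_grid[which.max(tune)]
  fit <- with_seed(seed, randomForest::randomForest(
    x = xy_train$x, y = xy_train$y, ntree = hp$ntree, mtry = best_mtry,
    keep.forest = TRUE
  ))
  structure(
    list(
      forest = fit,
      feature_names = colnames(xy_train$x),
      training_genes = split$train,
      provenance = list(
        cell_line_id = split$cell_line_id, seed = check_seed(seed),
        ntree = hp$ntree, mtry = best_mtry,
        mtry_grid = hp$mtry_grid, validation_auc = max(tune)
      )
    ),
    class = "depnet_classifier"
  )
}

#' @export
print.depnet_classifier <- function(x, ...) {
  cat(sprintf(
    "<depnet_classifier> %s: %d trees, mtry %d, %d training genes (validation AUC %.3f)\n",
    x$provenance$cell_line_id, x$provenance$ntree, x$provenance$mtry,
    length(x$training_genes), x$provenance$validation_auc
  ))
  invisible(x)
}

# Extract an aligned (x, y) pair for a gene set; errors list missing genes.
feature_matrix <- function(features, genes, labels = NULL,
                           feature_names = DEPNET_FEATURES) {
  features <- as_tibble(features)
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols) > 0L) {
    stopf("feature table is missing column(s): %s",
          paste(missing_cols, collapse = ", "),
          class = "depnet_argument_error")
  }
  idx <- match(genes, features$gene_id)
  if (anyNA(idx)) {
    miss <- genes[is.na(idx)]
    stopf("no features for gene(s): %s%s",
          paste(head(miss, 5L), collapse = ", "),
          if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "",
          class = "depnet_argument_error")
  }
  x <- as.matrix(features[idx, feature_names])
  rownames(x) <- genes
  y <- if (!is.null(labels)) factor(labels[genes], levels = c("0", "1")) else NULL
  list(x = x, y = y)
}

#' Predict cell-essentiality likelihoods
#'
#' The likelihood of a gene being cell-essential is the fraction of trees in
#' the forest voting for the essential class.
#'
#' @param model A [train_dependency_classifier()] fit.
#' @param features Feature table whose columns match the model's feature
#'   list.
#' @return A tibble with `gene_id` and `likelihood` in `[0, 1]`.
#' @export
predict_likelihood <- function(model, features) {
  stopifnot(inherits(model, "depnet_classifier"))
  features <- as_tibble(features)
  xy <- feature_matrix(features, features$gene_id,
                       feature_names = model$feature_names)
  votes <- predict(model$forest, xy$x, type = "prob")[, "1"]
  tibble(gene_id = features$gene_id, likelihood = unname(votes))
}

#' Evaluate a classifier on (possibly foreign) test data
#'
#' Removes every gene present in the model's training set from the test set
#' before scoring, so cross-cell-line evaluations are never inflated by
#' genes the model has already seen, then computes the AUC by the rank
#' statistic over the remaining balanced test genes.
#'
#' @param model A [train_dependency_classifier()] fit.
#' @param test_features Feature table of the test cell line (normalized).
#' @param test_genes Character vector of test gene IDs.
#' @param test_labels Named binary vector (names = gene IDs) covering
#'   `test_genes`.
#' @param stratum Optional label recorded in the report.
#' @return A `depnet_evaluation` list: `auc`, `n_test`, `n_removed`,
#'   `stratum`, `train_cell_line`, `test_cell_line`, and the per-gene
#'   `scores` tibble.
#' @export
cross_evaluate <- function(model, test_features, test_genes, test_labels,
                           stratum = NA_character_) {
  stopifnot(inherits(model, "depnet_classifier"))
  kept <- setdiff(test_genes, model$training_genes)
  n_removed <- length(test_genes) - length(kept)
  stopifnot(length(intersect(kept, model$training_genes)) == 0L)
  if (length(kept) < 2L || length(unique(test_labels[kept])) < 2L) {
    return(structure(
      list(auc = NA_real_, n_test = length(kept), n_removed = n_removed,
           empty = TRUE, stratum = stratum,
           train_cell_line = model$provenance$cell_line_id,
           test_cell_line = attr(test_features, "provenance")$cell_line_id %||% NA,
           scores = tibble(gene_id = character(0), likelihood = numeric(0),
                           label = integer(0))),
      class = "depnet_evaluation"
    ))
  }
  xy <- feature_matrix(as_tibble(test_features), kept,
                       feature_names = model$feature_names)
  votes <- predict(model$forest, xy$x, type = "prob")[, "1"]
  labels <- as.integer(test_labels[kept])
  structure(
    list(
      auc = auc_rank(votes, labels),
      n_test = length(kept), n_removed = n_removed, empty = FALSE,
      stratum = stratum,
      train_cell_line = model$provenance$cell_line_id,
      test_cell_line = attr(test_features, "provenance")$cell_line_id %||% NA,
      scores = tibble(gene_id = kept, likelihood = unname(votes),
                      label = labels)
    ),
    class = "depnet_evaluation"
  )
}

#' @export
print.depnet_evaluation <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("<depnet_evaluation> stratum %s: empty (no scorable genes)\n",
                x$stratum))
  } else {
    cat(sprintf(
      "<depnet_evaluation> AUC %.3f on %d genes (%d removed as train overlap)\n",
      x$auc, x$n_test, x$n_removed
    ))
  }
  invisible(x)
}

#' Concatenate per-cell-line training data into a super training set
#'
#' Stacks the training partitions of several cell lines into one labelled
#' table; a gene may appear once per cell line, with that line's features
#' and label, tracked by a `cell_line_id` provenance column.
#'
#' @param feature_tables Named list (by cell line) of normalized feature
#'   tables.
#' @param splits Named list (by cell line) of [balanced_split()] objects.
#' @return A tibble with `gene_id`, `cell_line_id`, `label` and the 12
#'   feature columns.
#' @export
super_training_set <- function(feature_tables, splits) {
  if (length(splits) < 2L) {
    stopf("a super training set needs >= 2 cell lines",
          class = "depnet_argument_error")
  }
  stopifnot(all(names(splits) %in% names(feature_tables)))
  purrr::map_dfr(names(splits), function(cl) {
    sp <- splits[[cl]]
    xy <- feature_matrix(feature_tables[[cl]], sp$train, sp$labels)
    dplyr::bind_cols(
      tibble(gene_id = sp$train, cell_line_id = cl,
             label = as.integer(as.character(xy$y))),
      as_tibble(xy$x)
    )
  })
}

#' Train on a super training set
#'
#' Convenience wrapper fitting one forest on the stacked rows of
#' [super_training_set()]; the training gene set is the union of all stacked
#' genes, so downstream overlap removal stays conservative.
#'
#' @param super Tibble from [super_training_set()].
#' @param hyperparams,seed As in [train_dependency_classifier()].
#' @return A `depnet_classifier`.
#' @export
train_super_classifier <- function(super, hyperparams = list(), seed = 1L) {
  hp <- modifyList(list(ntree = 500L, mtry = 3L), hyperparams)
  x <- as.matrix(super[, DEPNET_FEATURES])
  y <- factor(super$label, levels = c("0", "1"))
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = hp$ntree, mtry = hp$mtry
  ))
  structure(
    list(
      forest = fit, feature_names = DEPNET_FEATURES,
      training_genes = unique(super$gene_id),
      provenance = list(
        cell_line_id = "super",
        cell_lines = unique(super$cell_line_id),
        seed = check_seed(seed), ntree = hp$ntree, mtry = hp$mtry,
        validation_auc = NA_real_, mtry_grid = hp$mtry
      )
    ),
    class = "depnet_classifier"
  )
}

#' Evaluate a classifier across dependency-rarity strata
#'
#' For each stratum (from [rarity_strata()]), restricts the test positives
#' to the stratum's genes, pairs them with an equal-sized seeded sample of
#' test negatives, and reports one AUC per stratum. Strata with no scorable
#' positives are flagged empty rather than scored.
#'
#' @param model A `depnet_classifier`.
#' @param test_features Normalized feature table of the test cell line.
#' @param test_genes,test_labels Test gene IDs and named binary labels.
#' @param strata Named list of gene sets from [rarity_strata()].
#' @param seed Seed for the negative resampling.
#' @return Named list of `depnet_evaluation` objects.
#' @export
rarity_stratified_eval <- function(model, test_features, test_genes,
                                   test_labels, strata, seed = 1L) {
  kept <- setdiff(test_genes, model$training_genes)
  pos <- kept[test_labels[kept] == 1L]
  neg <- kept[test_labels[kept] == 0L]
  out <- purrr::imap(strata, function(genes, name) {
    p <- intersect(pos, genes)
    if (length(p) == 0L || length(neg) == 0L) {
      return(structure(
        list(auc = NA_real_, n_test = 0L, n_removed = NA_integer_,
             empty = TRUE, stratum = name,
             train_cell_line = model$provenance$cell_line_id,
             test_cell_line = NA,
             scores = tibble(gene_id = character(0),
                             likelihood = numeric(0), label = integer(0))),
        class = "depnet_evaluation"
      ))
    }
    n <- with_seed(seed, sample(neg, min(length(p), length(neg))))
    cross_evaluate(model, test_features, c(p, n), test_labels, stratum = name)
  })
  out
}

#' Leave-one-feature-out importance
#'
#' Quantifies each feature's contribution by retraining the forest without
#' it (same seed protocol) and measuring the decrease in validation
#' accuracy relative to the full model. Also reports per-feature
#' class-conditional summaries (mean and median by label) describing how the
#' feature's distribution differs between essential and non-essential genes.
#'
#' @param features Normalized feature table.
#' @param split A balanced [balanced_split()].
#' @param seed Integer seed shared by all refits.
#' @param hyperparams As in [train_dependency_classifier()]; the tuning grid
#'   is collapsed to its middle value so all refits share hyperparameters.
#' @return A tibble of class `depnet_importance`: one row per feature with
#'   `accuracy_drop`, `mean_essential`, `mean_non_essential`,
#'   `median_essential`, `median_non_essential`; the full-model validation
#'   accuracy is in attribute `baseline_accuracy`.
#' @export
feature_importance_loo <- function(features, split, seed = 1L,
                                   hyperparams = list()) {
  stopifnot(inherits(split, "depnet_split"))
  feat_names <- intersect(DEPNET_FEATURES, names(as_tibble(features)))
  if (length(feat_names) < 2L) {
    stopf("leave-one-out importance needs >= 2 features",
          class = "depnet_argument_error")
  }
  hp <- modifyList(list(ntree = 500L, mtry = 3L), hyperparams)
  xy_train <- feature_matrix(features, split$train, split$labels,
                             feature_names = feat_names)
  xy_val <- feature_matrix(features, split$validation, split$labels,
                           feature_names = feat_names)
  val_accuracy <- function(cols) {
    m <- min(hp$mtry, length(cols) - 1L)
    fit <- with_seed(seed, randomForest::randomForest(
      x = xy_train$x[, cols, drop = FALSE], y = xy_train$y,
      ntree = hp$ntree, mtry = m
    ))
    pred <- predict(fit, xy_val$x[, cols, drop = FALSE])
    mean(pred == xy_val$y)
  }
  base_acc <- val_accuracy(feat_names)
  drops <- purrr::map_dbl(feat_names, function(f) {
    base_acc - val_accuracy(setdiff(feat_names, f))
  })
  cls <- split$labels[c(split$train, split$validation)]
  pool <- feature_matrix(features, names(cls), feature_names = feat_names)$x
  out <- tibble(
    feature = feat_names,
    accuracy_drop = drops,
    mean_essential = apply(pool[cls == 1L, , drop = FALSE], 2L, mean),
    mean_non_essential = apply(pool[cls == 0L, , drop = FALSE], 2L, mean),
    median_essential = apply(pool[cls == 1L, , drop = FALSE], 2L, median),
    median_non_essential = apply(pool[cls == 0L, , drop = FALSE], 2L, median)
  )
  attr(out, "baseline_accuracy") <- base_acc
  class(out) <- c("depnet_importance", class(out))
  out
}
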