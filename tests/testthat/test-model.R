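# Shared scaffolding: one small cohort, one personalized feature table and
# a balanced split, reused across the model tests.
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      cl <- names(co$profiles)[1]
      nf <- normalize_features(
        compute_node_features(personalize(co$network, co$profiles[[cl]]))
      )
      ls <- call_cell_essential(co$dependency)
      sp <- balanced_split(ls, cl, seed = 2, genes = nf$gene_id)
      cache <<- list(cohort = co, cl = cl, features = nf, labels = ls,
                     split = sp)
    }
    cache
  }
})

test_that("training is seeded, tuned on validation only, and guarded", {
  fx <- model_fixture()
  m1 <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                    hyperparams = list(ntree = 150))
  m2 <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                    hyperparams = list(ntree = 150))
  expect_identical(predict(m1$forest, type = "prob"),
                   predict(m2$forest, type = "prob"))
  expect_true(m1$provenance$mtry %in% c(2, 3, 4))
  expect_setequal(m1$feature_names, feature_names())
  expect_equal(sort(m1$training_genes), sort(fx$split$train))

  raw <- compute_node_features(personalize(fx$cohort$network,
                                           fx$cohort$profiles[[fx$cl]]))
  expect_error(train_dependency_classifier(raw, fx$split, seed = 1),
               class = "depnet_argument_error")
  unbalanced <- fx$split
  unbalanced$balanced <- FALSE
  expect_error(train_dependency_classifier(fx$features, unbalanced, seed = 1),
               class = "depnet_argument_error")
})

test_that("likelihoods are tree-vote fractions on [0,1] and need all features", {
  fx <- model_fixture()
  m <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                   hyperparams = list(ntree = 200))
  pred <- predict_likelihood(m, fx$features)
  expect_equal(nrow(pred), nrow(fx$features))
  expect_true(all(pred$likelihood >= 0 & pred$likelihood <= 1))
  # vote fractions with 200 trees are multiples of 1/200
  expect_true(all(abs(pred$likelihood * 200 -
                        round(pred$likelihood * 200)) < 1e-9))
  # identical rows get identical likelihoods
  dup <- fx$features[c(1, 1, 1), ]
  dup$gene_id <- c("x1", "x2", "x3")
  pd <- predict_likelihood(m, dup)
  expect_equal(length(unique(pd$likelihood)), 1L)

  broken <- dplyr::select(fx$features, -"pagerank")
  err <- tryCatch(predict_likelihood(m, broken), error = identity)
  expect_s3_class(err, "depnet_argument_error")
  expect_match(conditionMessage(err), "pagerank")
})

test_that("cross-evaluation removes training genes before scoring", {
  fx <- model_fixture()
  m <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                   hyperparams = list(ntree = 150))
  # contaminate the test set with 10 training genes on purpose
  test_genes <- c(fx$split$test, fx$split$train[1:10])
  ev <- cross_evaluate(m, fx$features, test_genes, fx$split$labels)
  expect_equal(ev$n_removed, 10L)
  expect_equal(ev$n_test, length(fx$split$test))
  expect_equal(length(intersect(ev$scores$gene_id, m$training_genes)), 0L)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
})

test_that("shuffled labels drive the AUC to chance", {
  fx <- model_fixture()
  aucs <- purrr::map_dbl(1:10, function(i) {
    labels <- fx$split$labels
    names(labels) <- withr::with_seed(i, sample(names(labels)))
    m <- train_dependency_classifier(fx$features,
                                     modifyList(fx$split, list(labels = labels)),
                                     seed = i,
                                     hyperparams = list(ntree = 100,
                                                        mtry_grid = 3))
    cross_evaluate(m, fx$features, fx$split$test, labels)$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("the super training set stacks per-line rows with provenance", {
  co <- small_cohort()
  ls <- call_cell_essential(co$dependency)
  cls <- names(co$profiles)[1:3]
  fts <- purrr::map(setNames(nm = cls), function(cl) {
    normalize_features(
      compute_node_features(personalize(co$network, co$profiles[[cl]]))
    )
  })
  sps <- purrr::map(setNames(nm = cls), function(cl) {
    balanced_split(ls, cl, seed = 3, genes = fts[[cl]]$gene_id)
  })
  super <- super_training_set(fts, sps)
  expect_equal(nrow(super), sum(lengths(purrr::map(sps, "train"))))
  expect_setequal(unique(super$cell_line_id), cls)
  # a gene trained in two lines appears twice with that line's features
  dup_gene <- super |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::slice(1)
  if (nrow(dup_gene) == 1) {
    rows <- super[super$gene_id == dup_gene$gene_id, ]
    expect_gt(nrow(unique(rows[, feature_names()])), 1)
  }
  expect_error(super_training_set(fts[1], sps[1]),
               class = "depnet_argument_error")

  sm <- train_super_classifier(super, hyperparams = list(ntree = 100), seed = 1)
  expect_s3_class(sm, "depnet_classifier")
  expect_equal(sm$provenance$cell_line_id, "super")
})

test_that("rarity-stratified evaluation balances within strata and flags empties", {
  fx <- model_fixture()
  m <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                   hyperparams = list(ntree = 150))
  strata <- rarity_strata(fx$labels, bounds = c(3, 2))
  strata$impossible <- character(0)
  evs <- rarity_stratified_eval(m, fx$features, fx$split$test,
                                fx$split$labels, strata, seed = 6)
  expect_named(evs, names(strata))
  expect_true(evs$impossible$empty)
  for (ev in evs) {
    if (isTRUE(ev$empty)) next
    expect_true(ev$auc >= 0 && ev$auc <= 1)
    expect_equal(length(intersect(ev$scores$gene_id, m$training_genes)), 0L)
  }
})

test_that("leave-one-out importance finds a planted informative feature", {
  # construct features where only `degree` carries the label
  withr::local_seed(60)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  label <- rep(c(1L, 0L), each = n / 2)
  ft <- tibble::tibble(gene_id = genes)
  for (f in feature_names()) ft[[f]] <- runif(n)
  ft$degree <- label + rnorm(n, 0, 0.2)
  ft <- normalize_features(ft)
  labels <- setNames(label, genes)
  ls <- tibble::tibble(gene_id = genes, cell_line_id = "syn",
                       probability = ifelse(label == 1, 0.9, 0.1),
                       label = label) |>
    dplyr::group_by(gene_id) |>
    dplyr::mutate(essential_in = sum(label)) |>
    dplyr::ungroup()
  sp <- balanced_split(ls, "syn", seed = 2)
  imp <- feature_importance_loo(ft, sp, seed = 3,
                                hyperparams = list(ntree = 150))
  expect_equal(nrow(imp), 12L)
  expect_equal(imp$feature[which.max(imp$accuracy_drop)], "degree")
  # pure-noise features cost almost nothing
  noise_drop <- imp$accuracy_drop[imp$feature != "degree"]
  expect_lt(max(abs(noise_drop)), 0.06)
  # class-conditional summaries mirror the construction
  deg_row <- imp[imp$feature == "degree", ]
  expect_gt(deg_row$mean_essential, deg_row$mean_non_essential)

  expect_error(
    feature_importance_loo(ft[, c("gene_id", "degree")], sp, seed = 1),
    class = "depnet_argument_error"
  )
})

test_that("tidiers expose fits and evaluations as tibbles", {
  fx <- model_fixture()
  m <- train_dependency_classifier(fx$features, fx$split, seed = 4,
                                   hyperparams = list(ntree = 100))
  td <- tidy(m)
  expect_setequal(td$feature, feature_names())
  gl <- glance(m)
  expect_equal(gl$n_train, length(fx$split$train))
  ev <- cross_evaluate(m, fx$features, fx$split$test, fx$split$labels)
  expect_equal(nrow(tidy(ev)), ev$n_test)
  expect_equal(glance(ev)$auc, ev$auc)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
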