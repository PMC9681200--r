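test_that("hand-worked feature values are reproduced on toy graphs", {
  # path A-B-C
  ft <- compute_node_features(path_abc())
  row <- function(g) ft[ft$gene_id == g, ]
  expect_equal(row("B")$betweenness, 1)
  expect_equal(row("A")$eccentricity, 2)
  expect_equal(row("B")$degree, 2)
  expect_equal(row("B")$neighborhood_1, 3)  # ego included

  # 5-node star: hub degree 4, hub betweenness C(4,2)=6, neighborhood_1 = 5
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("S", 1:5)
  fs <- compute_node_features(star)
  hub <- fs[fs$gene_id == "S1", ]
  expect_equal(hub$degree, 4)
  expect_equal(hub$betweenness, 6)
  expect_equal(hub$neighborhood_1, 5)

  # K3: symmetry forces eigen centrality 1 and pagerank 1/3 everywhere
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("A", "B", "C")
  fk <- compute_node_features(k3)
  expect_equal(fk$eigen_centrality, rep(1, 3), tolerance = 1e-9)
  expect_equal(fk$pagerank, rep(1 / 3, 3), tolerance = 1e-9)

  expect_error(compute_node_features(igraph::make_empty_graph(0)),
               class = "depnet_argument_error")
})

test_that("weighted betweenness honours costs (Dijkstra by hand)", {
  # triangle with costs AB=1, BC=1, AC=3: A-C reroutes through B (cost 2 < 3)
  tri <- igraph::make_graph(c("A", "B", "B", "C", "A", "C"), directed = FALSE)
  igraph::E(tri)$weight <- c(1, 1, 3)
  ft <- compute_node_features(tri)
  expect_equal(ft$betweenness[ft$gene_id == "B"], 1)
  # closeness (harmonic, costs): A reaches B at 1, C at 2
  expect_equal(ft$closeness[ft$gene_id == "A"], 1 + 1 / 2)
  expect_equal(ft$eccentricity[ft$gene_id == "A"], 2)
})

test_that("path, peeling and pagerank features match brute-force oracles", {
  withr::local_seed(99)
  n_graphs <- 40
  for (i in seq_len(n_graphs)) {
    n <- sample(4:12, 1)
    g <- random_graph(n, runif(1, 0.2, 0.6))
    weighted <- i %% 2 == 0
    if (weighted) igraph::E(g)$weight <- runif(igraph::ecount(g), 0.05, 1)
    if (igraph::ecount(g) == 0) next
    ft <- compute_node_features(g)
    ord <- match(igraph::V(g)$name, ft$gene_id)
    expect_equal(ft$betweenness[ord], oracle_betweenness(g), tolerance = 1e-9)
    expect_equal(ft$closeness[ord], oracle_harmonic_closeness(g),
                 tolerance = 1e-9)
    expect_equal(ft$eccentricity[ord], oracle_eccentricity(g),
                 tolerance = 1e-9)
    expect_equal(ft$coreness[ord], oracle_coreness(g))
    aff <- if (weighted) 1 - igraph::E(g)$weight + 1e-9 else NULL
    expect_equal(ft$pagerank[ord], oracle_pagerank(g, weights = aff),
                 tolerance = 1e-10)
  }
})

test_that("structural invariants hold on random graphs", {
  withr::local_seed(123)
  for (i in 1:10) {
    g <- random_graph(sample(5:12, 1), runif(1, 0.2, 0.5))
    ft <- compute_node_features(g)
    expect_equal(ft$neighborhood_1, ft$degree + 1)
    expect_true(all(ft$neighborhood_1 <= ft$neighborhood_2))
    expect_true(all(ft$neighborhood_2 <= ft$neighborhood_6))
    expect_equal(sum(ft$pagerank), 1, tolerance = 1e-9)
    expect_false(any(is.na(as.matrix(ft[, -1]))))
  }
})

test_that("directed weighted personalized networks use out-direction topology", {
  g <- igraph::make_graph(c("A", "B", "B", "C", "C", "D"), directed = FALSE)
  prof <- make_profile(c(A = 1, B = 2, C = 0.5, D = 4))
  pers <- personalize(g, prof)
  ft <- compute_node_features(pers)
  sub <- igraph::induced_subgraph(g, igraph::V(pers)$name)
  expect_equal(ft$degree[match(igraph::V(sub)$name, ft$gene_id)],
               unname(igraph::degree(sub)))
  expect_false(any(is.na(as.matrix(ft[, -1]))))
  expect_equal(sum(ft$pagerank), 1, tolerance = 1e-9)
  expect_equal(max(ft$eigen_centrality), 1, tolerance = 1e-9)
})

test_that("disconnected graphs follow the documented conventions", {
  g <- igraph::make_graph(c("A", "B"), directed = FALSE) +
    igraph::vertices("Z")
  ft <- compute_node_features(g)
  z <- ft[ft$gene_id == "Z", ]
  expect_equal(z$closeness, 0)      # unreachable contributes 0
  expect_equal(z$eccentricity, 0)   # no reachable set
  expect_equal(z$constraint, 0)     # isolated convention
  expect_equal(z$neighborhood_6, 1) # just the ego
})

test_that("min-max normalization is columnwise, degenerate-safe, idempotent", {
  ft <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    betweenness = c(2, 4, 6), constraint = c(7, 7, 7),
    closeness = c(0, 1, 0.5), coreness = c(1, 2, 3), degree = c(1, 2, 3),
    eccentricity = c(3, 2, 1), eigen_centrality = c(0.1, 0.5, 1),
    hub_score = c(0, 0, 1), pagerank = c(0.2, 0.3, 0.5),
    neighborhood_1 = c(2, 3, 4), neighborhood_2 = c(3, 3, 4),
    neighborhood_6 = c(3, 3, 4)
  )
  nf <- normalize_features(ft)
  expect_equal(nf$betweenness, c(0, 0.5, 1))
  expect_equal(nf$constraint, c(0, 0, 0))  # constant column -> zeros
  expect_true(isTRUE(attr(nf, "normalized")))
  expect_equal(as.matrix(normalize_features(nf)[, -1]), as.matrix(nf[, -1]))
  for (col in setdiff(names(nf), c("gene_id", "constraint"))) {
    expect_equal(range(nf[[col]]), c(0, 1))
  }
})

test_that("feature tables round-trip through TSV with their metadata sidecar", {
  ft <- compute_node_features(path_abc())
  nf <- normalize_features(ft)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(nf, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(nf), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isTRUE(attr(back, "normalized")))
})
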