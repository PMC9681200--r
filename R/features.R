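#' Compute the twelve node-topology features
#'
#' Computes, for every node of a generic (undirected, unweighted) or
#' personalized (directed, weighted) network, the twelve features used by the
#' dependency classifiers: betweenness, constraint, closeness, coreness,
#' degree, eccentricity, eigen centrality, hub score, pagerank and
#' neighbourhood size at 1, 2 and 6 steps.
#'
#' On weighted networks one weight set feeds two different algorithm
#' families, which read it in opposite senses. The package resolves this so
#' that high expression consistently means "strong/close":
#'
#' * path-based features (betweenness, closeness, eccentricity) consume the
#'   stored weights as traversal **costs**;
#' * spectral features (eigen centrality, hub score, pagerank) and Burt's
#'   constraint consume the **affinity** `a = max(1 - w, 0) + delta` (with a
#'   small floor `delta` keeping affinities positive even for costs above 1)
#'   as connection strength;
#' * degree, coreness and the neighbourhood counts use the unweighted
#'   topology (out-direction on directed networks).
#'
#' Setting `weights_as_is = TRUE` feeds the raw weights to every algorithm
#' (the naive single-interpretation behaviour), for comparison.
#'
#' Conventions for disconnected networks: closeness is harmonic-style
#' (an unreachable pair contributes 0), eccentricity is taken over a node's
#' reachable set (0 for a node that reaches nothing), and isolated nodes get
#' constraint 0. Eigen centrality is scaled so its maximum is 1; pagerank
#' (damping 0.85) sums to 1; neighbourhood counts include the node itself.
#'
#' @param net An `igraph` network; directed weighted graphs are expected to
#'   carry the cost convention written by [personalize()].
#' @param weights_as_is Feed stored weights unchanged to all algorithms.
#' @param affinity_floor Small positive floor added when converting costs to
#'   affinities (default `1e-9`).
#' @return A tibble with `gene_id` plus the 12 feature columns, one row per
#'   node. Attributes: `normalized = FALSE` and a `provenance` list.
#' @export
compute_node_features <- function(net, weights_as_is = FALSE,
                                  affinity_floor = 1e-9) {
  if (igraph::vcount(net) == 0L) {
    stopf("cannot compute features on an empty network",
          class = "depnet_argument_error")
  }
  check_flag(weights_as_is, "weights_as_is")
  directed <- igraph::is_directed(net)
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  costs <- if (weighted) igraph::E(net)$weight else NULL
  if (weighted && any(costs <= 0)) {
    stopf("edge weights must be positive traversal costs",
          class = "depnet_argument_error")
  }
  affinity <- if (!weighted) NULL
              else if (weights_as_is) costs
              else pmax(1 - costs, 0) + affinity_floor
  mode <- if (directed) "out" else "all"
  names <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))

  d <- igraph::distances(net, mode = "out",
                         weights = if (weighted) costs else NA)
  diag(d) <- Inf  # self-distances never contribute
  finite <- is.finite(d)
  closeness <- rowSums(ifelse(finite, 1 / d, 0))
  ecc <- apply(d, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) 0 else max(r)
  })

  btw <- igraph::betweenness(net, directed = directed,
                             weights = if (weighted) costs else NA)

  cons <- igraph::constraint(net, weights = affinity)
  cons[!is.finite(cons)] <- 0

  eig <- igraph::eigen_centrality(net, directed = directed,
                                  weights = affinity)$vector
  hub <- igraph::hits_scores(net, scale = TRUE, weights = affinity)$hub
  pr <- igraph::page_rank(net, directed = directed, damping = 0.85,
                          weights = affinity)$vector

  ft <- tibble(
    gene_id = names,
    betweenness = unname(btw),
    constraint = unname(cons),
    closeness = unname(closeness),
    coreness = unname(igraph::coreness(net, mode = mode)),
    degree = unname(igraph::degree(net, mode = mode)),
    eccentricity = unname(ecc),
    eigen_centrality = unname(eig),
    hub_score = unname(hub),
    pagerank = unname(pr),
    neighborhood_1 = unname(igraph::ego_size(net, order = 1, mode = mode)),
    neighborhood_2 = unname(igraph::ego_size(net, order = 2, mode = mode)),
    neighborhood_6 = unname(igraph::ego_size(net, order = 6, mode = mode))
  )
  attr(ft, "normalized") <- FALSE
  attr(ft, "provenance") <- list(
    cell_line_id = igraph::graph_attr(net, "cell_line_id") %||% NA_character_,
    directed = directed, weighted = weighted,
    weight_convention = if (weighted) {
      if (weights_as_is) "as_is" else "cost_path_affinity_spectral"
    } else "unweighted",
    n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net)
  )
  ft
}

#' Min-max normalize a feature table
#'
#' Scales every feature column of one table (i.e. one cell line) to `[0, 1]`
#' independently: `(x - min) / (max - min)`. A constant column carries no
#' information and maps to all zeros. Idempotent on already-normalized
#' non-constant columns.
#'
#' @param ft A feature table from [compute_node_features()].
#' @return The normalized tibble, with attribute `normalized = TRUE`.
#' @export
normalize_features <- function(ft) {
  ft <- as_tibble(ft)
  cols <- intersect(DEPNET_FEATURES, names(ft))
  if (length(cols) == 0L) {
    stopf("no feature columns found to normalize",
          class = "depnet_argument_error")
  }
  prov <- attr(ft, "provenance")
  out <- dplyr::mutate(ft, dplyr::across(
    dplyr::all_of(cols),
    function(x) {
      rng <- range(x)
      if (rng[1L] == rng[2L]) rep(0, length(x))
      else (x - rng[1L]) / (rng[2L] - rng[1L])
    }
  ))
  attr(out, "normalized") <- TRUE
  attr(out, "provenance") <- prov
  out
}

#' Write / read a feature table with its metadata sidecar
#'
#' The table itself is written as TSV with the `gene_id` key column; the
#' provenance (source network, normalization state, weight convention) goes
#' to a JSON sidecar at `paste0(path, ".meta.json")`.
#'
#' @param ft A feature table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  readr::write_tsv(as_tibble(ft), path, progress = FALSE)
  meta <- list(
    normalized = isTRUE(attr(ft, "normalized")),
    provenance = attr(ft, "provenance")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"
  ), progress = FALSE, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(ft, "normalized") <- isTRUE(meta$normalized)
    attr(ft, "provenance") <- meta$provenance
  }
  ft
}
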