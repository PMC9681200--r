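#' Assemble the generic gene-level interaction network
#'
#' Builds an undirected simple graph from gene-level interaction records:
#' duplicate pairs (in either order) are collapsed, self-pairs (which arise
#' when several proteins map to one gene) are removed, and only genes that
#' take part in at least one retained interaction become nodes.
#'
#' @param records Tibble with columns `gene_a`, `gene_b` (from
#'   [map_to_genes()]), or any two-column data frame of gene pairs.
#' @return An undirected `igraph` object.
#' @export
#' @examples
#' build_network(tibble::tibble(gene_a = c("A", "B", "A"),
#'                              gene_b = c("B", "A", "A")))
build_network <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  a <- as.character(records[[1L]])
  b <- as.character(records[[2L]])
  keep <- a != b
  el <- cbind(a[keep], b[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Degree-preserving randomized network
#'
#' Produces a null network with the same node set and exactly the same degree
#' sequence as the input, by seeded double-edge swaps that never introduce
#' self-loops or parallel edges. This is the "randomized edges" baseline used
#' to measure how much of a model's performance survives when all structure
#' beyond the degree sequence is destroyed. An Erdős–Rényi alternative (same
#' node and edge count, degrees not preserved) is available via `model`.
#'
#' @param net An undirected `igraph` network.
#' @param seed Integer seed; the same seed gives a byte-identical result.
#' @param swaps_per_edge Number of attempted swaps per edge (default 10).
#' @param model `"degree_preserving"` (default) or `"erdos_renyi"`.
#' @return A rewired `igraph` network.
#' @export
rewire_null <- function(net, seed, swaps_per_edge = 10,
                        model = c("degree_preserving", "erdos_renyi")) {
  model <- match.arg(model)
  check_number(swaps_per_edge, "swaps_per_edge", lower = 1)
  with_seed(seed, {
    if (model == "degree_preserving") {
      out <- igraph::rewire(
        net,
        igraph::keeping_degseq(loops = FALSE,
                               niter = swaps_per_edge * igraph::ecount(net))
      )
    } else {
      out <- igraph::sample_gnm(igraph::vcount(net), igraph::ecount(net),
                                directed = FALSE)
      igraph::V(out)$name <- igraph::V(net)$name
    }
    out
  })
}

#' Withhold a random fraction of edges
#'
#' Removes `round(fraction * |E|)` uniformly sampled edges, emulating the
#' incompleteness of experimentally derived interaction networks. Nodes left
#' isolated are retained so feature tables stay aligned across ablation
#' levels.
#'
#' @param net An `igraph` network.
#' @param fraction Fraction of edges to remove, in `[0, 1)`.
#' @param seed Integer seed; the removed edge set is reproducible.
#' @return The ablated `igraph` network (same node set).
#' @export
ablate_edges <- function(net, fraction, seed) {
  check_number(fraction, "fraction", lower = 0, upper = 1,
               allow_equal_upper = FALSE)
  m <- igraph::ecount(net)
  n_remove <- round(fraction * m)
  if (n_remove == 0L) return(net)
  with_seed(seed, {
    drop <- sample.int(m, n_remove)
    igraph::delete_edges(net, drop)
  })
}

#' Write a network as GraphML
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a network as a two-column (or weighted three-column) edge TSV
#'
#' Directed networks with a `weight` edge attribute are written as
#' `source`, `target`, `weight`; unweighted networks as `gene_a`, `gene_b`.
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (igraph::is_directed(net) && "weight" %in% igraph::edge_attr_names(net)) {
    df <- tibble(source = el[, 1L], target = el[, 2L],
                 weight = igraph::E(net)$weight)
  } else {
    df <- tibble(gene_a = el[, 1L], gene_b = el[, 2L])
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Summarize a network as JSON
#'
#' Writes (or returns) a small JSON report with node count, edge count and
#' the degree histogram.
#'
#' @param net An `igraph` network.
#' @param path Optional output path; if `NULL` the summary list is returned.
#' @return The summary list, invisibly when written to file.
#' @export
network_summary <- function(net, path = NULL) {
  deg <- igraph::degree(net, mode = "all")
  tab <- table(factor(deg, levels = 0:max(c(deg, 0L))))
  summary <- list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    directed = igraph::is_directed(net),
    degree_histogram = list(degree = as.integer(names(tab)),
                            count = as.integer(tab))
  )
  if (is.null(path)) return(summary)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
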