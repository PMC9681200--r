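# Closed vocabularies for mutation records.
MUTATION_CONSEQUENCES <- c("frameshift", "insertion", "deletion", "nonsense",
                           "missense", "other")
MUTATION_PATHOGENICITY <- c("pathogenic", "benign", "unknown")
GENE_ROLES <- c("oncogene", "tumour_suppressor", "other")

#' Classify the functional effect of a mutation
#'
#' Truncating consequences (frameshift, insertion, deletion, nonsense) are
#' loss-of-function regardless of annotation. A pathogenic missense mutation
#' is gain-of-function in an oncogene and loss-of-function in a tumour
#' suppressor; every other combination is treated as neutral. Pathogenicity
#' calls are consumed pre-computed (e.g. from FATHMM), never derived here.
#'
#' @param consequence One of `r paste(MUTATION_CONSEQUENCES, collapse = ", ")`.
#' @param pathogenicity One of `r paste(MUTATION_PATHOGENICITY, collapse = ", ")`.
#' @param gene_role One of `r paste(GENE_ROLES, collapse = ", ")`.
#' @return `"LOF"`, `"GOF"` or `"neutral"` (vectorized over its arguments).
#' @export
#' @examples
#' classify_mutation_effect("frameshift", "unknown", "other")
#' classify_mutation_effect("missense", "pathogenic", "oncogene")
classify_mutation_effect <- function(consequence, pathogenicity, gene_role) {
  consequence <- as.character(consequence)
  pathogenicity <- as.character(pathogenicity)
  gene_role <- as.character(gene_role)
  bad <- setdiff(unique(consequence), MUTATION_CONSEQUENCES)
  if (length(bad) > 0L) {
    stopf("unknown mutation consequence '%s'", bad[1L],
          class = "depnet_argument_error")
  }
  bad <- setdiff(unique(pathogenicity), MUTATION_PATHOGENICITY)
  if (length(bad) > 0L) {
    stopf("unknown pathogenicity call '%s'", bad[1L],
          class = "depnet_argument_error")
  }
  bad <- setdiff(unique(gene_role), GENE_ROLES)
  if (length(bad) > 0L) {
    stopf("unknown gene role '%s'", bad[1L], class = "depnet_argument_error")
  }
  n <- max(length(consequence), length(pathogenicity), length(gene_role))
  consequence <- rep_len(consequence, n)
  pathogenicity <- rep_len(pathogenicity, n)
  gene_role <- rep_len(gene_role, n)
  out <- rep("neutral", n)
  out[consequence %in% c("frameshift", "insertion", "deletion", "nonsense")] <- "LOF"
  mis_path <- consequence == "missense" & pathogenicity == "pathogenic"
  out[mis_path & gene_role == "oncogene"] <- "GOF"
  out[mis_path & gene_role == "tumour_suppressor"] <- "LOF"
  out
}

#' Edge-weighting parameters
#'
#' @param epsilon Small positive offset added to expression before the log,
#'   so that zero expression is well defined (default `1e-10`).
#' @param gof_multiplier Factor applied to the expression of genes carrying a
#'   gain-of-function mutation before weighting (default 10), boosting their
#'   effective activity.
#' @param missing_expression_policy How to weight edges whose source gene has
#'   no expression measurement: `"treat_as_zero"` (weight near 1, weak flow —
#'   the formula's stated zero-expression limit) or `"weight_one"` (weight
#'   exactly 1).
#' @param log_base Base of the logarithm inside the weight function; the
#'   default `exp(1)` is the natural log.
#' @return A list of class `depnet_weight_params`.
#' @export
weight_params <- function(epsilon = 1e-10, gof_multiplier = 10,
                          missing_expression_policy = c("treat_as_zero",
                                                        "weight_one"),
                          log_base = exp(1)) {
  check_number(epsilon, "epsilon", lower = 0, allow_equal_lower = FALSE)
  check_number(gof_multiplier, "gof_multiplier", lower = 1)
  check_number(log_base, "log_base", lower = 1, allow_equal_lower = FALSE)
  structure(
    list(epsilon = epsilon, gof_multiplier = gof_multiplier,
         missing_expression_policy = match.arg(missing_expression_policy),
         log_base = log_base),
    class = "depnet_weight_params"
  )
}

#' Expression-driven edge weight
#'
#' Maps the expression `g` (TPM) of an edge's *source* gene to a traversal
#' cost `w = 0.5 - 0.5 * tanh(log(g + epsilon))`, so that weakly expressed
#' genes get weight near 1 (little information flow) and highly expressed
#' genes get weight near 0 (strong flow). With the natural log this is
#' analytically `1 / ((g + epsilon)^2 + 1)`. Gain-of-function genes have
#' their expression multiplied by `gof_multiplier` first.
#'
#' @param g Expression in TPM (non-negative; vectorized).
#' @param is_gof Whether the source gene carries a gain-of-function mutation.
#' @param params A [weight_params()] object.
#' @return Weights in `(0, 1]`.
#' @export
#' @examples
#' edge_weight(0)   # ~1: silent gene, weak flow
#' edge_weight(1)   # 0.5
#' edge_weight(1, is_gof = TRUE)  # ~0.0099: boosted tenfold
edge_weight <- function(g, is_gof = FALSE, params = weight_params()) {
  if (!is.numeric(g) || any(is.na(g))) {
    stopf("`g` must be numeric and non-missing", class = "depnet_argument_error")
  }
  if (any(g < 0)) {
    stopf("`g` must be non-negative (TPM); got %s", format(min(g)),
          class = "depnet_argument_error")
  }
  check_flag(is_gof, "is_gof")
  gp <- if (is_gof) g * params$gof_multiplier else g
  0.5 - 0.5 * tanh(log(gp + params$epsilon, base = params$log_base))
}

#' A cell line's molecular profile
#'
#' Bundles the per-gene expression and the mutation records of one cell line.
#'
#' @param cell_line_id Non-empty identifier.
#' @param expression Named numeric vector of TPM values (names are gene IDs),
#'   or a two-column data frame (`gene_id`, `tpm`).
#' @param mutations Data frame with columns `gene_id`, `consequence`,
#'   `pathogenicity`, `gene_role` (may have zero rows).
#' @param tissue Tissue label (default `"unknown"`).
#' @return A list of class `depnet_profile`.
#' @export
cell_line_profile <- function(cell_line_id, expression,
                              mutations = empty_mutation_table(),
                              tissue = "unknown") {
  check_string(cell_line_id, "cell_line_id")
  if (is.data.frame(expression)) {
    expression <- setNames(as.numeric(expression[[2L]]),
                           as.character(expression[[1L]]))
  }
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    stopf("`expression` must be named by gene ID",
          class = "depnet_argument_error")
  }
  if (any(expression < 0, na.rm = TRUE)) {
    stopf("TPM values must be non-negative in cell line '%s'", cell_line_id,
          class = "depnet_argument_error")
  }
  mutations <- as_tibble(mutations)
  needed <- c("gene_id", "consequence", "pathogenicity", "gene_role")
  if (!all(needed %in% names(mutations))) {
    stopf("`mutations` must have columns %s", paste(needed, collapse = ", "),
          class = "depnet_argument_error")
  }
  if (nrow(mutations) > 0L) {
    mutations$effect <- classify_mutation_effect(
      mutations$consequence, mutations$pathogenicity, mutations$gene_role
    )
  } else {
    mutations$effect <- character(0)
  }
  structure(
    list(cell_line_id = cell_line_id, tissue = tissue,
         expression = expression, mutations = mutations),
    class = "depnet_profile"
  )
}

empty_mutation_table <- function() {
  tibble(gene_id = character(0), consequence = character(0),
         pathogenicity = character(0), gene_role = character(0))
}

#' @export
print.depnet_profile <- function(x, ...) {
  cat(sprintf("<depnet_profile> %s (%s): %d genes with expression, %d mutation(s)\n",
              x$cell_line_id, x$tissue, length(x$expression),
              nrow(x$mutations)))
  invisible(x)
}

#' Personalize the generic network for one cell line
#'
#' Applies the two perturbations that turn the generic interaction network
#' into a cell-line-specific one:
#'
#' 1. every gene carrying at least one loss-of-function-classified mutation
#'    is deleted together with its incident edges (deletion wins over any
#'    gain-of-function evidence on the same gene);
#' 2. each surviving undirected edge `{u, v}` is replaced by two directed
#'    edges, `u -> v` weighted by [edge_weight()] of `u`'s expression and
#'    `v -> u` weighted by `v`'s expression — a directed edge's weight is a
#'    function of its *source* gene only.
#'
#' Weights are traversal costs: low weight (high expression) means easy
#' information flow. The convention is recorded on the returned graph
#' (`weight_convention` attribute) and honoured by [compute_node_features()].
#'
#' @param net The generic undirected `igraph` network.
#' @param profile A [cell_line_profile()].
#' @param params A [weight_params()].
#' @return A directed weighted `igraph` with graph attributes `cell_line_id`
#'   and `weight_convention = "cost"`.
#' @export
personalize <- function(net, profile, params = weight_params()) {
  stopifnot(inherits(profile, "depnet_profile"))
  lof_genes <- unique(profile$mutations$gene_id[profile$mutations$effect == "LOF"])
  gof_genes <- setdiff(
    unique(profile$mutations$gene_id[profile$mutations$effect == "GOF"]),
    lof_genes
  )
  keep <- setdiff(igraph::V(net)$name, lof_genes)
  sub <- igraph::induced_subgraph(net, keep)

  el <- igraph::as_edgelist(sub, names = TRUE)
  src <- c(el[, 1L], el[, 2L])
  dst <- c(el[, 2L], el[, 1L])
  w <- source_weights(src, profile$expression, gof_genes, params)

  g <- igraph::make_empty_graph(n = igraph::vcount(sub), directed = TRUE)
  igraph::V(g)$name <- igraph::V(sub)$name
  if (length(src) > 0L) {
    idx <- rbind(match(src, igraph::V(g)$name), match(dst, igraph::V(g)$name))
    g <- igraph::add_edges(g, as.vector(idx), weight = w)
  }
  g <- igraph::set_graph_attr(g, "cell_line_id", profile$cell_line_id)
  g <- igraph::set_graph_attr(g, "tissue", profile$tissue)
  igraph::set_graph_attr(g, "weight_convention", "cost")
}

# Weight of each directed edge from its source gene's expression.
source_weights <- function(src, expression, gof_genes, params) {
  if (length(src) == 0L) return(numeric(0))
  tpm <- unname(expression[src])
  missing <- is.na(tpm)
  tpm[missing] <- 0
  is_gof <- src %in% gof_genes
  w <- numeric(length(src))
  if (any(!is_gof)) {
    w[!is_gof] <- edge_weight(tpm[!is_gof], is_gof = FALSE, params = params)
  }
  if (any(is_gof)) {
    w[is_gof] <- edge_weight(tpm[is_gof], is_gof = TRUE, params = params)
  }
  if (params$missing_expression_policy == "weight_one") {
    w[missing] <- 1
  }
  w
}
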