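# Shared fixture builders. Everything is generated in code at test time.

write_toy_interactions <- function(path = tempfile(fileext = ".tsv"),
                                   rows = c("P1\tP2\t85", "P1\tP3\t80",
                                            "P2\tP3\t200", "P3\tP4\t12"),
                                   header = "protein1\tprotein2\texperimental") {
  writeLines(c(header, rows), path)
  path
}

toy_mapping <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4", "P5"),
    gene_id = c("G1", "G2", "G3", "G4", "G1")
  )
}

# Small random simple graph with named nodes, for property tests.
random_graph <- function(n, p = 0.35) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("N", seq_len(n))
  g
}

# A path graph A - B - C.
path_abc <- function() {
  igraph::make_graph(c("A", "B", "B", "C"), directed = FALSE)
}

# Profile with given TPM vector and optional mutation rows.
make_profile <- function(expression, mutations = NULL, id = "CL1",
                         tissue = "breast") {
  if (is.null(mutations)) {
    mutations <- tibble::tibble(
      gene_id = character(0), consequence = character(0),
      pathogenicity = character(0), gene_role = character(0)
    )
  }
  cell_line_profile(id, expression, mutations, tissue = tissue)
}

mutation_row <- function(gene, consequence, pathogenicity = "unknown",
                         role = "other") {
  tibble::tibble(gene_id = gene, consequence = consequence,
                 pathogenicity = pathogenicity, gene_role = role)
}

# Long dependency tibble from a genes x lines probability matrix.
dep_long <- function(mat) {
  tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-gene_id, names_to = "cell_line_id",
                        values_to = "probability")
}

# Small end-to-end cohort shared by model tests (cached per session).
small_cohort <- local({
  cache <- new.env()
  function(seed = 11) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(
        cohort_spec(n_genes = 200, lines_per_tissue = 2, seed = seed)
      )
    }
    cache[[key]]
  }
})

# A cohort at the generator's default study conditions (cached).
default_cohort <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(cohort_spec(seed = seed))
    }
    cache[[key]]
  }
})
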