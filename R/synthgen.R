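#' Specification of a synthetic cohort
#'
#' Describes the simulated study from which every other module can be
#' exercised without downloads: a scale-free-ish interaction network, per
#' cell line log-normal expression and sparse mutations, and a dependency
#' matrix with a planted topology-linked signal.
#'
#' Dependency probabilities follow
#' `p = plogis(alpha + beta * s + noise)`, where `s` in `[0, 1]` is a
#' per-line planted score mixing three rank-transformed centrality
#' components of the *personalized* network:
#'
#' * the gene's outgoing edge affinity (`1 - edge weight`, a monotone
#'   transform of its own expression) with weight `expr_mix`;
#' * the affinity-weighted eigenvector centrality after removing its degree
#'   component (rank-on-rank regression residual) with weight
#'   `1 - expr_mix - degree_mix`;
#' * the generic degree with weight `degree_mix`.
#'
#' Genes deleted by loss-of-function mutations score 0. This mixture makes
#' the planted dependencies behave like the study designs the cohort has to
#' exercise: personalized (weighted) features carry nearly all of the
#' signal; unweighted features of the generic network carry only the
#' spectral-residual and degree parts; an unweighted degree-preserving
#' rewired null carries almost nothing; and withholding a quarter of the
#' edges only partially perturbs the spectral residual while leaving the
#' affinity component intact.
#'
#' @param n_genes Number of genes (>= 50; default 600).
#' @param lines_per_tissue Cell lines simulated per tissue (default 3).
#' @param tissues Character vector of tissue labels (default breast,
#'   kidney).
#' @param pa_edges_per_node Preferential-attachment edges added per new node
#'   (default 3).
#' @param expr_meanlog,expr_sdlog Log-scale mean and SD of the TPM
#'   distribution (defaults 1 and 1.2).
#' @param lof_rate Per-gene probability of a truncating (loss-of-function)
#'   mutation in a given line (default 0.02).
#' @param missense_rate Per-gene probability of a missense mutation
#'   (default 0.03); pathogenicity and gene role are sampled so only a
#'   minority become GOF/LOF.
#' @param beta Planted-signal strength on the logit scale (default 4);
#'   `beta = 0` removes all topology linkage.
#' @param alpha Logit-scale intercept (default -2).
#' @param expr_mix Fraction of the planted score carried by the gene's own
#'   edge affinity (default 0.55).
#' @param degree_mix Fraction of the planted score carried by the raw
#'   degree rank (default 0.05); kept small so degree alone is only weakly
#'   informative, yet detectably so in rank tests.
#' @param noise_sd SD of logit-scale noise (default 0.3).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `depnet_cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 600L, lines_per_tissue = 3L,
                        tissues = c("breast", "kidney"),
                        pa_edges_per_node = 3L,
                        expr_meanlog = 1, expr_sdlog = 1.2,
                        lof_rate = 0.02, missense_rate = 0.03,
                        beta = 4, alpha = -2, expr_mix = 0.55,
                        degree_mix = 0.05, noise_sd = 0.3, seed) {
  spec <- list(
    n_genes = as.integer(n_genes), lines_per_tissue = as.integer(lines_per_tissue),
    tissues = as.character(tissues), pa_edges_per_node = as.integer(pa_edges_per_node),
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    lof_rate = lof_rate, missense_rate = missense_rate,
    beta = beta, alpha = alpha, expr_mix = expr_mix,
    degree_mix = degree_mix, noise_sd = noise_sd,
    seed = if (missing(seed)) NULL else seed
  )
  problems <- character(0)
  if (is.na(spec$n_genes) || spec$n_genes < 50L) {
    problems <- c(problems, "n_genes must be >= 50")
  }
  if (is.na(spec$lines_per_tissue) || spec$lines_per_tissue < 1L) {
    problems <- c(problems, "lines_per_tissue must be >= 1")
  }
  if (length(spec$tissues) < 1L || anyDuplicated(spec$tissues)) {
    problems <- c(problems, "tissues must be a non-empty set of unique labels")
  }
  if (is.na(spec$pa_edges_per_node) || spec$pa_edges_per_node < 1L) {
    problems <- c(problems, "pa_edges_per_node must be >= 1")
  }
  for (rate in c("lof_rate", "missense_rate", "expr_mix", "degree_mix")) {
    v <- spec[[rate]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      problems <- c(problems, sprintf("%s must lie in [0, 1]", rate))
    }
  }
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0) {
    problems <- c(problems, "noise_sd must be >= 0")
  }
  if (is.numeric(spec$expr_mix) && is.numeric(spec$degree_mix) &&
      isTRUE(spec$expr_mix + spec$degree_mix > 1)) {
    problems <- c(problems, "expr_mix + degree_mix must not exceed 1")
  }
  if (is.null(spec$seed) || !is.numeric(spec$seed) || is.na(spec$seed)) {
    problems <- c(problems, "seed is mandatory")
  }
  if (length(problems) > 0L) {
    stopf("invalid cohort spec: %s", paste(problems, collapse = "; "),
          class = "depnet_argument_error")
  }
  spec$seed <- as.integer(spec$seed)
  structure(spec, class = "depnet_cohort_spec")
}

#' Generate a complete synthetic cohort
#'
#' Produces a generic network, one molecular profile per cell line, a
#' dependency-probability matrix with planted topology-linked signal, and
#' the planted truth — all reproducible from the spec's seed alone.
#'
#' @param spec A [cohort_spec()].
#' @param params [weight_params()] used by the internal personalization that
#'   defines the planted centrality score.
#' @return A list of class `depnet_cohort` with elements `network`
#'   (undirected `igraph`), `profiles` (named list of
#'   [cell_line_profile()]), `dependency` (long tibble `gene_id`,
#'   `cell_line_id`, `tissue`, `probability`), `truth` (long tibble with the
#'   planted score `s`, the noiseless probability and the binary planted
#'   label) and `spec`.
#' @export
generate_cohort <- function(spec, params = weight_params()) {
  stopifnot(inherits(spec, "depnet_cohort_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    net <- igraph::sample_pa(spec$n_genes, m = spec$pa_edges_per_node,
                             directed = FALSE)
    igraph::V(net)$name <- genes
    deg_rank <- rank(igraph::degree(net), ties.method = "average") /
      spec$n_genes

    lines <- expand.grid(idx = seq_len(spec$lines_per_tissue),
                         tissue = spec$tissues, stringsAsFactors = FALSE)
    line_ids <- sprintf("%s_%02d", toupper(substr(lines$tissue, 1, 2)),
                        seq_len(nrow(lines)))

    profiles <- list()
    dep_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(lines))) {
      cl <- line_ids[i]
      expr <- setNames(rlnorm(spec$n_genes, spec$expr_meanlog,
                              spec$expr_sdlog), genes)
      mut <- simulate_mutations(genes, spec$lof_rate, spec$missense_rate)
      prof <- cell_line_profile(cl, expr, mut, tissue = lines$tissue[i])
      profiles[[cl]] <- prof

      s <- planted_score(net, prof, spec$expr_mix, spec$degree_mix,
                         deg_rank, params)

      eta_clean <- unname(spec$alpha + spec$beta * s)
      p <- plogis(eta_clean + rnorm(spec$n_genes, 0, spec$noise_sd))
      dep_rows[[cl]] <- tibble(gene_id = genes, cell_line_id = cl,
                               tissue = lines$tissue[i], probability = p)
      truth_rows[[cl]] <- tibble(
        gene_id = genes, cell_line_id = cl, s = unname(s),
        clean_probability = plogis(eta_clean),
        planted_essential = as.integer(plogis(eta_clean) > 0.65)
      )
    }
    structure(
      list(network = net, profiles = profiles,
           dependency = dplyr::bind_rows(dep_rows),
           truth = dplyr::bind_rows(truth_rows), spec = spec),
      class = "depnet_cohort"
    )
  })
}

# Planted per-line score in [0, 1]: a convex mixture of rank-transformed
# centrality components of the personalized network — own outgoing-edge
# affinity (expression), the affinity-weighted eigenvector centrality with
# its degree component removed (rank-on-rank regression residual), and the
# generic degree. LOF-deleted genes score 0 (the cell no longer carries
# them).
planted_score <- function(net, prof, expr_mix, degree_mix, deg_rank, params) {
  genes <- igraph::V(net)$name
  n <- length(genes)
  pers <- personalize(net, prof, params)
  cent <- setNames(rep(0, n), genes)
  if (igraph::ecount(pers) > 0L) {
    aff <- 1 - igraph::E(pers)$weight + 1e-9
    ec <- igraph::eigen_centrality(pers, directed = TRUE,
                                   weights = aff)$vector
    cent[names(ec)] <- ec
  }
  cent_rank <- rank(cent, ties.method = "average") / n
  resid_rank <- rank(residuals(lm(cent_rank ~ deg_rank)),
                     ties.method = "average") / n
  tpm <- prof$expression[genes]
  tpm[is.na(tpm)] <- 0
  own_aff <- 1 - edge_weight(unname(tpm), params = params)
  own_rank <- rank(own_aff, ties.method = "average") / n
  lof <- genes %in% unique(prof$mutations$gene_id[prof$mutations$effect == "LOF"])
  topo_mix <- 1 - expr_mix - degree_mix
  s <- expr_mix * own_rank + topo_mix * resid_rank + degree_mix * deg_rank
  s[lof] <- 0
  setNames(s, genes)
}

simulate_mutations <- function(genes, lof_rate, missense_rate) {
  n <- length(genes)
  lof_hit <- runif(n) < lof_rate
  mis_hit <- runif(n) < missense_rate
  rows <- list()
  if (any(lof_hit)) {
    rows$lof <- tibble(
      gene_id = genes[lof_hit],
      consequence = sample(c("frameshift", "nonsense", "deletion", "insertion"),
                           sum(lof_hit), replace = TRUE),
      pathogenicity = "unknown",
      gene_role = sample(GENE_ROLES, sum(lof_hit), replace = TRUE)
    )
  }
  if (any(mis_hit)) {
    rows$mis <- tibble(
      gene_id = genes[mis_hit],
      consequence = "missense",
      pathogenicity = sample(MUTATION_PATHOGENICITY, sum(mis_hit),
                             replace = TRUE, prob = c(0.4, 0.4, 0.2)),
      gene_role = sample(GENE_ROLES, sum(mis_hit), replace = TRUE,
                         prob = c(0.25, 0.25, 0.5))
    )
  }
  if (length(rows) == 0L) empty_mutation_table() else dplyr::bind_rows(rows)
}

#' @export
print.depnet_cohort <- function(x, ...) {
  cat(sprintf(
    "<depnet_cohort> %d genes, %d edges, %d cell lines (%s); seed %d\n",
    x$spec$n_genes, igraph::ecount(x$network), length(x$profiles),
    paste(x$spec$tissues, collapse = ", "), x$spec$seed
  ))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's input dialects
#'
#' Emits exactly the file shapes the package readers accept: a two-column
#' edge TSV, a genes-by-lines expression TSV, a long-format mutation TSV, a
#' genes-by-lines dependency CSV, and a JSON manifest (spec, tissue map,
#' file list).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent; must not already contain
#'   cohort files).
#' @return Invisible named character vector of the five file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "depnet_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    dependency = file.path(dir, "dependency.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  clash <- paths[file.exists(paths)]
  if (length(clash) > 0L) {
    stopf("refusing to overwrite existing cohort file(s): %s",
          paste(basename(clash), collapse = ", "), class = "depnet_io_error")
  }
  write_edge_tsv(cohort$network, paths[["edges"]])

  expr <- purrr::map(cohort$profiles, "expression")
  expr_tab <- dplyr::bind_cols(
    tibble(gene_id = names(expr[[1L]])),
    as_tibble(purrr::map(expr, unname))
  )
  readr::write_tsv(expr_tab, paths[["expression"]], progress = FALSE)

  mut <- purrr::imap_dfr(cohort$profiles, function(p, cl) {
    m <- p$mutations[, c("gene_id", "consequence", "pathogenicity", "gene_role")]
    if (nrow(m) == 0L) return(NULL)
    dplyr::bind_cols(tibble(cell_line_id = cl), m)
  })
  if (is.null(mut) || nrow(mut) == 0L) {
    mut <- tibble(cell_line_id = character(0), gene_id = character(0),
                  consequence = character(0), pathogenicity = character(0),
                  gene_role = character(0))
  }
  readr::write_tsv(mut, paths[["mutations"]], progress = FALSE)

  dep_wide <- tidyr::pivot_wider(
    cohort$dependency[, c("gene_id", "cell_line_id", "probability")],
    names_from = "cell_line_id", values_from = "probability"
  )
  readr::write_csv(dep_wide, paths[["dependency"]], progress = FALSE)

  tissue_map <- purrr::map_chr(cohort$profiles, "tissue")
  manifest <- list(
    tool = "depnet", version = as.character(packageVersion("depnet")),
    spec = unclass(cohort$spec),
    tissues = as.list(tissue_map),
    files = as.list(basename(paths[names(paths) != "manifest"]))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a written cohort back from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `network`, `profiles`, `dependency` and `manifest`
#'   (the planted truth is not persisted; it lives only in the in-memory
#'   cohort).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           col_types = "cc", progress = FALSE,
                           show_col_types = FALSE)
  net <- build_network(edges)
  expr_tab <- readr::read_tsv(file.path(dir, "expression.tsv"),
                              col_types = readr::cols(gene_id = "c",
                                                      .default = "d"),
                              progress = FALSE, show_col_types = FALSE)
  mut <- readr::read_tsv(file.path(dir, "mutations.tsv"),
                         col_types = "ccccc", progress = FALSE,
                         show_col_types = FALSE)
  tissue_map <- unlist(manifest$tissues)
  profiles <- purrr::map(setNames(nm = setdiff(names(expr_tab), "gene_id")),
    function(cl) {
      cell_line_profile(
        cl,
        setNames(expr_tab[[cl]], expr_tab$gene_id),
        dplyr::filter(mut, .data$cell_line_id == cl)[
          , c("gene_id", "consequence", "pathogenicity", "gene_role")],
        tissue = tissue_map[[cl]] %||% "unknown"
      )
    })
  dep <- read_dependency_matrix(file.path(dir, "dependency.csv"),
                                tissues = tissue_map)
  list(network = net, profiles = profiles, dependency = dep,
       manifest = manifest)
}
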