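#' Validate a pipeline configuration
#'
#' The configuration drives [run_pipeline()] and the command-line wrapper.
#' Parameters whose values are genuinely ambiguous in the underlying method
#' — the interaction score threshold (score scales differ between network
#' releases), the dependency "variation" statistic, the logarithm base of
#' the weight function, and any experimental z cut — have **no silent
#' defaults**: they must be present, and every threshold used ends up in
#' the run manifest.
#'
#' @param config A named list (or path to a YAML file) with blocks:
#'   * `input`: either `cohort_dir` (a [write_cohort()] directory) or
#'     `interactions` + `id_mapping` + `expression` + `mutations` +
#'     `dependency` file paths;
#'   * `network`: `score_threshold` (required with `interactions`);
#'   * `weights`: `log_base` (required), optional `epsilon`,
#'     `gof_multiplier`, `missing_expression_policy`;
#'   * `labels`: `variation_statistic` (required), optional
#'     `essential_threshold` (default 0.65), `min_variation` (default 0.1);
#'   * `model`: optional `ntree`, `mtry_grid`;
#'   * `seed`: required integer.
#' @return The validated config list, invisibly classed
#'   `depnet_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  input <- config$input
  need(is.list(input), "input: block is required")
  from_cohort <- !is.null(input$cohort_dir)
  if (!from_cohort) {
    for (f in c("interactions", "id_mapping", "expression", "mutations",
                "dependency")) {
      need(is.character(input[[f]]),
           sprintf("input.%s: required when input.cohort_dir is absent", f))
    }
    need(is.numeric(config$network$score_threshold),
         "network.score_threshold: required (no silent default; state it on your file's score scale)")
  }
  need(is.numeric(config$weights$log_base),
       "weights.log_base: required (no silent default; natural log is exp(1))")
  need(is.character(config$labels$variation_statistic) &&
         config$labels$variation_statistic %in% c("variance", "sd", "range"),
       "labels.variation_statistic: required, one of variance/sd/range")
  need(is.numeric(config$seed), "seed: required integer")
  if (length(problems) > 0L) {
    stopf("invalid pipeline config:\n  - %s",
          paste(problems, collapse = "\n  - "),
          class = "depnet_config_error")
  }
  config$labels$essential_threshold <- config$labels$essential_threshold %||% 0.65
  config$labels$min_variation <- config$labels$min_variation %||% 0.1
  structure(config, class = c("depnet_config", "list"))
}

#' Run the full per-cell-line pipeline
#'
#' Executes build-network, personalize, features, normalize, labels/splits,
#' train and same-line evaluation in order, writing every intermediate under
#' `out_dir` together with a run manifest (config snapshot, seed, input file
#' digests, package version, per-stage parameters). With `resume = TRUE`,
#' stages whose outputs already exist are loaded instead of recomputed.
#'
#' @param config A config list, YAML path, or [validate_config()] result.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage outputs (default `FALSE`).
#' @return A list with `evaluations` (tibble: one row per cell line),
#'   `manifest` (the manifest list) and `paths`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- check_seed(config$seed)
  wp <- weight_params(
    epsilon = config$weights$epsilon %||% 1e-10,
    gof_multiplier = config$weights$gof_multiplier %||% 10,
    missing_expression_policy = config$weights$missing_expression_policy %||%
      "treat_as_zero",
    log_base = config$weights$log_base
  )

  input_files <- character(0)
  if (!is.null(config$input$cohort_dir)) {
    cohort <- read_cohort(config$input$cohort_dir)
    net <- cohort$network
    profiles <- cohort$profiles
    dep <- cohort$dependency
    input_files <- file.path(config$input$cohort_dir,
                             c("edges.tsv", "expression.tsv", "mutations.tsv",
                               "dependency.csv"))
  } else {
    rec <- load_interactions(config$input$interactions,
                             config$network$score_threshold)
    mapping <- read_id_mapping(config$input$id_mapping)
    net <- build_network(map_to_genes(rec, mapping, on_missing = "drop"))
    expr_tab <- readr::read_tsv(config$input$expression,
                                col_types = readr::cols(gene_id = "c",
                                                        .default = "d"),
                                progress = FALSE, show_col_types = FALSE)
    mut <- readr::read_tsv(config$input$mutations, col_types = "ccccc",
                           progress = FALSE, show_col_types = FALSE)
    profiles <- purrr::map(
      setNames(nm = setdiff(names(expr_tab), "gene_id")),
      function(cl) cell_line_profile(
        cl, setNames(expr_tab[[cl]], expr_tab$gene_id),
        dplyr::filter(mut, .data$cell_line_id == cl)[
          , c("gene_id", "consequence", "pathogenicity", "gene_role")]
      )
    )
    dep <- read_dependency_matrix(config$input$dependency)
    input_files <- unlist(config$input[c("interactions", "id_mapping",
                                         "expression", "mutations",
                                         "dependency")])
  }
  write_edge_tsv(net, file.path(out_dir, "network_edges.tsv"))
  network_summary(net, file.path(out_dir, "network_summary.json"))

  keep_genes <- variance_filter(dep,
                                min_variation = config$labels$min_variation,
                                statistic = config$labels$variation_statistic)
  labels <- call_cell_essential(dep,
                                threshold = config$labels$essential_threshold)
  labels <- dplyr::filter(labels, .data$gene_id %in% keep_genes)

  evaluations <- purrr::imap_dfr(profiles, function(prof, cl) {
    ft_path <- file.path(out_dir, sprintf("features_%s.tsv", cl))
    if (resume && file.exists(ft_path)) {
      nf <- read_feature_table(ft_path)
    } else {
      pers <- personalize(net, prof, wp)
      nf <- normalize_features(compute_node_features(pers))
      write_feature_table(nf, ft_path)
    }
    split <- tryCatch(
      balanced_split(labels, cl, seed = seed, genes = nf$gene_id),
      depnet_argument_error = function(e) NULL
    )
    if (is.null(split)) {
      return(tibble(cell_line_id = cl, auc = NA_real_, n_test = 0L,
                    n_removed = 0L, note = "minority class too small"))
    }
    model <- train_dependency_classifier(
      nf, split, seed = seed,
      hyperparams = list(
        ntree = config$model$ntree %||% 500L,
        mtry_grid = config$model$mtry_grid %||% c(2L, 3L, 4L)
      )
    )
    ev <- cross_evaluate(model, nf, split$test, split$labels)
    tibble(cell_line_id = cl, auc = ev$auc, n_test = ev$n_test,
           n_removed = ev$n_removed, note = NA_character_)
  })
  readr::write_tsv(evaluations, file.path(out_dir, "evaluations.tsv"),
                   progress = FALSE)

  manifest <- list(
    tool = "depnet", version = as.character(packageVersion("depnet")),
    seed = seed,
    config = unclass(config),
    input_digests = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    stages = list(
      network = list(n_nodes = igraph::vcount(net),
                     n_edges = igraph::ecount(net)),
      weights = unclass(wp),
      labels = list(essential_threshold = config$labels$essential_threshold,
                    variation_statistic = config$labels$variation_statistic,
                    min_variation = config$labels$min_variation,
                    n_genes_retained = length(keep_genes)),
      model = list(ntree = config$model$ntree %||% 500L,
                   mtry_grid = config$model$mtry_grid %||% c(2L, 3L, 4L))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(evaluations = evaluations, manifest = manifest,
       paths = list(out_dir = out_dir))
}
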