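#' Read a STRING-style edge list and filter by confidence score
#'
#' Reads a tab-separated protein interaction table (two identifier columns
#' followed by one or more numeric confidence channels, with a header row —
#' the STRING "detailed links" dialect) and keeps only interactions whose
#' chosen score channel *strictly exceeds* `score_threshold`.
#'
#' The threshold has no default on purpose: STRING channel scores exist in
#' 0–1000 and rescaled variants, so the caller must state the cut on the
#' scale of their file.
#'
#' @param path Path to a tab-separated file. The first two columns are the
#'   interacting protein identifiers; remaining columns are numeric scores.
#' @param score_threshold Interactions with score strictly greater than this
#'   value are kept. Mandatory.
#' @param score_column Name of the score column to filter on. If the file has
#'   no column of that name, the third column is used (headerless three-column
#'   toy files are accepted too).
#' @return A tibble with columns `protein_a`, `protein_b`,
#'   `experimental_score`, in file row order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "protein1\tprotein2\texperimental",
#'   "ENSP1\tENSP2\t85", "ENSP1\tENSP3\t80",
#'   "ENSP2\tENSP3\t200", "ENSP3\tENSP4\t12"
#' ), f)
#' load_interactions(f, score_threshold = 80)
load_interactions <- function(path, score_threshold, score_column = "experimental") {
  check_string(path, "path")
  check_number(score_threshold, "score_threshold")
  if (!file.exists(path)) {
    stopf("interaction file not found: '%s'", path, class = "depnet_io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\S+\t\\S+\t[0-9.eE+-]+(\t|$)", first)
  raw <- readr::read_tsv(
    path, col_names = has_header, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 3L) {
    stopf("interaction file '%s' must have at least 3 columns, found %d",
          path, ncol(raw), class = "depnet_format_error")
  }
  score_idx <- match(score_column, names(raw))
  if (is.na(score_idx)) score_idx <- 3L
  scores <- suppressWarnings(as.numeric(raw[[score_idx]]))
  bad <- which(is.na(scores))
  if (length(bad) > 0L) {
    stopf("unparseable score '%s' in '%s' at data row %d",
          raw[[score_idx]][bad[1L]], path, bad[1L],
          class = "depnet_format_error")
  }
  if (any(scores < 0)) {
    stopf("negative score at data row %d of '%s'", which(scores < 0)[1L], path,
          class = "depnet_format_error")
  }
  out <- tibble(
    protein_a = as.character(raw[[1L]]),
    protein_b = as.character(raw[[2L]]),
    experimental_score = scores
  )
  if (any(!nzchar(out$protein_a)) || any(!nzchar(out$protein_b))) {
    stopf("empty protein identifier in '%s'", path,
          class = "depnet_format_error")
  }
  dplyr::filter(out, .data$experimental_score > score_threshold)
}

#' Read a protein-to-gene identifier mapping
#'
#' @param path Two-column tab-separated file (protein ID, gene ID), with or
#'   without a header row.
#' @return A tibble with columns `protein_id`, `gene_id`.
#' @export
read_id_mapping <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) {
    stopf("mapping file not found: '%s'", path, class = "depnet_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2L) {
    stopf("mapping file '%s' must have 2 columns", path,
          class = "depnet_format_error")
  }
  out <- tibble(protein_id = raw[[1L]], gene_id = raw[[2L]])
  validate_id_mapping(out)
}

validate_id_mapping <- function(mapping) {
  mapping <- as_tibble(mapping)
  if (!all(c("protein_id", "gene_id") %in% names(mapping))) {
    stopf("mapping must have columns `protein_id` and `gene_id`",
          class = "depnet_argument_error")
  }
  if (any(is.na(mapping$gene_id)) || any(!nzchar(mapping$gene_id))) {
    stopf("mapping contains empty gene IDs", class = "depnet_format_error")
  }
  if (anyDuplicated(mapping$protein_id)) {
    dup <- mapping$protein_id[duplicated(mapping$protein_id)][1L]
    stopf("protein ID '%s' maps to more than one gene", dup,
          class = "depnet_format_error")
  }
  mapping
}

#' Translate protein-level interactions to gene-level interactions
#'
#' Both endpoints of every interaction are translated with a protein-to-gene
#' lookup. Several proteins may map to one gene, so translated records can be
#' self-pairs; those are retained here (the mapping report stays faithful to
#' the input) and removed when the graph is assembled by [build_network()].
#'
#' @param records Tibble of interactions as returned by [load_interactions()].
#' @param mapping Tibble with columns `protein_id`, `gene_id` (one gene per
#'   protein).
#' @param on_missing What to do with records whose endpoint has no mapping:
#'   `"drop"` removes them (the number dropped is reported as a message and
#'   stored in the `n_dropped` attribute), `"error"` aborts naming the first
#'   unmapped protein ID.
#' @return A tibble with columns `gene_a`, `gene_b`, `experimental_score`,
#'   with attribute `n_dropped`.
#' @export
map_to_genes <- function(records, mapping, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  records <- as_tibble(records)
  mapping <- validate_id_mapping(mapping)
  lookup <- setNames(mapping$gene_id, mapping$protein_id)
  ga <- unname(lookup[records$protein_a])
  gb <- unname(lookup[records$protein_b])
  unmapped <- is.na(ga) | is.na(gb)
  if (on_missing == "error" && any(unmapped)) {
    miss <- c(records$protein_a[is.na(ga)], records$protein_b[is.na(gb)])
    stopf("no gene mapping for protein ID '%s'", miss[1L],
          class = "depnet_mapping_error")
  }
  out <- tibble(
    gene_a = ga[!unmapped],
    gene_b = gb[!unmapped],
    experimental_score = records$experimental_score[!unmapped]
  )
  n_dropped <- sum(unmapped)
  if (n_dropped > 0L) {
    message(sprintf("map_to_genes: dropped %d record(s) with unmapped endpoints",
                    n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
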