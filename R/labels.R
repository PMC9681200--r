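#' Read a DepMap-style dependency-probability matrix
#'
#' Genes are rows and cell lines columns (entries are probabilities that the
#' cell line depends on the gene). Gene headers of the DepMap export dialect
#' `"SYMBOL (HGNC_ID)"` have their parenthesized suffix stripped.
#'
#' @param path CSV or TSV file; first column gene IDs, remaining columns one
#'   per cell line.
#' @param tissues Optional named character vector mapping cell-line ID to
#'   tissue label.
#' @return A long tibble with columns `gene_id`, `cell_line_id`,
#'   `probability` and (if given) `tissue`.
#' @export
read_dependency_matrix <- function(path, tissues = NULL) {
  check_string(path, "path")
  if (!file.exists(path)) {
    stopf("dependency matrix not found: '%s'", path, class = "depnet_io_error")
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, progress = FALSE,
                           show_col_types = FALSE)
  names(raw)[1L] <- "gene_id"
  raw$gene_id <- sub("\\s*\\(.*\\)\\s*$", "", raw$gene_id)
  out <- tidyr::pivot_longer(raw, -"gene_id", names_to = "cell_line_id",
                             values_to = "probability")
  validate_dependency_matrix(out, tissues)
}

validate_dependency_matrix <- function(dm, tissues = NULL) {
  dm <- as_tibble(dm)
  needed <- c("gene_id", "cell_line_id", "probability")
  if (!all(needed %in% names(dm))) {
    stopf("dependency data must have columns %s",
          paste(needed, collapse = ", "), class = "depnet_argument_error")
  }
  if (any(is.na(dm$probability)) ||
      any(dm$probability < 0) || any(dm$probability > 1)) {
    stopf("dependency probabilities must lie in [0, 1]",
          class = "depnet_format_error")
  }
  if (anyDuplicated(dm[, c("gene_id", "cell_line_id")])) {
    stopf("duplicate (gene, cell line) entries in dependency data",
          class = "depnet_format_error")
  }
  if (!is.null(tissues) && !"tissue" %in% names(dm)) {
    dm$tissue <- unname(tissues[dm$cell_line_id])
  }
  dm
}

#' Call cell-essential genes from dependency probabilities
#'
#' A gene is cell-essential in a cell line when the dependency probability
#' *strictly exceeds* the threshold (default 0.65).
#'
#' @param dm Long dependency tibble (`gene_id`, `cell_line_id`,
#'   `probability`), e.g. from [read_dependency_matrix()].
#' @param threshold Probability cut in (0, 1); strict.
#' @return The input tibble with an added integer `label` column (1 =
#'   cell-essential) and an `essential_in` column counting, per gene, the
#'   cell lines in which it is essential.
#' @export
call_cell_essential <- function(dm, threshold = 0.65) {
  check_number(threshold, "threshold", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  dm <- validate_dependency_matrix(dm)
  dm$label <- as.integer(dm$probability > threshold)
  dm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(essential_in = sum(.data$label)) |>
    dplyr::ungroup()
}

#' Genes essential in every cell line
#'
#' @param ls A label tibble from [call_cell_essential()].
#' @return Character vector of pan-essential gene IDs (essential in all cell
#'   lines present in the table).
#' @export
pan_essential_set <- function(ls) {
  ls <- as_tibble(ls)
  if (nrow(ls) == 0L) return(character(0))
  n_lines <- dplyr::n_distinct(ls$cell_line_id)
  counts <- ls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_ess = sum(.data$label), n_obs = dplyr::n(),
                     .groups = "drop")
  counts$gene_id[counts$n_ess == n_lines & counts$n_obs == n_lines]
}

#' Filter genes by cross-cell-line dependency variation
#'
#' Genes that are almost always or almost never essential carry little
#' cell-line-specific information; this keeps only genes whose dependency
#' probabilities vary across cell lines. "Variation" is ambiguous between
#' variance, standard deviation and range, so the statistic must be chosen
#' explicitly.
#'
#' @param dm Long dependency tibble.
#' @param min_variation Minimum dispersion to retain a gene (default 0.1).
#' @param statistic `"variance"` (sample variance), `"sd"` or `"range"`.
#' @return Character vector of retained gene IDs.
#' @export
variance_filter <- function(dm, min_variation = 0.1,
                            statistic = c("variance", "sd", "range")) {
  statistic <- match.arg(statistic)
  check_number(min_variation, "min_variation", lower = 0)
  dm <- validate_dependency_matrix(dm)
  stat_fun <- switch(statistic,
    variance = function(x) if (length(x) < 2L) 0 else var(x),
    sd = function(x) if (length(x) < 2L) 0 else sd(x),
    range = function(x) diff(range(x))
  )
  disp <- dm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dispersion = stat_fun(.data$probability),
                     .groups = "drop")
  disp$gene_id[disp$dispersion >= min_variation]
}

#' Class-balanced train/validation/test split for one cell line
#'
#' The majority class is downsampled (seeded, without replacement) to the
#' minority class size; the balanced pool is then partitioned 60/20/20 into
#' train, validation and test sets, stratified by class so every partition
#' stays balanced to within one gene.
#'
#' @param ls Label tibble from [call_cell_essential()].
#' @param cell_line Cell line to split.
#' @param seed Integer seed; the same seed reproduces the split exactly.
#' @param test_frac,val_frac Fractions of the balanced pool held out for
#'   test and validation (defaults 0.2 and 0.2).
#' @param genes Optional universe of usable genes (e.g. genes with computed
#'   features); labels outside it are ignored.
#' @return A list of class `depnet_split` with character vectors `train`,
#'   `validation`, `test`, a `labels` lookup and provenance fields.
#' @export
balanced_split <- function(ls, cell_line, seed, test_frac = 0.2,
                           val_frac = 0.2, genes = NULL) {
  check_string(cell_line, "cell_line")
  check_number(test_frac, "test_frac", lower = 0, upper = 0.5)
  check_number(val_frac, "val_frac", lower = 0, upper = 0.5)
  sub <- dplyr::filter(as_tibble(ls), .data$cell_line_id == cell_line)
  if (!is.null(genes)) sub <- dplyr::filter(sub, .data$gene_id %in% genes)
  if (nrow(sub) == 0L) {
    stopf("no labelled genes for cell line '%s'", cell_line,
          class = "depnet_argument_error")
  }
  pos <- sub$gene_id[sub$label == 1L]
  neg <- sub$gene_id[sub$label == 0L]
  n_min <- min(length(pos), length(neg))
  if (n_min < 10L) {
    stopf("cell line '%s' has only %d genes in its minority class (>= 10 required)",
          cell_line, n_min, class = "depnet_argument_error")
  }
  with_seed(seed, {
    pos <- sample(pos, n_min)
    neg <- sample(neg, n_min)
    part <- function(ids) {
      n <- length(ids)
      n_test <- round(test_frac * n)
      n_val <- round(val_frac * n)
      list(test = ids[seq_len(n_test)],
           validation = ids[n_test + seq_len(n_val)],
           train = ids[-seq_len(n_test + n_val)])
    }
    p <- part(pos)
    n <- part(neg)
    labels <- setNames(
      c(rep(1L, n_min), rep(0L, n_min)),
      c(pos, neg)
    )
    structure(
      list(
        train = c(p$train, n$train),
        validation = c(p$validation, n$validation),
        test = c(p$test, n$test),
        labels = labels,
        cell_line_id = cell_line,
        seed = check_seed(seed),
        balanced = TRUE
      ),
      class = "depnet_split"
    )
  })
}

#' @export
print.depnet_split <- function(x, ...) {
  cat(sprintf(
    "<depnet_split> %s: train %d / validation %d / test %d (balanced, seed %d)\n",
    x$cell_line_id, length(x$train), length(x$validation), length(x$test),
    x$seed
  ))
  invisible(x)
}

#' Stratify cell-essential genes by dependency rarity
#'
#' Bins genes by the number of cell lines in which they are cell-essential:
#' an `"all"` stratum (essential everywhere), one `"<b"` stratum per bound
#' `b` (essential in fewer than `b` lines, but at least one), and a `"1"`
#' stratum (essential in exactly one line). The `<b` strata nest by
#' construction.
#'
#' @param ls Label tibble from [call_cell_essential()].
#' @param bounds Integer caps for the `<b` strata (default `c(30, 20, 10)`).
#' @return Named list of character vectors of gene IDs.
#' @export
rarity_strata <- function(ls, bounds = c(30, 20, 10)) {
  if (length(bounds) == 0L) {
    stopf("`bounds` must be non-empty", class = "depnet_argument_error")
  }
  ls <- as_tibble(ls)
  n_lines <- dplyr::n_distinct(ls$cell_line_id)
  counts <- ls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_ess = sum(.data$label), .groups = "drop") |>
    dplyr::filter(.data$n_ess > 0L)
  strata <- list(all = counts$gene_id[counts$n_ess == n_lines])
  for (b in sort(as.integer(bounds), decreasing = TRUE)) {
    strata[[paste0("<", b)]] <- counts$gene_id[counts$n_ess < b]
  }
  strata[["1"]] <- counts$gene_id[counts$n_ess == 1L]
  strata
}
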