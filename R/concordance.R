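#' Build a screen table from replicate viability z-scores and predictions
#'
#' Joins replicate-level siRNA viability z-scores (negative = reduced
#' viability on knockdown) with predicted cell-essentiality likelihoods.
#' When replicate columns are present, `mean_z` is their arithmetic mean;
#' tables already summarized to a mean z-score are accepted as is.
#'
#' @param df Data frame with `gene_id`, a `likelihood` column, and either a
#'   `mean_z` column or one or more `z`-prefixed replicate columns
#'   (`z1`, `z2`, ...).
#' @return A tibble with `gene_id`, `mean_z`, `likelihood` (class
#'   `depnet_screen`).
#' @export
screen_table <- function(df) {
  df <- as_tibble(df)
  if (!all(c("gene_id", "likelihood") %in% names(df))) {
    stopf("screen data needs `gene_id` and `likelihood` columns",
          class = "depnet_argument_error")
  }
  rep_cols <- grep("^z[0-9]+$", names(df), value = TRUE)
  if (!"mean_z" %in% names(df)) {
    if (length(rep_cols) == 0L) {
      stopf("screen data needs `mean_z` or replicate columns z1, z2, ...",
            class = "depnet_argument_error")
    }
    df$mean_z <- rowMeans(df[, rep_cols, drop = FALSE])
  }
  if (any(df$likelihood < 0 | df$likelihood > 1)) {
    stopf("likelihoods must lie in [0, 1]", class = "depnet_format_error")
  }
  out <- df[, c("gene_id", "mean_z", "likelihood",
                rep_cols[rep_cols %in% names(df)])]
  class(out) <- c("depnet_screen", class(out))
  out
}

#' Concordance between predictions and an siRNA viability screen
#'
#' Classifies genes as predicted cell-essential (likelihood strictly above
#' `hi`) or predicted non-cell-essential (likelihood strictly below `lo`);
#' genes between the cuts are excluded as unclassified. The experimental
#' call is `mean_z < z_cut` (reduced viability on knockdown). `z_cut` has no
#' default: the viability threshold that defines an experimental essential
#' is a study-level choice that must be stated.
#'
#' Returned alongside the confusion metrics are three parameter-free
#' helper counts used when inspecting a screen against its predictions:
#' how many of the top-`k` genes by likelihood have a negative mean z-score,
#' how many genes fall below a z threshold, and how many of those are also
#' predicted essential at `hi`.
#'
#' @param st A [screen_table()].
#' @param hi,lo Likelihood cuts for predicted essential / non-essential
#'   (defaults 0.85 and 0.15; `hi > lo` required).
#' @param z_cut Experimental z threshold defining an essential call.
#'   Mandatory.
#' @param top_k Size of the top-likelihood helper count (default 10).
#' @param z_threshold z bound for the helper counts (default `z_cut`).
#' @return A list of class `depnet_concordance`: `accuracy`, `sensitivity`,
#'   `fdr`, the confusion counts (`tp`, `fp`, `tn`, `fn`), `n_classified`,
#'   `n_unclassified`, and helpers `top_k_negative_z`, `n_below_z`,
#'   `below_z_and_predicted` (with the gene IDs of the latter).
#' @export
screen_concordance <- function(st, hi = 0.85, lo = 0.15, z_cut,
                               top_k = 10L, z_threshold = z_cut) {
  stopifnot(inherits(st, "depnet_screen") || is.data.frame(st))
  st <- as_tibble(st)
  check_number(hi, "hi", lower = 0, upper = 1)
  check_number(lo, "lo", lower = 0, upper = 1)
  if (hi <= lo) {
    stopf("`hi` (%s) must exceed `lo` (%s)", format(hi), format(lo),
          class = "depnet_argument_error")
  }
  check_number(z_cut, "z_cut")

  pred_pos <- st$likelihood > hi
  pred_neg <- st$likelihood < lo
  classified <- pred_pos | pred_neg
  exp_pos <- st$mean_z < z_cut

  tp <- sum(pred_pos & exp_pos)
  fp <- sum(pred_pos & !exp_pos)
  tn <- sum(pred_neg & !exp_pos)
  fn <- sum(pred_neg & exp_pos)

  top <- st[order(-st$likelihood), ][seq_len(min(top_k, nrow(st))), ]
  below <- st$mean_z < z_threshold
  both <- below & st$likelihood > hi

  structure(
    list(
      accuracy = if (tp + fp + tn + fn > 0) (tp + tn) / (tp + fp + tn + fn) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
      tp = tp, fp = fp, tn = tn, fn = fn,
      n_classified = sum(classified),
      n_unclassified = sum(!classified),
      top_k_negative_z = sum(top$mean_z < 0),
      n_below_z = sum(below),
      below_z_and_predicted = sum(both),
      below_z_and_predicted_genes = st$gene_id[both],
      params = list(hi = hi, lo = lo, z_cut = z_cut, top_k = top_k,
                    z_threshold = z_threshold)
    ),
    class = "depnet_concordance"
  )
}

#' @export
print.depnet_concordance <- function(x, ...) {
  cat(sprintf(
    paste0("<depnet_concordance> accuracy %.2f, sensitivity %.2f, FDR %.2f ",
           "(%d classified, %d unclassified)\n"),
    x$accuracy, x$sensitivity, x$fdr, x$n_classified, x$n_unclassified
  ))
  cat(sprintf("  top-%d by likelihood with negative mean z: %d\n",
              x$params$top_k, x$top_k_negative_z))
  cat(sprintf("  genes with mean z < %s: %d (of which predicted essential: %d)\n",
              format(x$params$z_threshold), x$n_below_z,
              x$below_z_and_predicted))
  invisible(x)
}

#' Bundled MCF7 screen summary tables
#'
#' Two published summary tables from a triplicate siRNA viability screen of
#' 240 DNA-damage-response genes in the MCF7 breast cancer cell line, joined
#' with pan-tissue classifier likelihoods: the ten genes with the highest
#' predicted cell-essentiality likelihood, and the ten genes with the lowest
#' mean viability z-scores.
#'
#' @param which `"top_likelihood"` or `"lowest_z"`.
#' @return A [screen_table()] tibble.
#' @export
#' @examples
#' mcf7_screen_table("top_likelihood")
mcf7_screen_table <- function(which = c("top_likelihood", "lowest_z")) {
  which <- match.arg(which)
  file <- switch(which,
    top_likelihood = "mcf7_top10_likelihood.tsv",
    lowest_z = "mcf7_bottom10_zscore.tsv"
  )
  path <- system.file("extdata", file, package = "depnet", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = "cdd", progress = FALSE,
                        show_col_types = FALSE)
  screen_table(df)
}
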