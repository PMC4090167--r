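#' Load a miRNA target-prediction table
#'
#' Reads the flat prediction dialect `mir, gene, db_count, flag_a..flag_e`
#' (tab-separated), where `db_count` is the number of prediction algorithms
#' supporting the pair and the flags carry the five stringency criteria
#' (seed complementarity, conservation, thermodynamic stability, multiple
#' sites, central loop) as metadata. Pairs supported by fewer than
#' `min_algorithms` databases are dropped; a lower threshold is the
#' "less stringent" mode.
#'
#' @param path Path to the predictions TSV.
#' @param min_algorithms Minimum number of supporting algorithms
#'   (3 = strict default, 1 = lenient).
#' @return Tibble of retained predictions, one row per (miRNA, gene) pair.
#' @export
load_predictions <- function(path, min_algorithms = 3) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    mir = readr::col_character(), gene = readr::col_character(),
    db_count = readr::col_integer(), .default = readr::col_logical()))
  if (!all(c("mir", "gene", "db_count") %in% names(x))) {
    abort("predictions file needs columns `mir`, `gene`, `db_count`.")
  }
  bad <- which(is.na(x$mir) | is.na(x$gene) | x$gene == "" | is.na(x$db_count))
  if (length(bad)) {
    abort(paste0("malformed prediction row(s) at line(s): ",
                 paste(bad + 1, collapse = ", ")))
  }
  filter_predictions(x, min_algorithms)
}

#' @rdname load_predictions
#' @param predictions An in-memory predictions tibble (same columns).
#' @export
filter_predictions <- function(predictions, min_algorithms = 3) {
  predictions[predictions$db_count >= min_algorithms, , drop = FALSE]
}

#' Intersect differentially expressed genes with predicted targets
#'
#' Produces one candidate pair per (DE miRNA, DE gene) combination for
#' which the gene lies in that miRNA's prediction set. Gene symbols are
#' matched case-insensitively. Candidate genes hit by several miRNAs are
#' counted once in the unique-gene summary.
#'
#' @param de_mirs Tibble of differentially expressed miRNAs with
#'   `feature_id` and `signed_fc`.
#' @param de_genes Tibble of differentially expressed genes with `gene`
#'   and `signed_fc`.
#' @param predictions Predictions tibble (`mir`, `gene`, ...), already at
#'   the desired stringency.
#' @return Tibble of candidate pairs: `mir`, `gene`, `predicted` (always
#'   `TRUE` here), `fc_mir`, `fc_gene`; attribute `n_unique_genes`.
#' @export
intersect_candidates <- function(de_mirs, de_genes, predictions) {
  stopifnot(all(c("feature_id", "signed_fc") %in% names(de_mirs)),
            all(c("gene", "signed_fc") %in% names(de_genes)))
  preds <- predictions |>
    dplyr::mutate(gene_key = toupper(.data$gene)) |>
    dplyr::filter(.data$mir %in% de_mirs$feature_id)
  genes <- de_genes |>
    dplyr::mutate(gene_key = toupper(.data$gene))
  out <- preds |>
    dplyr::inner_join(genes, by = "gene_key", suffix = c("_pred", "")) |>
    dplyr::inner_join(de_mirs, by = c(mir = "feature_id"),
                      suffix = c("_gene", "_mir")) |>
    dplyr::transmute(
      mir = .data$mir, gene = .data$gene, predicted = TRUE,
      fc_mir = .data$signed_fc_mir, fc_gene = .data$signed_fc_gene) |>
    dplyr::distinct(.data$mir, .data$gene, .keep_all = TRUE)
  attr(out, "n_unique_genes") <- length(unique(out$gene))
  out
}
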