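# Small builders shared across the suite.

# Wide expression tibble from a matrix (features x samples).
toy_expr <- function(m, id_col = "feature_id") {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  mirdcx::as_expr_tbl(m, id_col)
}

toy_design <- function(n1, n2, levels = c("F-BC", "NF-BC"),
                       ids = c(paste0("s", seq_len(n1 + n2)))) {
  tibble::tibble(sample_id = ids, group = rep(levels, c(n1, n2)))
}

# A normalized log2 miRNA expression table plus design straight from a
# generated cohort, ready for the statistical stages.
cohort_mir_log2 <- function(cohort, method = "median") {
  flt <- mirdcx::filter_detected(cohort$ct, cohort$design,
                                 controls = cohort$truth$controls)
  dct <- mirdcx::delta_ct(flt$retained)
  log2e <- dct
  log2e[-1] <- lapply(log2e[-1], function(x) -x)
  log2e <- log2e[!log2e$probe_id %in% cohort$truth$controls, ]
  keep <- !apply(is.na(mirdcx::expr_matrix(log2e)), 1, any)
  mirdcx::normalize_between_samples(log2e[keep, ], method)
}

# Build a dcx_result-like tibble by hand (for classification/summary/export
# tests that start from known categories).
toy_dcx_result <- function(mir, gene, r1, r2, p, predicted, fc_mir, fc_gene,
                           alpha = 0.05, groups = c("F-BC", "NF-BC")) {
  out <- tibble::tibble(
    mir = mir, gene = gene, r_group1 = r1, r_group2 = r2,
    delta_r = abs(r1 - r2), p_perm = p, significant = p < alpha,
    n_invalid = 0, predicted = predicted, fc_mir = fc_mir, fc_gene = fc_gene)
  out$category <- ifelse(out$significant,
                         mirdcx::classify_interaction(predicted, fc_mir, fc_gene),
                         NA_character_)
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- groups
  class(out) <- c("dcx_result", class(out))
  out
}
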