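#' Pearson correlation with pairwise missing handling
#'
#' Standard product-moment correlation on the complete pairs of two
#' vectors. A constant vector makes the correlation undefined; it is
#' reported as `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient, or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) abort("pearson_r needs at least 3 complete pairs.")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Correlation per column pair between two sample x pair matrices over a
# sample index subset; returns NA where a vector is constant.
col_pair_cor <- function(X, Y, idx) {
  n <- length(idx)
  Xs <- X[idx, , drop = FALSE]; Ys <- Y[idx, , drop = FALSE]
  cx <- colMeans(Xs); cy <- colMeans(Ys)
  sxy <- colSums(Xs * Ys) - n * cx * cy
  sxx <- colSums(Xs * Xs) - n * cx^2
  syy <- colSums(Ys * Ys) - n * cy^2
  den <- sxx * syy
  out <- rep(NA_real_, length(sxy))
  pos <- den > 0
  out[pos] <- sxy[pos] / sqrt(den[pos])
  out
}

# Assemble aligned sample x pair value matrices for the requested pairs.
pair_value_matrices <- function(mir_expr, gene_expr, pairs) {
  mm <- expr_matrix(mir_expr)
  gm <- expr_matrix(gene_expr)
  if (!setequal(colnames(mm), colnames(gm))) {
    abort("miRNA and gene expression tables must cover the same samples.")
  }
  gm <- gm[, colnames(mm), drop = FALSE]
  bad_m <- setdiff(unique(pairs$mir), rownames(mm))
  bad_g <- setdiff(unique(pairs$gene), rownames(gm))
  if (length(bad_m) || length(bad_g)) {
    abort(paste0("pair feature(s) absent from the expression tables: ",
                 paste(c(bad_m, bad_g), collapse = ", ")))
  }
  list(X = t(mm[pairs$mir, , drop = FALSE]),
       Y = t(gm[pairs$gene, , drop = FALSE]),
       samples = colnames(mm))
}

#' Group-wise miRNA-gene co-expression
#'
#' Computes the Pearson correlation of every requested (gene, miRNA) pair
#' separately within each group, over that group's samples only.
#'
#' @param mir_expr Wide miRNA expression tibble (log2 scale recommended).
#' @param gene_expr Wide gene expression tibble over the same samples.
#' @param design Tibble with `sample_id`, `group`.
#' @param mirs,genes Feature sets to cross; every (gene, miRNA) combination
#'   is computed.
#' @return A `coexpr_tbl` tibble: `gene`, `mir`, `group`, `r`.
#' @export
coexpr_matrices <- function(mir_expr, gene_expr, design, mirs, genes) {
  pairs <- tidyr::expand_grid(mir = mirs, gene = genes)
  pm <- pair_value_matrices(mir_expr, gene_expr, pairs)
  d <- check_design(design, pm$samples)
  res <- lapply(seq_along(d$levels), function(g) {
    idx <- match(if (g == 1) d$g1 else d$g2, pm$samples)
    tibble::tibble(gene = pairs$gene, mir = pairs$mir,
                   group = d$levels[g], r = col_pair_cor(pm$X, pm$Y, idx))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("coexpr_tbl", class(out))
  out
}

#' Extract one group's co-expression matrix
#'
#' @param coexpr A `coexpr_tbl` from [coexpr_matrices()].
#' @param group Group label to extract.
#' @return A genes x miRNAs correlation matrix.
#' @export
coexpr_matrix <- function(coexpr, group) {
  x <- coexpr[coexpr$group == group, ]
  if (!nrow(x)) abort(paste0("no co-expression rows for group '", group, "'."))
  tidyr::pivot_wider(x[, c("gene", "mir", "r")], names_from = "mir",
                     values_from = "r") |>
    tibble::column_to_rownames("gene") |>
    as.matrix()
}

#' Heatmap of group-wise co-expression matrices
#'
#' @param object A `coexpr_tbl`.
#' @param ... Unused.
#' @return A ggplot object (one facet per group, red-green fill over
#'   `[-1, 1]`).
#' @export
autoplot.coexpr_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mir, y = .data$gene,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_gradient2(low = "green3", mid = "black",
                                  high = "red2", limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   axis.text.y = ggplot2::element_text(size = 6)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Permutation test for differential co-expression
#'
#' For each (miRNA, gene) pair the observed statistic is
#' `delta_r = |r_group1 - r_group2|`, the absolute difference of the
#' within-group Pearson correlations. The null distribution is built by
#' randomly reassigning samples to two groups of the ORIGINAL sizes
#' (without replacement, independently each iteration) and recomputing
#' `delta_r`; each pair is compared to its own permutation distribution.
#' With sampled permutations `p = (1 + #(delta_r* >= delta_r)) / (1 + N)`;
#' when `choose(n, n1) <= n_perm` all distinct assignments are enumerated
#' instead and the exact tail fraction is returned. Permutations in which a
#' pair's correlation is undefined (constant vector) are excluded from that
#' pair's null count; the tally is recorded in the `n_invalid` column.
#'
#' @param mir_expr,gene_expr Wide expression tibbles over the same samples
#'   (log2 scale recommended; Pearson correlation on heavy-tailed linear
#'   `2^-dCT` values is unstable).
#' @param design Tibble with `sample_id`, `group`.
#' @param pairs Tibble with `mir`, `gene` and optionally `predicted`
#'   (logical) and `fc_mir`/`fc_gene` (signed fold changes, enabling
#'   interaction classification).
#' @param n_perm Number of permutations (study value: 100,000).
#' @param alpha Significance level on the permutation p (study value 0.05).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return A `dcx_result` tibble: `mir`, `gene`, `r_group1`, `r_group2`,
#'   `delta_r`, `p_perm`, `significant`, `n_invalid`, plus `predicted` and
#'   `category` when fold changes are supplied. Attributes record `n_perm`,
#'   `alpha`, `exhaustive` and the group labels.
#' @export
perm_diff_test <- function(mir_expr, gene_expr, design, pairs,
                           n_perm = 100000, alpha = 0.05, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  stopifnot(all(c("mir", "gene") %in% names(pairs)))
  pm <- pair_value_matrices(mir_expr, gene_expr, pairs)
  d <- check_design(design, pm$samples)
  i1 <- match(d$g1, pm$samples); i2 <- match(d$g2, pm$samples)
  n1 <- length(i1); n <- length(pm$samples)
  if (n1 < 3 || length(i2) < 3) abort("need >= 3 samples per group.")
  if (anyNA(pm$X) || anyNA(pm$Y)) {
    abort("permutation engine requires complete values for the tested pairs.")
  }

  r1 <- col_pair_cor(pm$X, pm$Y, i1)
  r2 <- col_pair_cor(pm$X, pm$Y, i2)
  dr_obs <- abs(r1 - r2)

  asg <- make_assignments(n, n1, n_perm, seed)
  all_idx <- seq_len(n)
  count_ge <- numeric(nrow(pairs))
  n_valid <- numeric(nrow(pairs))
  for (j1 in asg$idx) {
    j2 <- setdiff(all_idx, j1)
    dr <- abs(col_pair_cor(pm$X, pm$Y, j1) - col_pair_cor(pm$X, pm$Y, j2))
    ok <- !is.na(dr)
    n_valid <- n_valid + ok
    count_ge <- count_ge + (ok & dr >= dr_obs - 1e-12)
  }
  p <- if (asg$exhaustive) count_ge / n_valid else
    (1 + count_ge) / (1 + n_valid)

  out <- tibble::tibble(
    mir = pairs$mir, gene = pairs$gene,
    r_group1 = r1, r_group2 = r2, delta_r = dr_obs,
    p_perm = p, significant = p < alpha,
    n_invalid = length(asg$idx) - n_valid)
  if ("predicted" %in% names(pairs)) out$predicted <- pairs$predicted
  if (all(c("fc_mir", "fc_gene") %in% names(pairs))) {
    out$fc_mir <- pairs$fc_mir
    out$fc_gene <- pairs$fc_gene
    pred <- if ("predicted" %in% names(pairs)) pairs$predicted else
      rep(FALSE, nrow(pairs))
    out$category <- dplyr::if_else(
      out$significant,
      classify_interaction(pred, pairs$fc_mir, pairs$fc_gene),
      NA_character_)
  }
  attr(out, "n_perm") <- length(asg$idx)
  attr(out, "alpha") <- alpha
  attr(out, "exhaustive") <- asg$exhaustive
  attr(out, "groups") <- d$levels
  class(out) <- c("dcx_result", class(out))
  out
}

#' Classify a significant miRNA-gene interaction
#'
#' Quadrant classification by prediction status and fold-change signs: an
#' interaction is `inverse` when the signed fold changes of the miRNA and
#' the gene have opposite signs (consistent with repressive
#' post-transcriptional regulation) and `same` otherwise. Signs are taken
#' from the log ratio, so a tie fold change of exactly +1 (log ratio 0)
#' counts as `same`.
#'
#' @param predicted Logical: pair in the target-prediction set.
#' @param fc_mir,fc_gene Signed fold changes (never strictly inside
#'   (-1, 1)).
#' @return Character vector over `predicted_inverse`, `predicted_same`,
#'   `unpredicted_inverse`, `unpredicted_same`.
#' @export
classify_interaction <- function(predicted, fc_mir, fc_gene) {
  # signed_fc of +/-x corresponds to log-ratio sign; |fc| == 1 -> log 0
  sgn <- function(fc) sign(ifelse(abs(fc) == 1, 0, fc))
  inverse <- sgn(fc_mir) * sgn(fc_gene) < 0
  paste0(ifelse(predicted, "predicted_", "unpredicted_"),
         ifelse(inverse, "inverse", "same"))
}

#' Summarise classified interactions
#'
#' Counts and one-decimal percentages per interaction category among the
#' significant pairs. The four categories partition the significant set and
#' percentages are computed against the significant total. Two rounding
#' conventions are offered: `"half_away"` (round half away from zero,
#' default) and `"truncate"`; the mode used is recorded in the result.
#'
#' @param stats A `dcx_result` with a `category` column.
#' @param rounding `"half_away"` or `"truncate"`.
#' @return Tibble with `category`, `n`, `percent`; attributes `n_significant`
#'   and `rounding`.
#' @export
summarize_interactions <- function(stats, rounding = c("half_away", "truncate")) {
  rounding <- match.arg(rounding)
  cats <- c("predicted_inverse", "predicted_same",
            "unpredicted_inverse", "unpredicted_same")
  sig <- stats[stats$significant & !is.na(stats$category), ]
  n_tot <- nrow(sig)
  n <- unname(vapply(cats, function(cc) sum(sig$category == cc), numeric(1)))
  pct_raw <- if (n_tot == 0) rep(0, length(cats)) else 100 * n / n_tot
  pct <- if (rounding == "half_away") round_half_away(pct_raw, 1) else
    trunc_digits(pct_raw, 1)
  out <- tibble::tibble(category = cats, n = as.integer(n), percent = pct)
  attr(out, "n_significant") <- n_tot
  attr(out, "rounding") <- rounding
  out
}

#' Volcano-style view of a differential co-expression result
#'
#' @param object A `dcx_result`.
#' @param ... Unused.
#' @return A ggplot of `delta_r` against `-log10(p)`, coloured by category
#'   where available.
#' @export
autoplot.dcx_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"category" %in% names(df)) df$category <- NA_character_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_r,
                                   y = -log10(.data$p_perm),
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha") %||% 0.05),
                        linetype = 2) +
    ggplot2::labs(x = expression(abs(Delta * r)), y = expression(-log[10](p)),
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Export classified interactions as bipartite networks
#'
#' Writes one bipartite miRNA-gene graph per group: node attribute `size`
#' is the absolute signed fold change, node `type` distinguishes miRNAs
#' from genes, and each edge carries that group's Pearson correlation
#' (sign and magnitude) and the interaction category. Emitted as GraphML
#' plus a flat edge-list TSV per group.
#'
#' @param stats A `dcx_result`; only rows with `significant == TRUE` are
#'   exported (all rows if none are flagged significant and `stats` is
#'   empty the files still contain valid empty graphs).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of `igraph` objects (one per group).
#' @export
export_network <- function(stats, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- attr(stats, "groups") %||% c("group1", "group2")
  sig <- stats[stats$significant %in% TRUE, , drop = FALSE]
  out <- list()
  for (g in 1:2) {
    rcol <- paste0("r_group", g)
    edges <- tibble::tibble(
      from = sig$mir, to = sig$gene, r = sig[[rcol]],
      weight = abs(sig[[rcol]]),
      category = if ("category" %in% names(sig)) sig$category else
        NA_character_)
    nodes <- tibble::tibble(
      name = c(unique(sig$mir), unique(sig$gene)),
      type = rep(c(FALSE, TRUE),
                 c(length(unique(sig$mir)), length(unique(sig$gene)))),
      role = rep(c("mir", "gene"),
                 c(length(unique(sig$mir)), length(unique(sig$gene)))))
    if ("fc_mir" %in% names(sig) && nrow(sig)) {
      fc <- c(setNames(abs(sig$fc_mir), sig$mir)[unique(sig$mir)],
              setNames(abs(sig$fc_gene), sig$gene)[unique(sig$gene)])
      nodes$size <- unname(fc)
    } else {
      nodes$size <- 1
    }
    gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    tag <- gsub("[^A-Za-z0-9]+", "", groups[g])
    igraph::write_graph(gr, file.path(dir, sprintf("%s_%s.graphml", prefix, tag)),
                        format = "graphml")
    readr::write_tsv(edges, file.path(dir, sprintf("%s_%s_edges.tsv", prefix, tag)))
    out[[groups[g]]] <- gr
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
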