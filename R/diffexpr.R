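# Group-label reassignments preserving the original group sizes. Uses
# exhaustive enumeration (which includes the observed labeling) whenever
# choose(n, n1) <= n_perm, otherwise independent random draws.
make_assignments <- function(n, n1, n_perm, seed) {
  ex <- exhaustive_assignments(n, n1, n_perm)
  if (!is.null(ex)) return(list(idx = ex, exhaustive = TRUE))
  set.seed(seed)
  list(idx = replicate(n_perm, sample.int(n, n1), simplify = FALSE),
       exhaustive = FALSE)
}

# Vectorised two-sample moments over the rows of m for one index split.
row_group_stats <- function(m, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- unname(rowMeans(m[, i1, drop = FALSE]))
  m2 <- unname(rowMeans(m[, i2, drop = FALSE]))
  ss1 <- unname(rowSums((m[, i1, drop = FALSE] - m1)^2))
  ss2 <- unname(rowSums((m[, i2, drop = FALSE] - m2)^2))
  list(m1 = m1, m2 = m2, ss1 = ss1, ss2 = ss2, n1 = n1, n2 = n2)
}

#' SAM modified t-statistic
#'
#' For each feature, `d = (mean1 - mean2) / (s + s0)` where `s` is the
#' pooled standard error
#' `sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))` and `s0` is the
#' variance-stabilising fudge constant. With `s0 = 0`, `d` is the ordinary
#' pooled two-sample t statistic.
#'
#' @param expr Wide log2-scale expression tibble.
#' @param design Tibble with `sample_id` and `group` (first level minus
#'   second level in the numerator).
#' @param s0 Fudge constant (>= 0).
#' @return Tibble with `feature_id`, `d`, `numerator` (mean difference) and
#'   `s` (pooled standard error).
#' @export
sam_statistic <- function(expr, design, s0 = 0) {
  m <- expr_matrix(expr)
  d <- check_design(design, colnames(m))
  i1 <- match(d$g1, colnames(m)); i2 <- match(d$g2, colnames(m))
  if (length(i1) < 2 || length(i2) < 2) abort("need >= 2 samples per group.")
  st <- row_group_stats(m, i1, i2)
  s <- sqrt((1 / st$n1 + 1 / st$n2) * (st$ss1 + st$ss2) / (st$n1 + st$n2 - 2))
  if (s0 == 0 && any(s == 0)) {
    abort("zero pooled standard error with s0 = 0; supply a positive s0.")
  }
  tibble::tibble(feature_id = rownames(m), d = (st$m1 - st$m2) / (s + s0),
                 numerator = st$m1 - st$m2, s = s)
}

# Tusher-style automatic fudge constant: choose s0 among percentiles of s so
# that the coefficient of variation of the d spread across s-quantile windows
# is minimised.
choose_s0 <- function(r, s) {
  cand <- unique(quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  qs <- quantile(s, seq(0, 1, by = 0.01), names = FALSE)
  bin <- cut(s, breaks = unique(c(-Inf, qs, Inf)))
  cv <- vapply(cand, function(s0) {
    dd <- r / (s + s0)
    v <- tapply(dd, bin, mad)
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Fit the SAM permutation model
#'
#' Computes the observed SAM statistic for every feature and its expected
#' order statistics under group-label permutation, the inputs to delta-based
#' selection with [sam_select()].
#'
#' @inheritParams sam_statistic
#' @param s0 Fudge constant, or `"auto"` (default) for the percentile-search
#'   recipe minimising the coefficient of variation of the `d` spread.
#' @param n_perm Number of permutations; exhaustive enumeration is used when
#'   `choose(n, n1) <= n_perm`.
#' @param seed Integer seed (sampled permutations only).
#' @return A `sam_fit` object.
#' @export
sam_fit <- function(expr, design, s0 = "auto", n_perm = 1000, seed = 1L) {
  m <- expr_matrix(expr)
  d <- check_design(design, colnames(m))
  i1 <- match(d$g1, colnames(m)); i2 <- match(d$g2, colnames(m))
  if (length(i1) < 2 || length(i2) < 2) abort("need >= 2 samples per group.")
  st <- row_group_stats(m, i1, i2)
  s <- sqrt((1 / st$n1 + 1 / st$n2) * (st$ss1 + st$ss2) / (st$n1 + st$n2 - 2))
  r <- st$m1 - st$m2
  if (identical(s0, "auto")) s0 <- choose_s0(r, s)
  dobs <- r / (s + s0)

  n <- ncol(m)
  asg <- make_assignments(n, st$n1, n_perm, seed)
  all_idx <- seq_len(n)
  dstar <- vapply(asg$idx, function(j1) {
    j2 <- setdiff(all_idx, j1)
    stp <- row_group_stats(m, j1, j2)
    sp <- sqrt((1 / stp$n1 + 1 / stp$n2) * (stp$ss1 + stp$ss2) /
                 (stp$n1 + stp$n2 - 2))
    (stp$m1 - stp$m2) / (sp + s0)
  }, numeric(nrow(m)))
  dbar <- rowMeans(apply(dstar, 2, sort))

  lin1 <- unname(rowMeans(2^m[, i1, drop = FALSE]))
  lin2 <- unname(rowMeans(2^m[, i2, drop = FALSE]))
  ratio <- lin1 / lin2
  structure(list(
    stats = tibble::tibble(
      feature_id = rownames(m), d = dobs, s = s, numerator = r,
      signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio)),
    s0 = s0, dbar = dbar, dstar = dstar,
    n_perm = length(asg$idx), exhaustive = asg$exhaustive, seed = seed,
    groups = d$levels), class = "sam_fit")
}

#' Select differentially expressed features by SAM delta thresholding
#'
#' Orders the observed statistics against the permutation-expected order
#' statistics; features beyond the first crossing of the `delta` band are
#' called (up where `d - dbar >= delta`, down where `<= -delta`). The false
#' discovery rate is the median, across permutations, of the number of
#' permuted statistics beyond the cut points, divided by the number of
#' calls (optionally scaled by a pi0 estimate); 0/0 is reported as 0.
#'
#' @param fit A [sam_fit()] object.
#' @param delta Non-negative threshold on `|d - expected d|`.
#' @param pi0_correction Apply the permutation-based estimate of the null
#'   proportion to the FDR (default `FALSE`).
#' @return A `sam_result`: `called` tibble (`feature_id`, `d`, `signed_fc`,
#'   `direction`), `fdr`, `delta`, `cut_up`, `cut_low`, `n_called`.
#' @export
sam_select <- function(fit, delta, pi0_correction = FALSE) {
  stopifnot(inherits(fit, "sam_fit"), delta >= 0)
  ord <- order(fit$stats$d)
  ds <- fit$stats$d[ord]
  diff <- ds - fit$dbar
  up <- which(diff >= delta)
  lo <- which(diff <= -delta)
  cut_up <- if (length(up)) min(ds[up]) else Inf
  cut_low <- if (length(lo)) max(ds[lo]) else -Inf
  called_up <- fit$stats$d >= cut_up
  called_down <- fit$stats$d <= cut_low
  n_called <- sum(called_up | called_down)
  fp <- apply(fit$dstar, 2, function(x) sum(x >= cut_up | x <= cut_low))
  pi0 <- if (pi0_correction) {
    q <- quantile(fit$dstar, c(0.25, 0.75))
    min(1, sum(fit$stats$d > q[1] & fit$stats$d < q[2]) /
          (0.5 * nrow(fit$stats)))
  } else 1
  fdr <- if (n_called == 0) 0 else min(1, pi0 * median(fp) / n_called)
  called <- fit$stats[called_up | called_down,
                      c("feature_id", "d", "signed_fc")]
  called$direction <- ifelse(called$d > 0, "up", "down")
  structure(list(called = called[order(-abs(called$d)), ],
                 fdr = fdr, delta = delta, cut_up = cut_up,
                 cut_low = cut_low, n_called = n_called,
                 s0 = fit$s0, n_perm = fit$n_perm,
                 exhaustive = fit$exhaustive), class = "sam_result")
}

#' Delta table for a SAM fit
#'
#' The classic SAM tuning aid: number of calls and estimated FDR over a
#' grid of delta values (calls never increase with delta).
#'
#' @param fit A [sam_fit()] object.
#' @param deltas Numeric grid of delta values.
#' @inheritParams sam_select
#' @return Tibble with `delta`, `n_called`, `fdr`.
#' @export
sam_delta_table <- function(fit, deltas = seq(0.1, 4, by = 0.1),
                            pi0_correction = FALSE) {
  rows <- lapply(deltas, function(dl) {
    r <- sam_select(fit, dl, pi0_correction = pi0_correction)
    tibble::tibble(delta = dl, n_called = r$n_called, fdr = r$fdr)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM selection: delta =", x$delta, "->", x$n_called,
      "feature(s) called, estimated FDR =", signif(x$fdr, 3), "\n")
  invisible(x)
}

#' @rdname sam_select
#' @param x A `sam_result`.
#' @param ... Unused.
#' @export
tidy.sam_result <- function(x, ...) x$called

#' @rdname sam_select
#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(delta = x$delta, n_called = x$n_called, fdr = x$fdr,
                 s0 = x$s0, n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' Permutation two-sample t-test per feature
#'
#' Computes the pooled-variance t statistic per feature and a permutation
#' p-value from group-label reassignments preserving group sizes. With
#' sampled permutations the add-one estimator
#' `p = (1 + #(|t*| >= |t|)) / (1 + N)` is used; with exhaustive
#' enumeration the exact tail fraction over all labelings (which include
#' the observed one). Features with zero pooled variance are stabilised by
#' adding the 5th percentile of positive pooled variances.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (exhaustive when feasible).
#' @param seed Integer seed.
#' @param alpha Significance threshold on p (default 0.01).
#' @return Tibble with `feature_id`, `t`, `p`, `signed_fc`, `direction`,
#'   `significant`; attributes `n_perm` and `exhaustive`.
#' @export
permuted_ttest <- function(expr, design, n_perm = 1000, seed = 1L,
                           alpha = 0.01) {
  m <- expr_matrix(expr)
  d <- check_design(design, colnames(m))
  i1 <- match(d$g1, colnames(m)); i2 <- match(d$g2, colnames(m))
  if (length(i1) < 2 || length(i2) < 2) abort("need >= 2 samples per group.")
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  se_scale <- 1 / n1 + 1 / n2
  df <- n1 + n2 - 2

  tstat <- function(j1, j2, floor_v) {
    st <- row_group_stats(m, j1, j2)
    vp <- (st$ss1 + st$ss2) / df
    vp <- pmax(vp, floor_v)
    (st$m1 - st$m2) / sqrt(vp * se_scale)
  }
  st0 <- row_group_stats(m, i1, i2)
  vp0 <- (st0$ss1 + st0$ss2) / df
  floor_v <- if (any(vp0 == 0)) {
    pos <- vp0[vp0 > 0]
    if (!length(pos)) abort("all features have zero pooled variance.")
    quantile(pos, 0.05, names = FALSE)
  } else 0
  tobs <- tstat(i1, i2, floor_v)

  asg <- make_assignments(n, n1, n_perm, seed)
  all_idx <- seq_len(n)
  counts <- numeric(nrow(m))
  for (j1 in asg$idx) {
    tp <- tstat(j1, setdiff(all_idx, j1), floor_v)
    counts <- counts + (abs(tp) >= abs(tobs) - 1e-12)
  }
  N <- length(asg$idx)
  p <- if (asg$exhaustive) counts / N else (1 + counts) / (1 + N)

  lin1 <- unname(rowMeans(2^m[, i1, drop = FALSE]))
  lin2 <- unname(rowMeans(2^m[, i2, drop = FALSE]))
  ratio <- lin1 / lin2
  out <- tibble::tibble(
    feature_id = rownames(m), t = tobs, p = p,
    signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio),
    direction = ifelse(st0$m1 - st0$m2 >= 0, "up", "down"),
    significant = p <= alpha)
  attr(out, "n_perm") <- N
  attr(out, "exhaustive") <- asg$exhaustive
  attr(out, "alpha") <- alpha
  out
}

#' Collapse probe-level calls to unique genes
#'
#' Maps significant probes to gene symbols, keeping one record per gene.
#' The per-gene direction is that of the most significant probe (smallest
#' p, ties broken by |statistic|); genes whose probes disagree in direction
#' are flagged `ambiguous`. Probes absent from the map are dropped with a
#' warning.
#'
#' @param records Probe-level tibble with `feature_id`, `direction` and a
#'   `p` (or `d`/`t` statistic) column, e.g. from [permuted_ttest()].
#' @param gene_map Tibble with `probe_id` and `gene`.
#' @return Gene-level tibble: `gene`, `n_probes`, `n_up`, `n_down`,
#'   `direction`, `ambiguous`, `top_probe` plus the top probe's statistics.
#' @export
collapse_probes_to_genes <- function(records, gene_map) {
  stopifnot(all(c("probe_id", "gene") %in% names(gene_map)))
  unmapped <- setdiff(records$feature_id, gene_map$probe_id)
  if (length(unmapped)) {
    warn(paste0("dropping ", length(unmapped), " probe(s) without a gene mapping: ",
                paste(head(unmapped, 5), collapse = ", ")))
  }
  stat_col <- intersect(c("t", "d"), names(records))[1]
  x <- dplyr::inner_join(records, gene_map,
                         by = c(feature_id = "probe_id"))
  if (!"p" %in% names(x)) x$p <- NA_real_
  if (is.na(stat_col)) { stat_col <- ".stat"; x$.stat <- 0 }
  x |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data[[stat_col]])),
                   .by_group = TRUE) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      direction = dplyr::first(.data$direction),
      ambiguous = n_up > 0 & n_down > 0,
      top_probe = dplyr::first(.data$feature_id),
      top_p = dplyr::first(.data$p),
      signed_fc = if ("signed_fc" %in% names(x))
        dplyr::first(.data$signed_fc) else NA_real_,
      .groups = "drop")
}
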