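#' Filter probes by qPCR detection
#'
#' A probe is excluded when, within EACH group separately, the fraction of
#' samples with CT above the detection limit (or missing/`Undetermined`)
#' exceeds `max_undetected_fraction`. Endogenous control probes are exempt
#' from exclusion but are flagged when they would fail the same rule.
#'
#' @param ct Wide CT tibble (`probe_id` first, then one column per sample);
#'   `NA` marks undetermined wells.
#' @param design Tibble with `sample_id` and `group`.
#' @param detection_limit CT detection limit in cycles; values strictly above
#'   it count as undetected.
#' @param max_undetected_fraction Exclusion threshold on the undetected
#'   fraction, applied strictly (`> 0.60` by default) within each group.
#' @param controls Character vector of control probe ids.
#' @return A list: `retained` (CT tibble), `excluded` (tibble of excluded
#'   probes with per-group undetected fractions), `flagged_controls`
#'   (controls failing the rule), and `stats` (per-probe detection tibble).
#' @export
filter_detected <- function(ct, design, detection_limit = 38,
                            max_undetected_fraction = 0.60,
                            controls = character()) {
  m <- expr_matrix(ct)
  d <- check_design(design, colnames(m))
  if (length(controls)) {
    missing_ctrl <- setdiff(controls, rownames(m))
    if (length(missing_ctrl)) {
      abort(paste0("control probe(s) absent from the CT matrix: ",
                   paste(missing_ctrl, collapse = ", ")))
    }
  }
  undet <- function(cols) {
    rowMeans(is.na(m[, cols, drop = FALSE]) | m[, cols, drop = FALSE] > detection_limit)
  }
  stats <- tibble::tibble(
    probe_id = rownames(m),
    frac_undetected_g1 = undet(d$g1),
    frac_undetected_g2 = undet(d$g2),
    is_control = rownames(m) %in% controls
  )
  fails <- stats$frac_undetected_g1 > max_undetected_fraction &
    stats$frac_undetected_g2 > max_undetected_fraction
  excluded <- stats$probe_id[fails & !stats$is_control]
  flagged <- stats$probe_id[fails & stats$is_control]
  list(
    retained = ct[!ct[[1]] %in% excluded, , drop = FALSE],
    excluded = stats[stats$probe_id %in% excluded, ],
    flagged_controls = flagged,
    stats = stats
  )
}

#' Delta-CT normalisation against an endogenous control
#'
#' Per sample `s` and probe `p`, `dCT = CT(p, s) - CT(control, s)`. Lower
#' dCT means higher abundance; `2^-dCT` (see [rel_expr()]) is linear-scale
#' relative expression. Missing CT propagates to missing dCT.
#'
#' @param ct Wide CT tibble.
#' @param control Endogenous control probe id (default `"RNU48"`).
#' @return A wide dCT tibble with the control row removed.
#' @export
delta_ct <- function(ct, control = "RNU48") {
  m <- expr_matrix(ct)
  if (!control %in% rownames(m)) {
    abort(paste0("endogenous control '", control, "' not found in the CT matrix."))
  }
  ctrl <- m[control, ]
  if (anyNA(ctrl)) {
    bad <- colnames(m)[is.na(ctrl)]
    abort(paste0("control '", control, "' is undetermined in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  dct <- sweep(m[setdiff(rownames(m), control), , drop = FALSE], 2, ctrl, "-")
  as_expr_tbl(dct, "probe_id")
}

#' Linear-scale relative expression from delta-CT
#'
#' Elementwise `2^-dCT`; one PCR cycle corresponds to a factor of two.
#'
#' @param dct Wide dCT tibble.
#' @return A wide tibble of `2^-dCT` values.
#' @export
rel_expr <- function(dct) {
  out <- dct
  out[-1] <- lapply(out[-1], function(x) 2^(-x))
  out
}

#' Between-sample normalisation of an expression table
#'
#' `"quantile"` forces every sample onto the same value distribution
#' (via limma), `"median"` shifts each sample so per-sample medians are
#' equal (appropriate on a log scale), `"none"` is the identity.
#'
#' @param expr Wide expression tibble (any scale; quantile/median act on the
#'   values as given).
#' @param method One of `"quantile"`, `"median"`, `"none"`.
#' @return A wide tibble with the same shape.
#' @export
normalize_between_samples <- function(expr, method = c("quantile", "median", "none")) {
  method <- match.arg(method)
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("between-sample normalisation needs at least 2 samples.")
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na) && method != "none") {
    abort(paste0("sample(s) with no observed values: ",
                 paste(colnames(m)[all_na], collapse = ", ")))
  }
  out <- switch(method,
    none = m,
    quantile = {
      q <- limma::normalizeQuantiles(m)
      dimnames(q) <- dimnames(m)
      q
    },
    median = {
      med <- apply(m, 2, median, na.rm = TRUE)
      sweep(m, 2, med - mean(med), "-")
    })
  tbl <- as_expr_tbl(out, names(expr)[1])
  tbl
}

#' Signed fold change between two groups
#'
#' The ratio of group means on the linear scale, reported with the symmetric
#' signed convention: `ratio` when `ratio >= 1`, `-1/ratio` otherwise, so
#' magnitudes are comparable across directions and no value falls strictly
#' inside (-1, 1). Ties (`ratio == 1`) are reported as `+1`.
#'
#' @param expr Wide LINEAR-scale expression tibble (e.g. `2^-dCT`).
#' @param design Tibble with `sample_id` and `group`; the first group level
#'   is the numerator.
#' @param features Optional feature ids to restrict to.
#' @return Tibble with `feature_id`, `group_mean_1`, `group_mean_2`,
#'   `ratio`, `signed_fc`.
#' @export
signed_fold_change <- function(expr, design, features = NULL) {
  m <- expr_matrix(expr)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing)) abort(paste0("unknown feature(s): ",
                                      paste(missing, collapse = ", ")))
    m <- m[features, , drop = FALSE]
  }
  d <- check_design(design, colnames(m))
  m1 <- unname(rowMeans(m[, d$g1, drop = FALSE], na.rm = TRUE))
  m2 <- unname(rowMeans(m[, d$g2, drop = FALSE], na.rm = TRUE))
  if (any(!is.finite(m1) | !is.finite(m2) | m1 <= 0 | m2 <= 0)) {
    abort("group means must be positive and finite on the linear scale.")
  }
  ratio <- m1 / m2
  tibble::tibble(
    feature_id = rownames(m),
    group_mean_1 = m1, group_mean_2 = m2, ratio = ratio,
    signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio)
  )
}

#' Relative quantification by the delta-delta-CT method
#'
#' `ddCT = dCT(sample) - dCT(reference sample)`; the returned quantity is
#' `2^-ddCT`, the fold expression of the probe in `sample` relative to the
#' reference sample. The reference sample maps to 1 by construction.
#'
#' @param ct Wide CT tibble.
#' @param probe Probe id to quantify.
#' @param sample Sample id(s) to quantify (vectorised).
#' @param reference_sample Reference (calibrator) sample id.
#' @param control Endogenous control probe id.
#' @return Numeric vector of `2^-ddCT` ratios, named by sample.
#' @export
ddct_ratio <- function(ct, probe, sample, reference_sample, control = "RNU48") {
  m <- expr_matrix(ct)
  for (p in c(probe, control)) {
    if (!p %in% rownames(m)) abort(paste0("probe '", p, "' not in CT matrix."))
  }
  for (s in c(sample, reference_sample)) {
    if (!s %in% colnames(m)) abort(paste0("sample '", s, "' not in CT matrix."))
  }
  dct <- m[probe, ] - m[control, ]
  need <- c(sample, reference_sample)
  if (anyNA(dct[need])) {
    abort(paste0("missing CT for probe '", probe, "' or control '", control,
                 "' in: ", paste(need[is.na(dct[need])], collapse = ", ")))
  }
  ddct <- dct[sample] - dct[reference_sample]
  setNames(2^(-ddct), sample)
}

#' Efficiency-corrected relative quantification (Pfaffl)
#'
#' `ratio = E_target^(CP_target_ref - CP_target_sample) /
#'          E_ref^(CP_refgene_ref - CP_refgene_sample)`,
#' where `E` is the amplification efficiency per cycle (2 = perfect
#' doubling). With both efficiencies equal to 2 this reduces exactly to
#' `2^-ddCT`.
#'
#' @param cp_target_sample,cp_target_ref Crossing points of the target gene
#'   in the sample of interest and the reference sample.
#' @param cp_refgene_sample,cp_refgene_ref Crossing points of the reference
#'   gene (e.g. ACTB) in the same two samples.
#' @param e_target,e_ref Amplification efficiencies, each in (1, 2].
#' @return The dimensionless expression ratio (vectorised).
#' @export
pfaffl_ratio <- function(cp_target_sample, cp_target_ref,
                         cp_refgene_sample, cp_refgene_ref,
                         e_target = 2, e_ref = 2) {
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    abort("amplification efficiencies must lie in (1, 2].")
  }
  e_target^(cp_target_ref - cp_target_sample) /
    e_ref^(cp_refgene_ref - cp_refgene_sample)
}
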