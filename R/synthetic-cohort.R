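#' Configure a synthetic two-group miRNA/mRNA cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' emulate a TaqMan low-density miRNA array study of early-onset breast
#' tumours: 377 miRNA probes plus 7 endogenous control assays profiled over
#' two unbalanced groups (familial, `F-BC`, and sporadic, `NF-BC`), with a
#' matching microarray-style mRNA table, miRNA target-prediction lists and a
#' clinical table.
#'
#' CT values are simulated on the cycle scale as
#' `CT = baseline - log2(fold) + noise`, so a planted fold change of `m`
#' shifts the affected group by `log2(m)` cycles and the ratio of group means
#' of `2^-dCT` recovers `m` in expectation. Differential co-expression is
#' planted per (miRNA, gene) pair through a latent factor shared with the
#' miRNA's realised log2 expression, giving each group its own target
#' Pearson correlation.
#'
#' @param n_probes_mir Number of miRNA probes on the panel.
#' @param n_controls Number of endogenous control probes (RNU48 first).
#' @param n_genes Number of genes on the mRNA array.
#' @param n_samples_per_group Integer pair: samples in `F-BC` and `NF-BC`.
#' @param n_below_detection Number of miRNA probes planted as always below
#'   the detection limit (CT > 38) in every sample.
#' @param de_mir Optional tibble `probe`, `magnitude` (linear fold, >= 1) and
#'   `direction` (`"up"` = higher in `F-BC`).
#' @param de_gene Optional tibble `gene`, `lfc` (log2 fold, `F-BC` minus
#'   `NF-BC`).
#' @param dcx_pairs Optional tibble `mir`, `gene`, `r_group1`, `r_group2` and
#'   optionally `predicted` (logical, default `TRUE`): pairs planted with a
#'   group-specific Pearson correlation.
#' @param n_multiprobe_genes Genes given a second, independent array probe
#'   (exercises probe-to-gene collapsing downstream).
#' @param n_predictions_per_mir Rows per miRNA in the emitted
#'   target-prediction table.
#' @param pred_overlap Fraction of each miRNA's prediction list drawn from
#'   the planted differentially expressed genes.
#' @param ct_noise_sd Gaussian noise on CT, in cycles.
#' @param control_ct_sd Noise on control-probe CT, in cycles (controls are
#'   deliberately low-variance).
#' @param baseline_ct_range Range of per-probe baseline CT, in cycles.
#' @param undetermined_fraction Fraction of below-detection cells emitted as
#'   the literal instrument token `"Undetermined"` (held as `NA` in memory).
#' @param gene_noise_sd Gaussian noise of gene log2 intensities.
#' @param gene_mean_range Range of gene mean log2 intensities.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_probes_mir = 377, n_controls = 7, n_genes = 500,
                          n_samples_per_group = c(9, 26),
                          n_below_detection = 0,
                          de_mir = NULL, de_gene = NULL, dcx_pairs = NULL,
                          n_multiprobe_genes = 0,
                          n_predictions_per_mir = 30, pred_overlap = 0.3,
                          ct_noise_sd = 0.5, control_ct_sd = ct_noise_sd / 4,
                          baseline_ct_range = c(22, 32),
                          undetermined_fraction = 0.3,
                          gene_noise_sd = 0.5, gene_mean_range = c(6, 12),
                          seed = 1L) {
  cfg <- list(
    n_probes_mir = as.integer(n_probes_mir),
    n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_below_detection = as.integer(n_below_detection),
    de_mir = de_mir, de_gene = de_gene, dcx_pairs = dcx_pairs,
    n_multiprobe_genes = as.integer(n_multiprobe_genes),
    n_predictions_per_mir = as.integer(n_predictions_per_mir),
    pred_overlap = pred_overlap,
    ct_noise_sd = ct_noise_sd, control_ct_sd = control_ct_sd,
    baseline_ct_range = baseline_ct_range,
    undetermined_fraction = undetermined_fraction,
    gene_noise_sd = gene_noise_sd, gene_mean_range = gene_mean_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$n_samples_per_group) != 2L || any(cfg$n_samples_per_group < 3L)) {
    abort("each group needs at least 3 samples.")
  }
  if (cfg$n_below_detection > cfg$n_probes_mir) {
    abort("`n_below_detection` cannot exceed `n_probes_mir`.")
  }
  if (cfg$n_below_detection < 0 || cfg$n_controls < 1 || cfg$n_genes < 1) {
    abort("counts must be non-negative (and at least one control probe).")
  }
  if (!is.null(cfg$de_mir)) {
    stopifnot(all(c("probe", "magnitude", "direction") %in% names(cfg$de_mir)))
    if (any(cfg$de_mir$magnitude < 1)) {
      abort("`de_mir$magnitude` is a linear fold magnitude and must be >= 1.")
    }
    if (!all(cfg$de_mir$direction %in% c("up", "down"))) {
      abort("`de_mir$direction` must be 'up' or 'down'.")
    }
  }
  if (!is.null(cfg$dcx_pairs)) {
    stopifnot(all(c("mir", "gene", "r_group1", "r_group2") %in% names(cfg$dcx_pairs)))
    r <- c(cfg$dcx_pairs$r_group1, cfg$dcx_pairs$r_group2)
    if (any(abs(r) > 1)) abort("planted correlations must satisfy |r| <= 1.")
    if (any(abs(r) == 1) && cfg$ct_noise_sd > 0) {
      abort("|r| = 1 is infeasible with non-zero CT noise.")
    }
    if (anyDuplicated(cfg$dcx_pairs$gene)) {
      abort("each gene may carry at most one planted co-expression pair.")
    }
  }
  if (cfg$undetermined_fraction < 0 || cfg$undetermined_fraction > 1) {
    abort("`undetermined_fraction` must be in [0, 1].")
  }
  cfg
}

control_probe_names <- function(n) {
  base <- c("RNU48", "RNU44", "RNU6B", "RNU24", "RNU43", "RNU58A", "RNU38B")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("CTRL-%02d", seq_len(n - length(base))))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Simulates the full input set of a two-group miRNA/mRNA integration study:
#' a raw CT matrix (with below-detection probes and `Undetermined` cells held
#' as `NA`), an mRNA log2-intensity table with a probe-to-gene map, the group
#' design, a target-prediction table, a clinical table, and the planted truth
#' needed for recovery tests.
#'
#' @param config A [cohort_config()] object.
#' @return A `mir_cohort` list with elements `ct`, `mrna`, `gene_map`,
#'   `design`, `predictions`, `clinical`, `truth` and `config`. All tabular
#'   elements are tibbles; `ct` and `mrna` are wide (feature column first).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)

  n1 <- cfg$n_samples_per_group[1]
  n2 <- cfg$n_samples_per_group[2]
  samples <- c(sprintf("F-BC-%02d", seq_len(n1)), sprintf("NF-BC-%02d", seq_len(n2)))
  groups <- rep(c("F-BC", "NF-BC"), c(n1, n2))
  design <- tibble::tibble(sample_id = samples, group = groups)
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)

  ## ---- miRNA probe panel ----------------------------------------------
  de_probes <- if (is.null(cfg$de_mir)) character() else cfg$de_mir$probe
  dcx_mirs <- if (is.null(cfg$dcx_pairs)) character() else unique(cfg$dcx_pairs$mir)
  n_named <- length(de_probes)
  n_filler <- cfg$n_probes_mir - n_named
  if (n_filler < 0) abort("more DE miRNA probes than `n_probes_mir`.")
  fillers <- sprintf("miR-sim-%03d", seq_len(n_filler))
  mir_probes <- c(de_probes, fillers)
  if (!all(dcx_mirs %in% mir_probes)) {
    abort("every `dcx_pairs$mir` must name a probe on the panel.")
  }
  # below-detection probes drawn from plain filler probes (never DE/dcx)
  bd_candidates <- setdiff(fillers, dcx_mirs)
  if (cfg$n_below_detection > length(bd_candidates)) {
    abort("not enough plain probes to plant the below-detection set.")
  }
  bd_probes <- utils::tail(bd_candidates, cfg$n_below_detection)

  n <- n1 + n2
  baseline <- runif(cfg$n_probes_mir, cfg$baseline_ct_range[1], cfg$baseline_ct_range[2])
  ct <- matrix(baseline, nrow = cfg$n_probes_mir, ncol = n)
  dimnames(ct) <- list(mir_probes, samples)
  if (n_named > 0) {
    shift <- log2(cfg$de_mir$magnitude) * ifelse(cfg$de_mir$direction == "up", 1, -1)
    # higher expression in F-BC means lower CT there
    ct[cfg$de_mir$probe, idx1] <- ct[cfg$de_mir$probe, idx1] - shift
  }
  ct <- ct + matrix(rnorm(length(ct), 0, cfg$ct_noise_sd), nrow = nrow(ct))
  if (length(bd_probes)) {
    ct[bd_probes, ] <- matrix(runif(length(bd_probes) * n, 38.5, 40),
                              nrow = length(bd_probes))
  }

  controls <- control_probe_names(cfg$n_controls)
  ctrl_baseline <- runif(cfg$n_controls, 20, 26)
  ctrl_ct <- matrix(ctrl_baseline, nrow = cfg$n_controls, ncol = n) +
    matrix(rnorm(cfg$n_controls * n, 0, cfg$control_ct_sd), nrow = cfg$n_controls)
  dimnames(ctrl_ct) <- list(controls, samples)
  ct <- rbind(ct, ctrl_ct)

  # instrument 'Undetermined' tokens: a random subset of below-detection cells
  if (length(bd_probes) && cfg$undetermined_fraction > 0) {
    mask <- matrix(rbinom(length(bd_probes) * n, 1, cfg$undetermined_fraction) == 1,
                   nrow = length(bd_probes))
    ct[bd_probes, ][mask] <- NA_real_
  }

  ## ---- mRNA table -------------------------------------------------------
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  de_gene <- cfg$de_gene
  if (!is.null(de_gene) && !all(de_gene$gene %in% genes)) {
    abort("every `de_gene$gene` must be one of the generated gene ids.")
  }
  if (!is.null(cfg$dcx_pairs) && !all(cfg$dcx_pairs$gene %in% genes)) {
    abort("every `dcx_pairs$gene` must be one of the generated gene ids.")
  }
  gmean <- runif(cfg$n_genes, cfg$gene_mean_range[1], cfg$gene_mean_range[2])
  gshift <- setNames(numeric(cfg$n_genes), genes)
  if (!is.null(de_gene)) gshift[de_gene$gene] <- de_gene$lfc
  expr <- matrix(gmean, nrow = cfg$n_genes, ncol = n)
  dimnames(expr) <- list(genes, samples)
  expr[, idx1] <- expr[, idx1] + gshift
  expr <- expr + matrix(rnorm(length(expr), 0, cfg$gene_noise_sd), nrow = nrow(expr))

  # planted differential co-expression: regenerate each dcx gene from the
  # miRNA's standardised log2 expression within each group
  if (!is.null(cfg$dcx_pairs)) {
    log2_mir <- -ct[seq_len(cfg$n_probes_mir), , drop = FALSE]
    for (k in seq_len(nrow(cfg$dcx_pairs))) {
      p <- cfg$dcx_pairs[k, ]
      for (g in 1:2) {
        idx <- if (g == 1) idx1 else idx2
        r <- if (g == 1) p$r_group1 else p$r_group2
        z <- as.numeric(scale(log2_mir[p$mir, idx]))
        eps <- rnorm(length(idx))
        expr[p$gene, idx] <- gmean[match(p$gene, genes)] +
          (if (g == 1) gshift[p$gene] else 0) +
          cfg$gene_noise_sd * (r * z + sqrt(1 - r^2) * eps)
      }
    }
  }

  # probe layer: one probe per gene, plus a second probe for a few genes
  dcx_genes <- if (is.null(cfg$dcx_pairs)) character() else cfg$dcx_pairs$gene
  multi <- head(setdiff(genes, dcx_genes), cfg$n_multiprobe_genes)
  probe_ids <- paste0("P_", genes)
  mrna <- expr
  rownames(mrna) <- probe_ids
  gene_map <- tibble::tibble(probe_id = probe_ids, gene = genes)
  if (length(multi)) {
    extra <- matrix(gmean[match(multi, genes)], nrow = length(multi), ncol = n)
    extra[, idx1] <- extra[, idx1] + gshift[multi]
    extra <- extra + matrix(rnorm(length(extra), 0, cfg$gene_noise_sd),
                            nrow = nrow(extra))
    rownames(extra) <- paste0("P2_", multi)
    colnames(extra) <- samples
    mrna <- rbind(mrna, extra)
    gene_map <- dplyr::bind_rows(
      gene_map, tibble::tibble(probe_id = paste0("P2_", multi), gene = multi))
  }

  ## ---- target predictions ----------------------------------------------
  pred_mirs <- unique(c(de_probes, dcx_mirs))
  predictions <- make_predictions(cfg, pred_mirs, genes, dcx_genes)

  ## ---- clinical table ---------------------------------------------------
  clinical <- simulate_clinical(design)

  truth <- list(
    de_mirs = cfg$de_mir,
    de_genes = cfg$de_gene,
    dcx_pairs = cfg$dcx_pairs,
    predicted_pairs = predictions[, c("mir", "gene")],
    below_detection = bd_probes,
    controls = controls
  )

  structure(list(
    ct = as_expr_tbl(ct, "probe_id"),
    mrna = as_expr_tbl(mrna, "probe_id"),
    gene_map = gene_map,
    design = design,
    predictions = predictions,
    clinical = clinical,
    truth = truth,
    config = cfg
  ), class = "mir_cohort")
}

make_predictions <- function(cfg, pred_mirs, genes, dcx_genes) {
  empty <- tibble::tibble(
    mir = character(), gene = character(), db_count = integer(),
    flag_a = logical(), flag_b = logical(), flag_c = logical(),
    flag_d = logical(), flag_e = logical())
  if (!length(pred_mirs)) return(empty)
  de_genes <- if (is.null(cfg$de_gene)) character() else cfg$de_gene$gene
  rows <- lapply(pred_mirs, function(m) {
    planted <- if (!is.null(cfg$dcx_pairs)) {
      dp <- cfg$dcx_pairs[cfg$dcx_pairs$mir == m, ]
      if ("predicted" %in% names(dp)) dp$gene[dp$predicted] else dp$gene
    } else character()
    n_extra <- max(cfg$n_predictions_per_mir - length(planted), 0L)
    n_de <- min(round(cfg$pred_overlap * n_extra), length(setdiff(de_genes, planted)))
    pick_de <- sample(setdiff(de_genes, planted), n_de)
    pool <- setdiff(genes, c(planted, pick_de, de_genes))
    pick_bg <- sample(pool, min(n_extra - n_de, length(pool)))
    g <- c(planted, pick_de, pick_bg)
    tibble::tibble(
      mir = m, gene = g,
      db_count = c(sample(3:5, length(planted), replace = TRUE),
                   sample(1:5, length(g) - length(planted), replace = TRUE)))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty)
  flags <- matrix(rbinom(5 * nrow(out), 1, 0.5) == 1, ncol = 5)
  out$flag_a <- flags[, 1]; out$flag_b <- flags[, 2]; out$flag_c <- flags[, 3]
  out$flag_d <- flags[, 4]; out$flag_e <- flags[, 5]
  out
}

# Clinical rows drawn from the frequency profile of the study cohort:
# early-onset tumours, mostly luminal, stage I-II dominant, familial status
# given by the design. Subtype is derived from the drawn receptor calls so
# the records are internally consistent.
simulate_clinical <- function(design) {
  freq <- list(
    "F-BC" = list(stage12 = 0.8, er = 0.8, pr = 0.7, her2 = 0.1,
                  gh12 = 0.5, gn2 = 0.05),
    "NF-BC" = list(stage12 = 19 / 26, er = 21 / 26, pr = 15 / 26, her2 = 8 / 26,
                   gh12 = 0.75, gn2 = 1 / 3)
  )
  n <- nrow(design)
  rows <- lapply(seq_len(n), function(i) {
    f <- freq[[design$group[i]]]
    stage <- if (runif(1) < f$stage12) {
      sample(c("I", "IIA", "IIB"), 1, prob = c(0.15, 0.5, 0.35))
    } else {
      sample(c("IIIA", "IIIB", "IV"), 1, prob = c(0.5, 0.35, 0.15))
    }
    er <- if (runif(1) < f$er) "POS" else "NEG"
    pr <- if (runif(1) < f$pr) "POS" else "NEG"
    her2 <- if (runif(1) < f$her2) "POS" else "NEG"
    gh <- if (runif(1) < f$gh12) sample(1:2, 1) else 3L
    gn <- if (runif(1) < f$gn2) 2L else 3L
    grade <- if (runif(1) < 0.08) "NA" else sprintf("GN%d/GH%d", gn, gh)
    tibble::tibble(
      ID = design$sample_id[i],
      Age = sample(22:35, 1),
      Grade = grade,
      TNM = stage,
      Subtype = subtype_from_receptors(er, pr, her2),
      Familial = if (design$group[i] == "F-BC") "(+)" else "(-)",
      ER = er, PR = pr, `Her-2` = her2)
  })
  dplyr::bind_rows(rows)
}

#' Study-scale cohort preset
#'
#' Returns a [cohort_config()] reproducing the dimensions of the motivating
#' study: a 377-miRNA + 7-control panel over 35 tumours (9 familial, 26
#' sporadic), 121 probes planted below the CT detection limit (leaving 256
#' detectable), nine strongly differentially expressed miRNAs (six up, three
#' down in the familial group, with the published fold magnitudes), 91
#' differentially expressed genes (57 up, 34 down) and 20 planted
#' differentially co-expressed miRNA-gene pairs.
#'
#' @param seed Integer seed forwarded to the config.
#' @return A `cohort_config`.
#' @export
paper_scale_preset <- function(seed = 101L) {
  de_mir <- tibble::tibble(
    probe = c("hsa-miR-124", "hsa-miR-210", "hsa-miR-455-3p", "hsa-miR-660",
              "hsa-miR-381", "hsa-miR-501-5p", "hsa-miR-98",
              "hsa-miR-486-3p", "hsa-miR-874"),
    magnitude = c(10.08, 7.32, 4.28, 2.65, 2.47, 2.15, 2.29, 4.53, 4.70),
    direction = c(rep("up", 6), rep("down", 3)))
  up_genes <- sprintf("GENE%04d", 1:57)
  down_genes <- sprintf("GENE%04d", 58:91)
  de_gene <- tibble::tibble(
    gene = c(up_genes, down_genes),
    lfc = c(rep(c(1, 1.5, 2), length.out = 57),
            -rep(c(1, 1.5, 2), length.out = 34)))
  dcx_genes <- sprintf("GENE%04d", round(seq(1, 91, length.out = 20)))
  dcx_pairs <- tibble::tibble(
    mir = rep(de_mir$probe, length.out = 20),
    gene = dcx_genes,
    r_group1 = rep(c(0.8, -0.7, 0.6, -0.8), length.out = 20),
    r_group2 = rep(c(-0.6, 0.5, -0.7, 0.2), length.out = 20),
    predicted = rep(c(TRUE, TRUE, TRUE, FALSE), length.out = 20))
  cohort_config(
    n_probes_mir = 377, n_controls = 7, n_genes = 1200,
    n_samples_per_group = c(9, 26), n_below_detection = 121,
    de_mir = de_mir, de_gene = de_gene, dcx_pairs = dcx_pairs,
    n_multiprobe_genes = 25, n_predictions_per_mir = 40, pred_overlap = 0.35,
    seed = seed)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the instrument-style file dialects consumed by the reading helpers:
#' a CT matrix TSV in which missing CT cells carry the literal token
#' `Undetermined`, an mRNA expression TSV, a probe-to-gene map TSV, a group
#' CSV, a predictions TSV, a clinical CSV and a truth JSON.
#'
#' @param cohort A `mir_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mir_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ct = file.path(dir, "ct_matrix.tsv"),
    mrna = file.path(dir, "mrna_expression.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    design = file.path(dir, "design.csv"),
    predictions = file.path(dir, "predictions.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.json"))
  ct_out <- cohort$ct
  ct_out[-1] <- lapply(ct_out[-1], function(x) {
    ifelse(is.na(x), "Undetermined", format(x, digits = 10, trim = TRUE))
  })
  readr::write_tsv(ct_out, paths["ct"])
  readr::write_tsv(cohort$mrna, paths["mrna"])
  readr::write_tsv(cohort$gene_map, paths["gene_map"])
  readr::write_csv(cohort$design, paths["design"])
  readr::write_tsv(cohort$predictions, paths["predictions"])
  readr::write_csv(cohort$clinical, paths["clinical"])
  truth <- cohort$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a CT matrix TSV
#'
#' Accepts the TaqMan-export-style dialect written by [write_cohort()]:
#' rows are probes, columns samples, and cells either a CT value or the
#' token `Undetermined` (read as `NA`).
#'
#' @param path Path to the TSV.
#' @return A wide CT tibble (`probe_id` first).
#' @export
read_ct_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  names(x)[1] <- "probe_id"
  x[-1] <- lapply(x[-1], function(v) {
    v[v %in% c("Undetermined", "undetermined", "NA", "")] <- NA
    as.numeric(v)
  })
  x
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat("<mir_cohort>\n")
  cat("  CT matrix:  ", nrow(x$ct), "probes x", ncol(x$ct) - 1, "samples\n")
  cat("  mRNA table: ", nrow(x$mrna), "probes /", length(unique(x$gene_map$gene)),
      "genes\n")
  cat("  groups:     ", paste(sprintf("%s (n=%d)", names(table(x$design$group)),
                                      table(x$design$group)), collapse = ", "), "\n")
  cat("  planted:    ",
      if (is.null(x$truth$de_mirs)) 0 else nrow(x$truth$de_mirs), "DE miRNAs,",
      if (is.null(x$truth$de_genes)) 0 else nrow(x$truth$de_genes), "DE genes,",
      if (is.null(x$truth$dcx_pairs)) 0 else nrow(x$truth$dcx_pairs),
      "co-expression pairs,", length(x$truth$below_detection),
      "below-detection probes\n")
  invisible(x)
}
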