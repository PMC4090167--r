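#' Assemble a pipeline configuration
#'
#' Collects every threshold of the integrated analysis in one validated
#' list. Exactly one of `simulate` (a [cohort_config()], in which case the
#' cohort is generated in-run) or `inputs` (named paths `ct`, `mrna`,
#' `gene_map`, `design`, `predictions`, `clinical`) must be supplied.
#'
#' @param out_dir Output directory for all stage artefacts.
#' @param seed Master seed; per-stage child seeds are derived
#'   deterministically (see [run_pipeline()]).
#' @param simulate Optional [cohort_config()].
#' @param inputs Optional named list of input paths.
#' @param detection_limit CT detection limit (cycles).
#' @param max_undetected_fraction Detection-filter threshold.
#' @param endogenous_control Control probe id for delta-CT.
#' @param between_sample_method `"median"` (default), `"quantile"` or
#'   `"none"`. Median shifting is the pipeline default: full quantile
#'   normalisation maps a probe occupying the same within-group rank in
#'   every sample to identical values, leaving its Pearson correlations
#'   undefined downstream.
#' @param sam_delta SAM delta threshold (study value 0.77).
#' @param sam_n_perm SAM permutation count.
#' @param mrna_alpha mRNA permutation t-test threshold (study value 0.01).
#' @param mrna_n_perm mRNA permutation count.
#' @param min_algorithms Target-prediction stringency (supporting
#'   algorithms).
#' @param coexpr_alpha Differential co-expression threshold (study value
#'   0.05).
#' @param coexpr_n_perm Co-expression permutation count (study value
#'   100,000).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL, inputs = NULL,
                            detection_limit = 38,
                            max_undetected_fraction = 0.60,
                            endogenous_control = "RNU48",
                            between_sample_method = "median",
                            sam_delta = 0.77, sam_n_perm = 1000,
                            mrna_alpha = 0.01, mrna_n_perm = 1000,
                            min_algorithms = 3,
                            coexpr_alpha = 0.05, coexpr_n_perm = 100000) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              inputs = inputs, detection_limit = detection_limit,
              max_undetected_fraction = max_undetected_fraction,
              endogenous_control = endogenous_control,
              between_sample_method = between_sample_method,
              sam_delta = sam_delta, sam_n_perm = as.integer(sam_n_perm),
              mrna_alpha = mrna_alpha, mrna_n_perm = as.integer(mrna_n_perm),
              min_algorithms = min_algorithms,
              coexpr_alpha = coexpr_alpha,
              coexpr_n_perm = as.integer(coexpr_n_perm))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (a `simulate` mapping is forwarded to
#'   [cohort_config()]).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(cohort_config, y$simulate)
  do.call(pipeline_config, y)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate) == is.null(cfg$inputs)) {
    abort("supply exactly one of `simulate` or `inputs`.")
  }
  if (cfg$detection_limit <= 0 || cfg$detection_limit > 45) {
    abort("`detection_limit` must lie in (0, 45].")
  }
  for (p in c("max_undetected_fraction", "mrna_alpha", "coexpr_alpha")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      abort(paste0("`", p, "` must lie in (0, 1)."))
    }
  }
  if (cfg$sam_delta < 0) abort("`sam_delta` must be non-negative.")
  if (any(c(cfg$sam_n_perm, cfg$mrna_n_perm, cfg$coexpr_n_perm) < 1)) {
    abort("permutation counts must be at least 1.")
  }
  if (!is.null(cfg$inputs)) {
    need <- c("ct", "mrna", "gene_map", "design", "predictions", "clinical")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) abort(paste0("`inputs` lacks: ", paste(miss, collapse = ", ")))
    for (nm in need) {
      if (!file.exists(cfg$inputs[[nm]])) {
        abort(paste0("input file not found: ", cfg$inputs[[nm]], " (", nm, ")"))
      }
    }
  }
  cfg
}

pipeline_stages <- c("simulate", "quantify", "de_mir", "de_mrna",
                     "discriminant", "integrate", "diffcoexpr", "clinical")

#' Run the integrated miRNA/mRNA pipeline end to end
#'
#' Executes, in order: cohort simulation (or input loading), CT detection
#' filtering and delta-CT quantification with between-sample
#' normalisation, SAM differential expression of miRNAs, permutation
#' t-test differential expression of mRNA probes with gene collapsing,
#' linear discriminant classification with leave-one-out cross-validation,
#' target-list integration, the differential co-expression permutation
#' test with interaction classification and network export, and the
#' clinical frequency table. Stage `k` runs under the child seed
#' `(seed + 7919 k) mod (2^31 - 1)` so any stage can be reproduced in
#' isolation.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return The run manifest (also written to `out_dir/manifest.json`):
#'   package version, seeds, input digests, and every stage's output
#'   paths. On stage failure the error names the stage and a partial
#'   manifest is written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- setNames(
    vapply(seq_along(pipeline_stages), function(i) stage_seed(cfg$seed, i),
           integer(1)), pipeline_stages)
  manifest <- list(
    package = "mirdcx",
    version = as.character(utils::packageVersion("mirdcx")),
    generated_at = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed, stage_seeds = as.list(seeds),
    stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest(manifest, cfg$out_dir)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(res)))
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
  }

  run_stage("simulate", function() {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      sim$seed <- seeds[["simulate"]]
      state$cohort <- generate_cohort(sim)
      paths <- write_cohort(state$cohort, file.path(cfg$out_dir, "cohort"))
      state$controls <- state$cohort$truth$controls
      list(outputs = as.list(paths), input_digests = NULL)
    } else {
      state$cohort <- list(
        ct = read_ct_matrix(cfg$inputs$ct),
        mrna = {
          x <- readr::read_tsv(cfg$inputs$mrna, show_col_types = FALSE)
          names(x)[1] <- "probe_id"; x
        },
        gene_map = readr::read_tsv(cfg$inputs$gene_map, show_col_types = FALSE),
        design = readr::read_csv(cfg$inputs$design, show_col_types = FALSE),
        predictions = readr::read_tsv(cfg$inputs$predictions,
                                      show_col_types = FALSE),
        clinical_path = cfg$inputs$clinical)
      state$controls <- cfg$endogenous_control
      list(outputs = list(),
           input_digests = as.list(tools::md5sum(unlist(cfg$inputs))))
    }
  })

  run_stage("quantify", function() {
    co <- state$cohort
    flt <- filter_detected(co$ct, co$design,
                           detection_limit = cfg$detection_limit,
                           max_undetected_fraction = cfg$max_undetected_fraction,
                           controls = state$controls)
    dct <- delta_ct(flt$retained, control = cfg$endogenous_control)
    # drop the remaining control assays; keep quantifiable miRNA probes
    dct <- dct[!dct$probe_id %in% state$controls, ]
    log2_expr <- dct
    log2_expr[-1] <- lapply(log2_expr[-1], function(x) -x)
    norm <- normalize_between_samples(log2_expr, cfg$between_sample_method)
    lin <- norm
    lin[-1] <- lapply(lin[-1], function(x) 2^x)
    complete <- !apply(is.na(expr_matrix(norm)), 1, any)
    state$mir_log2 <- norm[complete, ]
    state$mir_linear <- lin[complete, ]
    state$n_retained <- nrow(flt$retained) - sum(flt$retained[[1]] %in% state$controls)
    fc <- signed_fold_change(state$mir_linear, co$design)
    p_expr <- file.path(cfg$out_dir, "mir_expression_normalized.tsv")
    p_fc <- file.path(cfg$out_dir, "mir_fold_changes.tsv")
    readr::write_tsv(state$mir_log2, p_expr)
    readr::write_tsv(fc, p_fc)
    list(outputs = list(expression = p_expr, fold_changes = p_fc),
         n_retained = state$n_retained, n_excluded = nrow(flt$excluded))
  })

  run_stage("de_mir", function() {
    fit <- sam_fit(state$mir_log2, state$cohort$design,
                   n_perm = cfg$sam_n_perm, seed = seeds[["de_mir"]])
    res <- sam_select(fit, cfg$sam_delta)
    state$de_mir <- res
    p <- file.path(cfg$out_dir, "de_mir_sam.tsv")
    readr::write_tsv(res$called, p)
    list(outputs = list(table = p), n_called = res$n_called, fdr = res$fdr,
         s0 = fit$s0)
  })

  run_stage("de_mrna", function() {
    co <- state$cohort
    tt <- permuted_ttest(co$mrna, co$design, n_perm = cfg$mrna_n_perm,
                         seed = seeds[["de_mrna"]], alpha = cfg$mrna_alpha)
    sig <- tt[tt$significant, ]
    genes <- collapse_probes_to_genes(sig, co$gene_map)
    state$de_genes <- genes
    p1 <- file.path(cfg$out_dir, "de_mrna_probes.tsv")
    p2 <- file.path(cfg$out_dir, "de_mrna_genes.tsv")
    readr::write_tsv(tt, p1); readr::write_tsv(genes, p2)
    list(outputs = list(probes = p1, genes = p2),
         n_probes = nrow(sig), n_genes = nrow(genes))
  })

  run_stage("discriminant", function() {
    co <- state$cohort
    feats <- state$de_mir$called$feature_id
    if (length(feats) < 1) {
      return(list(outputs = list(), skipped = "no differentially expressed miRNAs"))
    }
    model <- fit_lda(state$mir_log2, co$design, features = feats)
    resub <- resubstitution_report(model, state$mir_log2, co$design)
    cv <- loocv_report(state$mir_log2, co$design, features = feats)
    proj <- predict(model, state$mir_log2)
    p1 <- file.path(cfg$out_dir, "lda_predictions.tsv")
    p2 <- file.path(cfg$out_dir, "lda_projection.tsv")
    readr::write_tsv(cv$predictions, p1)
    readr::write_tsv(proj, p2)
    list(outputs = list(predictions = p1, projection = p2),
         resubstitution_accuracy = resub$accuracy,
         misclassified = resub$misclassified,
         loocv_overall = cv$overall,
         loocv_per_group = setNames(cv$per_group$accuracy,
                                    cv$per_group$group))
  })

  run_stage("integrate", function() {
    co <- state$cohort
    preds <- filter_predictions(co$predictions, cfg$min_algorithms)
    de_mirs <- state$de_mir$called
    de_genes <- state$de_genes[, c("gene", "signed_fc")]
    cand <- intersect_candidates(de_mirs, de_genes, preds)
    state$candidates <- cand
    state$predictions_strict <- preds
    p <- file.path(cfg$out_dir, "candidate_pairs.tsv")
    readr::write_tsv(cand, p)
    list(outputs = list(candidates = p), n_pairs = nrow(cand),
         n_unique_genes = attr(cand, "n_unique_genes"))
  })

  run_stage("diffcoexpr", function() {
    co <- state$cohort
    de_mirs <- state$de_mir$called
    genes <- unique(state$candidates$gene)
    if (!nrow(de_mirs) || !length(genes)) {
      return(list(outputs = list(), skipped = "no candidate pairs"))
    }
    gene_expr <- gene_level_expression(co$mrna, co$gene_map)
    pairs <- tidyr::expand_grid(mir = de_mirs$feature_id, gene = genes)
    pred_key <- paste(state$predictions_strict$mir,
                      toupper(state$predictions_strict$gene))
    pairs$predicted <- paste(pairs$mir, toupper(pairs$gene)) %in% pred_key
    pairs$fc_mir <- de_mirs$signed_fc[match(pairs$mir, de_mirs$feature_id)]
    pairs$fc_gene <- state$de_genes$signed_fc[match(pairs$gene,
                                                    state$de_genes$gene)]
    res <- perm_diff_test(state$mir_log2, gene_expr, co$design, pairs,
                          n_perm = cfg$coexpr_n_perm,
                          alpha = cfg$coexpr_alpha,
                          seed = seeds[["diffcoexpr"]])
    summ <- summarize_interactions(res)
    nets <- export_network(res, cfg$out_dir, prefix = "network")
    p1 <- file.path(cfg$out_dir, "pair_stats.tsv")
    p2 <- file.path(cfg$out_dir, "interaction_summary.json")
    readr::write_tsv(tibble::as_tibble(res), p1)
    jsonlite::write_json(
      list(n_significant = attr(summ, "n_significant"),
           rounding = attr(summ, "rounding"),
           categories = summ),
      p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    net_paths <- list.files(cfg$out_dir, pattern = "^network_", full.names = TRUE)
    list(outputs = c(list(pair_stats = p1, summary = p2),
                     setNames(as.list(net_paths), basename(net_paths))),
         n_significant = attr(summ, "n_significant"))
  })

  run_stage("clinical", function() {
    co <- state$cohort
    path <- if (!is.null(co$clinical_path)) co$clinical_path else
      file.path(cfg$out_dir, "cohort", "clinical.csv")
    rec <- read_clinical(path)
    ft <- frequency_table(rec)
    p <- file.path(cfg$out_dir, "clinical_frequencies.tsv")
    readr::write_tsv(ft, p)
    list(outputs = list(frequencies = p), n_records = nrow(rec),
         n_familial = sum(rec$familial))
  })

  manifest$outputs <- unlist(lapply(manifest$stages, function(s) s$outputs),
                             use.names = TRUE)
  manifest$output_digests <- as.list(tools::md5sum(unname(manifest$outputs)))
  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Collapse an mRNA probe table to gene-level expression
#'
#' Averages probe rows mapping to the same gene (microarray probes on the
#' log2 scale), yielding one expression row per gene.
#'
#' @param mrna Wide probe-level expression tibble.
#' @param gene_map Tibble with `probe_id`, `gene`.
#' @return Wide gene-level tibble (`gene` first).
#' @export
gene_level_expression <- function(mrna, gene_map) {
  m <- expr_matrix(mrna)
  keep <- rownames(m) %in% gene_map$probe_id
  m <- m[keep, , drop = FALSE]
  g <- gene_map$gene[match(rownames(m), gene_map$probe_id)]
  agg <- rowsum(m, g) / as.vector(table(g)[sort(unique(g))])
  as_expr_tbl(agg[sort(unique(g)), , drop = FALSE], "gene")
}
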