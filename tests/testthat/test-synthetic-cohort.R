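test_that("the generator is fully determined by its seed", {
  cfg <- cohort_config(n_probes_mir = 40, n_genes = 50,
                       n_samples_per_group = c(4, 6), n_below_detection = 5,
                       de_mir = tibble::tibble(probe = "miR-x", magnitude = 3,
                                               direction = "up"),
                       seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ct, b$ct)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$clinical, b$clinical)

  # byte-identical files too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(a, d1); p2 <- write_cohort(b, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # and a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_cohort(cfg2)$ct, a$ct))
})

test_that("a null configuration plants nothing and yields no DE calls", {
  cfg <- cohort_config(n_probes_mir = 60, n_genes = 30,
                       n_samples_per_group = c(5, 7), seed = 3)
  co <- generate_cohort(cfg)
  expect_null(co$truth$de_mirs)
  expect_null(co$truth$dcx_pairs)
  expect_equal(length(co$truth$below_detection), 0)
  expr <- cohort_mir_log2(co)
  fit <- sam_fit(expr, co$design, n_perm = 200, seed = 5)
  res <- sam_select(fit, delta = 2)
  expect_equal(res$n_called, 0)
  expect_equal(res$fdr, 0)
})

test_that("planted fold changes are recovered at large n", {
  cfg <- cohort_config(n_probes_mir = 30, n_genes = 10,
                       n_samples_per_group = c(200, 200),
                       de_mir = tibble::tibble(probe = "miR-455", magnitude = 4.28,
                                               direction = "up"),
                       seed = 11)
  co <- generate_cohort(cfg)
  lin <- rel_expr(delta_ct(co$ct))
  lin <- lin[lin$probe_id == "miR-455", ]
  fc <- signed_fold_change(lin, co$design)
  expect_equal(fc$signed_fc, 4.28, tolerance = 0.10)
})

test_that("planted group correlations are recovered within 3 standard errors", {
  cfg <- cohort_config(n_probes_mir = 20, n_genes = 20,
                       n_samples_per_group = c(500, 500),
                       dcx_pairs = tibble::tibble(mir = "miR-sim-001",
                                                  gene = "GENE0005",
                                                  r_group1 = 0.8,
                                                  r_group2 = -0.8),
                       seed = 21)
  co <- generate_cohort(cfg)
  mirs <- cohort_mir_log2(co, method = "none")
  gexpr <- gene_level_expression(co$mrna, co$gene_map)
  cx <- coexpr_matrices(mirs, gexpr, co$design,
                        mirs = "miR-sim-001", genes = "GENE0005")
  se <- function(r, n) (1 - r^2) / sqrt(n - 1)
  r1 <- cx$r[cx$group == "F-BC"]; r2 <- cx$r[cx$group == "NF-BC"]
  expect_lt(abs(r1 - 0.8), 3 * se(0.8, 500))
  expect_lt(abs(r2 + 0.8), 3 * se(0.8, 500))
})

test_that("control probes are low-variance and below-detection probes undetected in both groups", {
  co <- generate_cohort(paper_scale_preset(seed = 13))
  m <- expr_matrix(co$ct)
  for (ctrl in co$truth$controls) {
    expect_lte(sd(m[ctrl, ]), co$config$ct_noise_sd)
  }
  d <- mirdcx:::check_design(co$design)
  for (p in co$truth$below_detection) {
    for (g in list(d$g1, d$g2)) {
      frac <- mean(is.na(m[p, g]) | m[p, g] > 38)
      expect_gt(frac, 0.60)
    }
  }
  # every planted entity names an existing feature
  expect_true(all(co$truth$de_mirs$probe %in% co$ct$probe_id))
  expect_true(all(co$truth$dcx_pairs$gene %in% co$gene_map$gene))
  expect_true(all(co$truth$dcx_pairs$mir %in% co$ct$probe_id))
})

test_that("the study-scale preset matches the panel dimensions", {
  cfg <- paper_scale_preset()
  expect_equal(cfg$n_probes_mir, 377)
  expect_equal(cfg$n_controls, 7)
  expect_equal(cfg$n_samples_per_group, c(9L, 26L))
  expect_equal(cfg$n_below_detection, 121)
  expect_equal(nrow(cfg$de_mir), 9)
  expect_equal(sum(cfg$de_mir$direction == "down"), 3)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_samples_per_group = c(2, 10)), "at least 3")
  expect_error(cohort_config(n_probes_mir = 10, n_below_detection = 11),
               "cannot exceed")
  expect_error(
    cohort_config(dcx_pairs = tibble::tibble(mir = "a", gene = "GENE0001",
                                             r_group1 = 1.2, r_group2 = 0)),
    "r")
  expect_error(
    cohort_config(ct_noise_sd = 0.5,
                  dcx_pairs = tibble::tibble(mir = "a", gene = "GENE0001",
                                             r_group1 = 1, r_group2 = 0)),
    "infeasible")
})

test_that("CT files round-trip through the Undetermined dialect", {
  cfg <- cohort_config(n_probes_mir = 15, n_genes = 10,
                       n_samples_per_group = c(4, 5), n_below_detection = 4,
                       undetermined_fraction = 0.5, seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  raw <- readLines(paths["ct"])
  expect_true(any(grepl("Undetermined", raw)))
  back <- read_ct_matrix(paths["ct"])
  expect_equal(expr_matrix(back), expr_matrix(co$ct), tolerance = 1e-9)
})
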