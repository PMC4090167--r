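test_that("pearson_r matches the product-moment formula and its edge cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(pearson_r(c(1, 2, 3), c(5, 5, 5))))  # constant vector
  expect_error(pearson_r(c(1, 2, NA), c(1, 2, 3)), "3 complete pairs")
  # missing pairs are dropped pairwise
  expect_equal(pearson_r(c(1, 2, 3, NA), c(2, 4, 6, 100)), 1)
})

test_that("co-expression matrices have the contract shape and are permutation invariant", {
  set.seed(61)
  mir <- toy_expr(matrix(rnorm(3 * 10), nrow = 3,
                         dimnames = list(paste0("m", 1:3), paste0("s", 1:10))),
                  "probe_id")
  gene <- toy_expr(matrix(rnorm(4 * 10), nrow = 4,
                          dimnames = list(paste0("g", 1:4), paste0("s", 1:10))),
                   "gene")
  design <- toy_design(4, 6)
  cx <- coexpr_matrices(mir, gene, design, mirs = paste0("m", 1:3),
                        genes = paste0("g", 1:4))
  M <- coexpr_matrix(cx, "F-BC")
  expect_equal(dim(M), c(4, 3))  # genes x miRs
  expect_true(all(abs(cx$r) <= 1))

  # permuting one group's sample columns leaves its matrix unchanged
  perm <- c("s3", "s1", "s4", "s2", paste0("s", 5:10))
  mir2 <- mir[, c("probe_id", perm)]
  gene2 <- gene[, c("gene", perm)]
  cx2 <- coexpr_matrices(mir2, gene2, design, mirs = paste0("m", 1:3),
                         genes = paste0("g", 1:4))
  expect_equal(coexpr_matrix(cx2, "F-BC"), M)
})

test_that("exhaustive permutation p equals the enumeration oracle on a 3+3 toy", {
  set.seed(67)
  x <- rnorm(6); y <- rnorm(6)
  mir <- toy_expr(matrix(x, nrow = 1, dimnames = list("m1", paste0("s", 1:6))),
                  "probe_id")
  gene <- toy_expr(matrix(y, nrow = 1, dimnames = list("g1", paste0("s", 1:6))),
                   "gene")
  design <- toy_design(3, 3)
  pairs <- tibble::tibble(mir = "m1", gene = "g1")
  res <- perm_diff_test(mir, gene, design, pairs, n_perm = 1000, seed = 1)
  expect_true(attr(res, "exhaustive"))

  # independent oracle: enumerate all 20 labelings directly
  combos <- combn(6, 3)
  dr <- apply(combos, 2, function(i1) {
    i2 <- setdiff(1:6, i1)
    abs(cor(x[i1], y[i1]) - cor(x[i2], y[i2]))
  })
  dr_obs <- abs(cor(x[1:3], y[1:3]) - cor(x[4:6], y[4:6]))
  expect_equal(res$delta_r, dr_obs)
  expect_equal(res$p_perm, mean(dr >= dr_obs - 1e-12))
})

test_that("delta_r and p are symmetric under a group-label swap", {
  set.seed(71)
  mir <- toy_expr(matrix(rnorm(2 * 7), nrow = 2,
                         dimnames = list(c("m1", "m2"), paste0("s", 1:7))),
                  "probe_id")
  gene <- toy_expr(matrix(rnorm(2 * 7), nrow = 2,
                          dimnames = list(c("g1", "g2"), paste0("s", 1:7))),
                   "gene")
  d1 <- toy_design(3, 4)
  d2 <- d1
  d2$group <- ifelse(d1$group == "F-BC", "NF-BC", "F-BC")
  pairs <- tibble::tibble(mir = c("m1", "m2"), gene = c("g1", "g2"))
  r1 <- perm_diff_test(mir, gene, d1, pairs, n_perm = 100, seed = 3)
  r2 <- perm_diff_test(mir, gene, d2, pairs, n_perm = 100, seed = 3)
  expect_true(attr(r1, "exhaustive"))  # choose(7,3) = 35 <= 100
  expect_equal(r1$delta_r, r2$delta_r)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$r_group1, r2$r_group2)
})

test_that("planted opposite correlations are recovered at large n", {
  cfg <- cohort_config(
    n_probes_mir = 10, n_genes = 10, n_samples_per_group = c(200, 200),
    dcx_pairs = tibble::tibble(mir = "miR-sim-001", gene = "GENE0002",
                               r_group1 = 0.8, r_group2 = -0.8),
    seed = 73)
  co <- generate_cohort(cfg)
  mirs <- cohort_mir_log2(co, method = "none")
  gexpr <- gene_level_expression(co$mrna, co$gene_map)
  cx <- coexpr_matrices(mirs, gexpr, co$design, mirs = "miR-sim-001",
                        genes = "GENE0002")
  se <- (1 - 0.8^2) / sqrt(200 - 1)
  expect_lt(abs(cx$r[cx$group == "F-BC"] - 0.8), 3 * se)
  expect_lt(abs(cx$r[cx$group == "NF-BC"] + 0.8), 3 * se)
})

test_that("interaction classification follows the fold-change quadrants", {
  expect_equal(classify_interaction(TRUE, 87.6, -100.0), "predicted_inverse")
  expect_equal(classify_interaction(TRUE, 10.2, 1.29), "predicted_same")
  expect_equal(classify_interaction(FALSE, -2, 3), "unpredicted_inverse")
  expect_equal(classify_interaction(FALSE, -2, -3), "unpredicted_same")
  # a tie fold change (+1, log ratio 0) is not inverse
  expect_equal(classify_interaction(TRUE, 1, -2), "predicted_same")
})

test_that("interaction summaries reproduce the category shares with both roundings", {
  stats <- toy_dcx_result(
    mir = paste0("m", 1:49), gene = paste0("g", 1:49),
    r1 = rep(0.5, 49), r2 = rep(-0.5, 49), p = rep(0.01, 49),
    predicted = rep(c(TRUE, TRUE, FALSE, FALSE), c(17, 14, 8, 10)),
    fc_mir = rep(2, 49),
    fc_gene = rep(c(-2, 2, -2, 2), c(17, 14, 8, 10)))
  s <- summarize_interactions(stats)
  expect_equal(s$n, c(17L, 14L, 8L, 10L))
  expect_equal(s$percent, c(34.7, 28.6, 16.3, 20.4))
  expect_equal(sum(s$n), attr(s, "n_significant"))
  s2 <- summarize_interactions(stats, rounding = "truncate")
  expect_equal(s2$percent, c(34.6, 28.5, 16.3, 20.4))
  expect_equal(attr(s2, "rounding"), "truncate")

  # empty input -> zero counts, percentages defined as zero
  empty <- stats[0, ]
  class(empty) <- class(stats)
  s0 <- summarize_interactions(empty)
  expect_equal(s0$n, rep(0L, 4))
  expect_equal(s0$percent, rep(0, 4))

  # a single occupied category carries 100%
  one <- toy_dcx_result("m", "g", 0.9, -0.9, 0.001, TRUE, 3, -3)
  expect_equal(summarize_interactions(one)$percent[1], 100)
})

test_that("network export writes one bipartite graph per group with the expected size", {
  # 17 predicted-inverse pairs spanning 7 miRs and 16 genes
  mirs <- paste0("miR-", 1:7)[c(1:7, 1:7, 1:3)]
  genes <- paste0("G", c(1:16, 16))
  stats <- toy_dcx_result(
    mir = mirs, gene = genes, r1 = seq(-0.9, 0.9, length.out = 17),
    r2 = rep(0.1, 17), p = rep(0.01, 17), predicted = TRUE,
    fc_mir = rep(2, 17), fc_gene = rep(-2, 17))
  dir <- withr::local_tempdir()
  nets <- export_network(stats, dir, prefix = "net")
  expect_named(nets, c("F-BC", "NF-BC"))
  g <- nets[["F-BC"]]
  expect_equal(igraph::vcount(g), 23)  # 7 miRs + 16 genes
  expect_equal(igraph::ecount(g), 17)
  expect_true(igraph::is_bipartite(g))
  expect_true(all(abs(igraph::E(g)$r) <= 1))
  files <- list.files(dir)
  expect_true(all(c("net_FBC.graphml", "net_FBC_edges.tsv",
                    "net_NFBC.graphml", "net_NFBC_edges.tsv") %in% files))

  # empty stats still produce valid (empty) graphs
  empty <- stats[0, ]
  class(empty) <- class(stats)
  attr(empty, "groups") <- c("F-BC", "NF-BC")
  nets0 <- export_network(empty, dir, prefix = "empty")
  expect_equal(igraph::vcount(nets0[["F-BC"]]), 0)
})

test_that("significant categories partition the significant set", {
  set.seed(79)
  co <- generate_cohort(cohort_config(
    n_probes_mir = 12, n_genes = 30, n_samples_per_group = c(8, 10),
    dcx_pairs = tibble::tibble(
      mir = paste0("miR-sim-00", 1:3), gene = sprintf("GENE%04d", 1:3),
      r_group1 = c(0.9, -0.8, 0.85), r_group2 = c(-0.8, 0.8, -0.75)),
    seed = 83))
  mirs <- cohort_mir_log2(co, method = "none")
  gexpr <- gene_level_expression(co$mrna, co$gene_map)
  pairs <- tidyr::expand_grid(mir = paste0("miR-sim-00", 1:3),
                              gene = sprintf("GENE%04d", 1:5))
  pairs$predicted <- pairs$gene %in% sprintf("GENE%04d", 1:3)
  pairs$fc_mir <- 2; pairs$fc_gene <- rep(c(-2, 2, -2, 2, -2), each = 3)[1:15]
  res <- perm_diff_test(mirs, gexpr, co$design, pairs, n_perm = 500, seed = 5)
  s <- summarize_interactions(res)
  expect_equal(sum(s$n), sum(res$significant, na.rm = TRUE))
  expect_true(all(res$delta_r >= 0 & res$delta_r <= 2, na.rm = TRUE))
  # determinism under the seed
  res2 <- perm_diff_test(mirs, gexpr, co$design, pairs, n_perm = 500, seed = 5)
  expect_equal(res$p_perm, res2$p_perm)
})
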