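test_that("detection filter excludes a probe only when both groups exceed the threshold", {
  # 9 + 26 samples; probe 'bad' undetected (CT 39) in 6/9 and 16/26 samples,
  # both fractions strictly above 0.60
  n1 <- 9; n2 <- 26
  m <- matrix(25, nrow = 3, ncol = n1 + n2,
              dimnames = list(c("ok", "bad", "onesided"), NULL))
  m["bad", c(1:6, 10:25)] <- 39
  m["onesided", 1:7] <- 39  # fails only in group 1
  ct <- toy_expr(m, "probe_id")
  design <- toy_design(n1, n2, ids = names(ct)[-1])
  flt <- filter_detected(ct, design)
  expect_equal(flt$excluded$probe_id, "bad")
  expect_setequal(flt$retained$probe_id, c("ok", "onesided"))
  # partition invariant
  expect_equal(nrow(flt$retained) + nrow(flt$excluded), nrow(ct))
})

test_that("all-detected matrices pass the filter untouched and NA counts as undetected", {
  m <- matrix(25, nrow = 4, ncol = 10)
  ct <- toy_expr(m, "probe_id")
  design <- toy_design(5, 5, ids = names(ct)[-1])
  flt <- filter_detected(ct, design)
  expect_equal(nrow(flt$excluded), 0)

  # Undetermined (NA) cells count as undetected
  m2 <- m
  m2[1, ] <- NA
  flt2 <- filter_detected(toy_expr(m2, "probe_id"), design)
  expect_equal(flt2$excluded$probe_id, "f1")
})

test_that("control probes are exempt from exclusion but flagged", {
  m <- matrix(39.5, nrow = 2, ncol = 8,
              dimnames = list(c("RNU48", "miR-x"), NULL))
  ct <- toy_expr(m, "probe_id")
  design <- toy_design(4, 4, ids = names(ct)[-1])
  flt <- filter_detected(ct, design, controls = "RNU48")
  expect_true("RNU48" %in% flt$retained$probe_id)
  expect_equal(flt$flagged_controls, "RNU48")
  expect_equal(flt$excluded$probe_id, "miR-x")
  expect_error(filter_detected(ct, design, controls = "RNU6B"), "absent")
})

test_that("delta-CT follows the one-cycle doubling arithmetic", {
  m <- rbind(RNU48 = c(20, 21), a = c(20, 21), b = c(21, 22), c = c(18, 19))
  colnames(m) <- c("s1", "s2")
  dct <- delta_ct(toy_expr(m, "probe_id"), control = "RNU48")
  lin <- rel_expr(dct)
  lm <- expr_matrix(lin)
  expect_equal(unname(lm["a", ]), c(1, 1))     # same CT as control
  expect_equal(unname(lm["b", ]), c(0.5, 0.5)) # one cycle later = half
  expect_equal(unname(lm["c", ]), c(4, 4))     # two cycles earlier = 4x
  # missing CT propagates
  m["b", 2] <- NA
  dct2 <- delta_ct(toy_expr(m, "probe_id"))
  expect_true(is.na(expr_matrix(dct2)["b", "s2"]))
})

test_that("a control undetermined in any sample is an error naming the sample", {
  m <- rbind(RNU48 = c(20, NA), a = c(22, 23))
  colnames(m) <- c("s1", "s2")
  expect_error(delta_ct(toy_expr(m, "probe_id")), "s2")
})

test_that("between-sample normalization honours its method contracts", {
  m <- rbind(a = c(0, 3), b = c(1, 4), c = c(2, 5))
  colnames(m) <- c("s1", "s2")
  expr <- toy_expr(m)
  expect_equal(normalize_between_samples(expr, "none"), expr)

  # median: per-sample medians 1 and 4 are equalised
  med <- normalize_between_samples(expr, "median")
  mm <- expr_matrix(med)
  expect_equal(median(mm[, 1]), median(mm[, 2]))
  expect_equal(median(mm[, 1]), 2.5)

  # quantile: columns that are permutations of each other end up as
  # permutations of one common multiset
  m2 <- cbind(s1 = c(5, 1, 3), s2 = c(1, 3, 5))
  rownames(m2) <- paste0("f", 1:3)
  q <- expr_matrix(normalize_between_samples(toy_expr(m2), "quantile"))
  expect_equal(unname(sort(q[, 1])), unname(sort(q[, 2])))

  expect_error(normalize_between_samples(expr[, 1:2, drop = FALSE], "median"),
               "2 samples")
})

test_that("signed fold change uses the symmetric reciprocal convention", {
  m <- rbind(up = c(rep(4.28, 3), rep(1, 3)),
             down = c(rep(0.5, 3), rep(1, 3)),
             tie = rep(2, 6))
  colnames(m) <- paste0("s", 1:6)
  design <- toy_design(3, 3)
  fc <- signed_fold_change(toy_expr(m), design)
  expect_equal(fc$signed_fc[fc$feature_id == "up"], 4.28)
  expect_equal(fc$signed_fc[fc$feature_id == "down"], -2)
  expect_equal(fc$signed_fc[fc$feature_id == "tie"], 1)
  expect_true(all(abs(fc$signed_fc) >= 1))
  expect_error(signed_fold_change(toy_expr(m - 2), design), "positive")
})

test_that("signed fold change is antisymmetric under group swap", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(2^rnorm(40), nrow = 5)
    expr <- toy_expr(m)
    d1 <- toy_design(4, 4, ids = names(expr)[-1])
    d2 <- d1
    d2$group <- ifelse(d1$group == "F-BC", "NF-BC", "F-BC")
    f1 <- signed_fold_change(expr, d1)
    f2 <- signed_fold_change(expr, d2)
    nt <- f1$ratio != 1
    expect_equal(f2$signed_fc[nt], -f1$signed_fc[nt])
  }
})

test_that("ddCT quantification is anchored at the reference and multiplicative", {
  m <- rbind(RNU48 = c(20, 20, 20), g = c(25, 24, 27))
  colnames(m) <- c("ref", "a", "b")
  ct <- toy_expr(m, "probe_id")
  expect_equal(unname(ddct_ratio(ct, "g", "ref", reference_sample = "ref")), 1)
  # dCT(a) = 4, dCT(ref) = 5 -> 2
  expect_equal(unname(ddct_ratio(ct, "g", "a", reference_sample = "ref")), 2)
  # dCT(b) = 7, dCT(ref) = 5 -> 0.25
  expect_equal(unname(ddct_ratio(ct, "g", "b", reference_sample = "ref")), 0.25)
  # ratio(a vs ref) / ratio(b vs ref) = ratio(a vs b)
  r_ab <- ddct_ratio(ct, "g", "a", reference_sample = "b")
  expect_equal(unname(ddct_ratio(ct, "g", "a", reference_sample = "ref") /
                        ddct_ratio(ct, "g", "b", reference_sample = "ref")),
               unname(r_ab))
  m["g", "a"] <- NA
  expect_error(ddct_ratio(toy_expr(m, "probe_id"), "g", "a",
                          reference_sample = "ref"), "missing CT")
})

test_that("Pfaffl ratios match hand arithmetic and reduce to 2^-ddCT at E = 2", {
  expect_equal(pfaffl_ratio(10, 10, 10, 10), 1)
  # exponents (2, 1): 1.9^2 / 2.0
  expect_equal(pfaffl_ratio(8, 10, 9, 10, e_target = 1.9, e_ref = 2.0),
               1.9^2 / 2.0)
  expect_equal(1.9^2 / 2.0, 1.805)
  m <- rbind(ACTB = c(18, 19.5), g = c(25.2, 23.1))
  colnames(m) <- c("ref", "a")
  ct <- toy_expr(m, "probe_id")
  dd <- ddct_ratio(ct, "g", "a", reference_sample = "ref", control = "ACTB")
  pf <- pfaffl_ratio(m["g", "a"], m["g", "ref"], m["ACTB", "a"], m["ACTB", "ref"])
  expect_equal(unname(pf), unname(dd), tolerance = 1e-12)
  expect_error(pfaffl_ratio(1, 2, 3, 4, e_target = 1), "efficienc")
})
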