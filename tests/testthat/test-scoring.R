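test_that("quartile-fence trimming matches the worked example", {
  tr <- trim_outliers(c(10, 11, 12, 13, 14, 100), multiplier = 1.7)
  # type-7 quartiles: Q1 = 11.25, Q3 = 13.75, IQR = 2.5, fences 7 / 18
  expect_equal(tr$fences, c(7, 18))
  expect_equal(tr$values, c(10, 11, 12, 13, 14))
  expect_equal(tr$keep, c(rep(TRUE, 5), FALSE))
})

test_that("trimming edge cases: equal values, in-fence identity, small n", {
  allsame <- trim_outliers(rep(3.2, 6))
  expect_equal(allsame$values, rep(3.2, 6))
  inside <- trim_outliers(c(4, 5, 6, 7))
  expect_equal(inside$values, c(4, 5, 6, 7))
  expect_warning(tr <- trim_outliers(c(1, 2, 100)), "fewer than 4")
  expect_equal(tr$values, c(1, 2, 100))
})

test_that("trimming agrees with brute-force fence enumeration", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rlnorm(n), round(rcauchy(n), 1))
    m <- sample(c(1.5, 1.7, 2.0), 1)
    expect_identical(trim_outliers(x, multiplier = m)$keep,
                     brute_trim_keep(x, multiplier = m))
  }
})

test_that("normalization to controls: ratio and difference modes", {
  expect_equal(normalize_to_controls(6, 3, "n_fold"), 2)
  expect_equal(normalize_to_controls(6, 3, "delta"), 3)
  expect_equal(normalize_to_controls(3, 3, "n_fold"), 1)
  expect_equal(normalize_to_controls(3, 3, "delta"), 0)
  z <- normalize_to_controls(c(1, 2), 0, "n_fold")
  expect_true(all(is.na(z)))
  expect_equal(attr(z, "reason"), "zero_control_mean")
})

test_that("z test, cluster and combined scores are direct arithmetic", {
  expect_equal(z_test(10, 10, 2), 0)
  expect_equal(z_test(12, 10, 2), 1)
  expect_true(is.na(z_test(5, 5, 0)))
  expect_equal(cluster_z(c(1, -1)), 0)
  expect_equal(cluster_z(0.5), 0.5)
  expect_equal(cluster_z(c(1, 2, 3)), 2)
  expect_equal(cluster_z(c(1, NA, 3)), 2)    # equal weights over non-missing
  expect_true(is.na(cluster_z(c(NA_real_, NA_real_))))
  expect_equal(combined_z(1, 0.5), 0.75)
  expect_equal(combined_z(0, 0), 0)
  expect_equal(combined_z(-2, 2), 0)
  expect_true(is.na(combined_z(NA, 1)))
  expect_true(is.na(combined_z(1, NA)))
})

test_that("cluster scores are order invariant and linear in members", {
  set.seed(32)
  z <- rnorm(5)
  expect_equal(cluster_z(z), cluster_z(rev(z)))
  expect_equal(cluster_z(2 * z + 1), 2 * cluster_z(z) + 1)
})

test_that("z of a sample against its own moments standardizes", {
  set.seed(33)
  x <- rnorm(500, 7, 3)
  z <- z_test(x, mean(x), sd(x))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("zscore_panel reproduces hand-computed cluster scores", {
  clusters <- list(pro_all = c("TNFa", "IL6"), anti_all = "IL4",
                   pro_core = c("TNFa", "IL6"), anti_core = "IL4")
  cyto <- expand.grid(analyte = c("TNFa", "IL6", "IL4"),
                      animal = c("C1", "C2", "C3", "K1"),
                      treatment = "BzATP", stringsAsFactors = FALSE)
  cyto$genotype <- ifelse(grepl("^C", cyto$animal), "CTRL", "KO")
  set.seed(34)
  cyto$n_fold <- rnorm(nrow(cyto), 2, 0.5)
  zp <- zscore_panel(cyto, shape_folds = NULL, clusters = clusters)
  expect_equal(nrow(zp), 1L)
  byhand <- vapply(c("TNFa", "IL6", "IL4"), function(an) {
    ref <- cyto$n_fold[cyto$genotype == "CTRL" & cyto$analyte == an]
    (cyto$n_fold[cyto$animal == "K1" & cyto$analyte == an] - mean(ref)) /
      sd(ref)
  }, numeric(1))
  expect_equal(zp$z_pro_core, mean(byhand[c("TNFa", "IL6")]))
  expect_equal(zp$z_anti_core, byhand[["IL4"]])
  # no shape folds supplied: combined scores propagate missingness
  expect_true(is.na(zp$proif) && is.na(zp$antiif))
})
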