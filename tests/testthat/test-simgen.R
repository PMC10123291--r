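test_that("cell generator is a pure function of (params, seed)", {
  p <- shape_params("ramified")
  set.seed(1)
  before <- .Random.seed
  c1 <- generate_cell_shape(p, seed = 7)
  c2 <- generate_cell_shape(p, seed = 7)
  expect_identical(c1$mask, c2$mask)
  expect_identical(before, .Random.seed)  # global RNG untouched
  c3 <- generate_cell_shape(p, seed = 8)
  expect_false(identical(c1$mask, c3$mask))
})

test_that("constructed round cells have no processes and classify round", {
  for (s in 1:5) {
    cell <- generate_cell_shape(
      shape_params("round_amoeboid", elongation = 1), seed = s)
    expect_equal(cell$truth$n_processes, 0L)
    d <- shape_descriptors(measure_cell(cell$mask))
    np <- count_processes(cell$mask)$n_processes
    expect_equal(as.character(
      classify_morphotype(d$aspect_ratio, np)$morphotype),
      "round_amoeboid")
  }
})

test_that("shape parameter invariants are enforced", {
  expect_error(shape_params("round_amoeboid", n_processes = 2), "processes")
  expect_error(shape_params("polarized", elongation = 2), "elongation")
  expect_error(shape_params("ramified", n_processes = 1), "3 processes")
  expect_error(shape_params(soma_radius_um = -1), "soma_radius")
  expect_error(generate_cell_shape(shape_params("ramified"), seed = 1,
                                   raster_px = c(20, 20)), "too small")
})

test_that("empty and degenerate ROI mixtures behave", {
  roi <- generate_roi(c(1, 0, 0), n_cells = 0, seed = 1,
                      roi_px = c(100L, 100L))
  expect_equal(max(roi$labels), 0)
  expect_equal(nrow(roi$truth), 0L)
  roi2 <- generate_roi(c(1, 0, 0), n_cells = 20, seed = 2,
                       roi_px = c(400L, 400L))
  expect_true(all(roi2$truth$morphotype == "round_amoeboid"))
  expect_equal(sort(unique(as.vector(roi2$labels))), 0:20)
})

test_that("ROI generator is deterministic and truth matches the raster", {
  roi1 <- generate_roi(c(0.5, 0.3, 0.2), 15, seed = 9,
                       roi_px = c(400L, 400L))
  roi2 <- generate_roi(c(0.5, 0.3, 0.2), 15, seed = 9,
                       roi_px = c(400L, 400L))
  expect_identical(roi1$labels, roi2$labels)
  expect_identical(roi1$nuclei, roi2$nuclei)
  expect_identical(roi1$truth, roi2$truth)
  # every truth row owns a nonempty region, centred inside it
  for (i in roi1$truth$cell_id) {
    expect_gt(sum(roi1$labels == i), 0)
  }
  # construction-rule classification agrees with truth labels
  cm <- measure_roi(roi1)
  merged <- merge(cm, roi1$truth, by = "cell_id")
  expect_gte(mean(as.character(merged$morphotype.x) ==
                  merged$morphotype.y), 0.9)
})

test_that("sampled morphotype proportions sit in exact binomial bounds", {
  mix <- c(0.6, 0.2, 0.2)
  pooled <- table(factor(
    unlist(lapply(1:20, function(s) sample_morphotypes(mix, 300, seed = s))),
    levels = morphotype_levels()))
  n <- 20 * 300
  for (k in 1:3) {
    ci <- stats::qbinom(c(0.005, 0.995), n, mix[k])
    expect_gte(pooled[k], ci[1])
    expect_lte(pooled[k], ci[2])
  }
  # convergence: at n = 3000 each class proportion is within +/- 2%
  big <- table(factor(sample_morphotypes(mix, 3000, seed = 123),
                      levels = morphotype_levels())) / 3000
  expect_true(all(abs(as.numeric(big) - mix) <= 0.02))
})

test_that("zero-noise standards lie exactly on the forward 5PL", {
  des <- plate_design(n_animals = 2, noise_cv = 0, bio_cv = 0)
  pd <- generate_cytokine_experiment(des, seed = 3)
  cp <- des$curve_params
  for (an in c("TNFa", "IL6")) {
    st <- pd$standards[pd$standards$analyte == an, ]
    pp <- cp[cp$analyte == an, ]
    expect_equal(st$response,
                 fivepl(st$concentration, pp$A, pp$D, pp$C, pp$B, pp$g),
                 tolerance = 1e-12)
  }
  # standards: 6 concentrations, strictly decreasing by 10x, duplicated
  st <- pd$standards[pd$standards$analyte == "TNFa", ]
  conc <- unique(st$concentration)
  expect_equal(length(conc), 6L)
  expect_equal(conc[-6] / conc[-1], rep(10, 5))
  expect_equal(nrow(st), 12L)
})

test_that("plate structure: two control wells per animal, positive effects", {
  des <- plate_design(n_animals = 3)
  pd <- generate_cytokine_experiment(des, seed = 4)
  ctl <- pd$samples[pd$samples$role == "control" &
                    pd$samples$analyte == "IL6", ]
  expect_true(all(table(ctl$animal) == 2L))
  expect_error(plate_design(noise_cv = -0.1), "noise_cv")
  bad_eff <- default_effects(); bad_eff$multiplier[3] <- 0
  expect_error(plate_design(effects = bad_eff), "multiplier")
})

test_that("null effects leave treated and control wells exchangeable", {
  # with all multipliers at 1, the KS p value comparing treated vs
  # control responses should be uniform over repeated experiments
  des <- plate_design(n_animals = 6, analytes = "TNFa",
                      curve_params = default_curve_params()[1, ],
                      effects = null_effects(), bio_cv = 0)
  pvals <- vapply(1:200, function(s) {
    pd <- generate_cytokine_experiment(des, seed = 5000 + s)
    sa <- pd$samples
    suppressWarnings(stats::ks.test(
      sa$response[sa$role == "treatment"],
      sa$response[sa$role == "control"])$p.value)
  }, numeric(1))
  # the two-sample KS p value is discrete at these group sizes, so assert
  # calibration (no excess rejections, p values centred) rather than
  # exact uniformity
  expect_lte(mean(pvals < 0.05), 0.07)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.75)
})
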