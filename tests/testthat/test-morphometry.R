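test_that("analytic circle measures match closed forms", {
  g <- measure_cell(raster_disk(50), pixel_size_um = 1)
  d <- shape_descriptors(g)
  expect_lt(abs(g$area_um2 - pi * 50^2) / (pi * 50^2), 0.01)
  expect_lt(abs(g$perimeter_um - 2 * pi * 50) / (2 * pi * 50), 0.02)
  expect_gte(d$circularity, 0.98)
  expect_lte(d$circularity, 1)
  expect_lt(abs(d$roundness - 1), 0.02)
  expect_lt(abs(d$aspect_ratio - 1), 0.02)
  expect_gte(d$solidity, 0.98)
  expect_lt(abs(d$complexity_index - 2 / 50) / (2 / 50), 0.05)
})

test_that("analytic square measures match closed forms", {
  g <- measure_cell(raster_square(100))
  d <- shape_descriptors(g)
  expect_equal(g$area_um2, 1e4)
  expect_lt(abs(g$perimeter_um - 400) / 400, 0.02)
  expect_lt(abs(d$circularity - pi / 4) / (pi / 4), 0.02)
  expect_lt(abs(g$convex_area_um2 - g$area_um2) / g$area_um2, 0.02)
})

test_that("ellipse axes and descriptors match the 60/20 closed form", {
  g <- measure_cell(raster_ellipse(60, 20))
  d <- shape_descriptors(g)
  expect_lt(abs(d$aspect_ratio - 3), 0.05)
  expect_lt(abs(d$roundness - 1 / 3), 0.01)
  # area-preserving ellipse convention
  expect_lt(abs(pi * (g$major_axis_um / 2) * (g$minor_axis_um / 2) -
                g$area_um2) / g$area_um2, 1e-9)
})

test_that("cross fixture: hull area from the polygon oracle", {
  g <- measure_cell(raster_cross())
  d <- shape_descriptors(g)
  expect_equal(g$area_um2, 3600)
  expect_lt(abs(g$convex_area_um2 - 6800) / 6800, 0.02)
  expect_lt(abs(d$solidity - 3600 / 6800), 0.02)
})

test_that("pixel size scales dimensional measures and leaves ratios alone", {
  m <- raster_ellipse(40, 25)
  g1 <- measure_cell(m, pixel_size_um = 1)
  g2 <- measure_cell(m, pixel_size_um = 2)
  expect_equal(g2$perimeter_um, 2 * g1$perimeter_um, tolerance = 1e-12)
  expect_equal(g2$major_axis_um, 2 * g1$major_axis_um, tolerance = 1e-12)
  expect_equal(g2$area_um2, 4 * g1$area_um2, tolerance = 1e-12)
  expect_equal(g2$convex_area_um2, 4 * g1$convex_area_um2,
               tolerance = 1e-12)
  d1 <- shape_descriptors(g1); d2 <- shape_descriptors(g2)
  for (col in c("circularity", "aspect_ratio", "roundness", "solidity")) {
    expect_equal(d2[[col]], d1[[col]], tolerance = 1e-6)
  }
  expect_equal(d2$complexity_index, d1$complexity_index / 2,
               tolerance = 1e-6)
})

test_that("descriptors are rotation invariant within 2%", {
  ref <- shape_descriptors(measure_cell(raster_ellipse(50, 25, angle = 0)))
  for (ang in c(pi / 7, pi / 4, 1.2, 2.0)) {
    d <- shape_descriptors(measure_cell(raster_ellipse(50, 25, angle = ang)))
    for (col in names(ref)) {
      expect_lt(abs(d[[col]] - ref[[col]]) / abs(ref[[col]]), 0.02)
    }
  }
})

test_that("roundness is the exact reciprocal of aspect ratio", {
  set.seed(41)
  for (i in 1:50) {
    mt <- sample(morphotype_levels(), 1)
    cell <- generate_cell_shape(shape_params(mt), seed = 7000 + i)
    d <- shape_descriptors(measure_cell(cell$mask))
    expect_lt(abs(d$roundness * d$aspect_ratio - 1), 1e-9)
  }
})

test_that("process counting: disk has none, generated cells re-measure", {
  expect_identical(count_processes(raster_disk(20))$n_processes, 0L)
  set.seed(5)
  n_ram <- integer(8); n_pol <- integer(8)
  for (i in 1:8) {
    ram <- generate_cell_shape(
      shape_params("ramified", n_processes = 5, boundary_noise = 0.03),
      seed = 300 + i)
    n_ram[i] <- count_processes(ram$mask)$n_processes
    pol <- generate_cell_shape(
      shape_params("polarized", n_processes = 2, boundary_noise = 0.03),
      seed = 400 + i)
    n_pol[i] <- count_processes(pol$mask)$n_processes
  }
  expect_true(all(abs(n_ram - 5) <= 1))
  expect_true(all(n_pol >= 0 & n_pol <= 2))
})

test_that("morphotype decision rules follow the three-class taxonomy", {
  expect_equal(as.character(
    classify_morphotype(1.2, 0L)$morphotype), "round_amoeboid")
  expect_equal(as.character(
    classify_morphotype(3.5, 1L)$morphotype), "polarized")
  expect_equal(as.character(
    classify_morphotype(1.5, 4L)$morphotype), "ramified")
  # taxonomy gap: some processes, not elongated, not ramified
  gap <- classify_morphotype(2.0, 2L)
  expect_equal(as.character(gap$morphotype), "round_amoeboid")
  expect_true(gap$flagged)
  # boundary: exactly AR 3 with a process is polarized
  expect_equal(as.character(
    classify_morphotype(3.0, 1L)$morphotype), "polarized")
})

test_that("measure_cell rejects empty and fragmented regions", {
  expect_error(measure_cell(matrix(FALSE, 5, 5)), "empty")
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE; m[12:15, 12:15] <- TRUE
  expect_error(measure_cell(m, cell_id = 7), "7")
})

test_that("measure_roi excludes border-touching cells and handles empties", {
  lab <- matrix(0L, 60, 60)
  lab[1:10, 5:14] <- 1L          # touches border
  lab[30:40, 30:40] <- 2L        # interior
  res <- measure_roi(lab)
  expect_equal(res$cell_id, 2L)
  res_all <- measure_roi(lab, exclude_border = FALSE)
  expect_equal(sort(res_all$cell_id), c(1L, 2L))
  empty <- measure_roi(matrix(0L, 30, 30))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("morphotype", "complexity_index") %in% names(empty)))
})
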