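test_that("blank rasters count zero without error", {
  r <- count_nuclei(matrix(0, 50, 50))
  expect_equal(r$n_cells, 0L)
  expect_equal(nrow(r$centroids), 0L)
  expect_equal(r$density_per_mm2, 0)
})

test_that("well-separated synthetic nuclei are counted accurately", {
  img <- nuclei_fixture(n_blobs = 64, dim_px = 400, rad = 5)
  r <- count_nuclei(img, pixel_size_um = 1)
  expect_lte(abs(r$n_cells - 64), 2)  # within ~2%
  # deterministic
  r2 <- count_nuclei(img, pixel_size_um = 1)
  expect_identical(r$centroids, r2$centroids)
})

test_that("watershed splits a fused two-peak blob", {
  img <- matrix(0, 60, 60)
  add_blob <- function(img, x0, y0, rad = 7) {
    gx <- matrix(1:60, 60, 60); gy <- t(gx)
    d <- sqrt((gx - x0)^2 + (gy - y0)^2)
    pmax(img, pmax(0, 0.9 * (1 - (d / rad)^2)))
  }
  img <- add_blob(img, 26, 30)
  img <- add_blob(img, 36, 30)   # centres 10 px apart: blobs fuse
  with_ws <- count_nuclei(img, sigma = 1, size_range_um2 = c(10, 800))
  without <- count_nuclei(img, sigma = 1, watershed = FALSE,
                          size_range_um2 = c(10, 800))
  expect_equal(with_ws$n_cells, 2L)
  expect_equal(without$n_cells, 1L)
})

test_that("widening the size filter never decreases the count", {
  img <- nuclei_fixture(n_blobs = 36, dim_px = 300, rad = 5, seed = 7)
  ranges <- list(c(40, 60), c(30, 90), c(10, 200), c(0, 1e5))
  counts <- vapply(ranges, function(rg)
    count_nuclei(img, size_range_um2 = rg)$n_cells, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("nucleus centroids map to cells and flag multinucleation", {
  lab <- matrix(0L, 40, 40)
  lab[10:20, 10:20] <- 1L
  one <- nuclei_per_cell(lab, cbind(x_um = 15, y_um = 15))
  expect_equal(one$per_cell$n_nuclei, 1L)
  expect_false(one$multinucleated)
  two <- nuclei_per_cell(lab, cbind(x_um = c(12, 18), y_um = c(12, 18)))
  expect_equal(two$per_cell$n_nuclei, 2L)
  expect_true(two$multinucleated)
  expect_warning(
    bg <- nuclei_per_cell(lab, cbind(x_um = 35, y_um = 35)),
    "background")
  expect_equal(bg$per_cell$n_nuclei, 0L)
  expect_equal(bg$n_unassigned, 1L)
})

test_that("misaligned rasters raise an alignment error", {
  img <- nuclei_fixture(n_blobs = 4, dim_px = 80, rad = 5)
  cn <- count_nuclei(img)
  expect_error(nuclei_per_cell(matrix(0L, 60, 60), cn), "shapes")
})

test_that("generated ROIs carry one nucleus per cell (counting truth)", {
  roi <- generate_roi(c(0.6, 0.2, 0.2), 12, seed = 17,
                      roi_px = c(400L, 400L), multinucleated_prob = 0)
  cn <- count_nuclei(roi$nuclei, roi$pixel_size_um)
  expect_lte(abs(cn$n_cells - 12) / 12, 0.02)
  npc <- suppressWarnings(nuclei_per_cell(roi$labels, cn,
                                          roi$pixel_size_um))
  expect_false(npc$multinucleated)
})
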