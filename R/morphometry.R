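#' @import EBImage
NULL

# The three morphotype labels used throughout, in decision order.
MORPHOTYPES <- c("round_amoeboid", "polarized", "ramified")

#' Morphotype labels
#'
#' The three cell-shape classes used for classification: round/amoeboid
#' (no processes), polarized/rod-like (length-to-width ratio >= 3) and
#' ramified (>= 3 processes).
#'
#' @return character vector of the three labels.
#' @export
morphotype_levels <- function() MORPHOTYPES

# Separable truncated-Gaussian smoothing via banded convolution matrices
# (cached per size); the input is expected to be zero-padded by at least
# `radius`, so edge truncation only ever touches zeros.
.band_cache <- new.env(parent = emptyenv())

.band_matrix <- function(n, k, radius) {
  key <- paste0(n, ":", radius)
  got <- .band_cache[[key]]
  if (!is.null(got)) return(got)
  K <- matrix(0, n, n)
  for (o in seq.int(-radius, radius)) {
    i <- max(1L, 1L - o):min(n, n - o)
    K[cbind(i, i + o)] <- k[o + radius + 1L]
  }
  .band_cache[[key]] <- K
  K
}

.gauss_smooth <- function(z, sigma = 1.0, radius = 3L) {
  k <- stats::dnorm(seq.int(-radius, radius), sd = sigma)
  k <- k / sum(k)
  Kr <- .band_matrix(nrow(z), k, radius)
  Kc <- .band_matrix(ncol(z), k, radius)
  Kr %*% z %*% Kc
}

# Sub-pixel outer contour of a binary mask: the mask is zero-padded,
# smoothed with a small Gaussian and traced at the 0.5 level.  Pixel-edge
# perimeters systematically overestimate the length of smooth boundaries
# (and push circularity past 1); the smoothed iso-contour stays within
# ~1% of analytic values for disk- and bar-like shapes.
.outer_contour <- function(mask, sigma = 1.0, pad = 6L) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  z[pad + seq_len(nr), pad + seq_len(nc)] <- as.numeric(mask)
  zs <- .gauss_smooth(z, sigma = sigma)
  cl <- grDevices::contourLines(seq_len(nrow(zs)), seq_len(ncol(zs)), zs,
                                levels = 0.5)
  if (length(cl) == 0L) stop("no contour found for region", call. = FALSE)
  areas <- vapply(cl, function(cc) polygon_area(cc$x, cc$y), numeric(1))
  outer <- cl[[which.max(areas)]]
  list(x = outer$x - pad, y = outer$y - pad)
}

.perimeter_of <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  j <- c(seq.int(2L, n), 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Measure the geometry of a single cell mask
#'
#' Computes area, sub-pixel contour perimeter, the axes of the
#' second-moment ellipse rescaled to preserve the region area, convex-hull
#' area and centroid, all in micrometres via \code{pixel_size_um}.  Holes
#' are filled before measurement.  With the area-preserving ellipse
#' convention, \code{pi * (major/2) * (minor/2)} equals the region area
#' exactly, which makes roundness the exact reciprocal of aspect ratio.
#'
#' @param mask logical or 0/1 matrix, one connected region.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param intensity optional numeric matrix of the same shape; the mean
#'   value over the region is reported as \code{mean_intensity}.
#' @param cell_id identifier carried into the output (and error messages).
#' @return one-row data.frame with columns \code{cell_id}, \code{area_um2},
#'   \code{perimeter_um}, \code{major_axis_um}, \code{minor_axis_um},
#'   \code{convex_area_um2}, \code{centroid_x_um}, \code{centroid_y_um},
#'   \code{mean_intensity}.
#' @export
measure_cell <- function(mask, pixel_size_um = 1, intensity = NULL,
                         cell_id = 1L) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  m <- (mask > 0) * 1
  if (!any(m > 0)) stop("empty region for cell ", cell_id, call. = FALSE)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1L) {
    stop("region for cell ", cell_id, " has ", max(lab),
         " connected components; expected 1", call. = FALSE)
  }
  m <- EBImage::fillHull(lab) > 0

  px <- which(m, arr.ind = TRUE)
  n <- nrow(px)
  area_px <- n
  cx <- mean(px[, 1]); cy <- mean(px[, 2])

  # second-order central moments (pixels as unit squares: +1/12 each axis)
  dx <- px[, 1] - cx; dy <- px[, 2] - cy
  mu20 <- mean(dx * dx) + 1 / 12
  mu02 <- mean(dy * dy) + 1 / 12
  mu11 <- mean(dx * dy)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 1e-12)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  # rescale so the ellipse area equals the region area exactly
  s <- sqrt(area_px / (pi * (major / 2) * (minor / 2)))
  major <- major * s
  minor <- minor * s

  contour <- .outer_contour(m)
  perim_px <- .perimeter_of(contour)
  # convex hull over pixel corners (each pixel a unit square), so hull
  # area is exact for polygonal shapes and >= pixel area always
  hx <- c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5)
  hy <- c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5)
  hull <- grDevices::chull(hx, hy)
  hull_area_px <- polygon_area(hx[hull], hy[hull])

  u <- pixel_size_um
  structure(list(
    cell_id = cell_id,
    area_um2 = area_px * u^2,
    perimeter_um = perim_px * u,
    major_axis_um = major * u,
    minor_axis_um = minor * u,
    convex_area_um2 = hull_area_px * u^2,
    centroid_x_um = cx * u,
    centroid_y_um = cy * u,
    mean_intensity = if (is.null(intensity)) NA_real_ else mean(intensity[m])
  ), class = "data.frame", row.names = 1L)
}

#' Shape descriptors from cell geometry
#'
#' The five descriptors: circularity \eqn{4\pi A / P^2}, aspect ratio
#' major/minor, roundness \eqn{4A/(\pi \cdot major^2)}, solidity
#' \eqn{A / A_{convex}}, and the complexity index \eqn{P / A} (1/um), a
#' proxy for ramification (long perimeter relative to area = more complex
#' cell).  Circularity and solidity live in [0, 1] and are clamped there
#' when discretization overshoots; roundness is the reciprocal of aspect
#' ratio under the area-preserving ellipse convention.
#'
#' @param shape data.frame as returned by \code{\link{measure_cell}}
#'   (one or more rows).
#' @return data.frame with columns \code{circularity}, \code{aspect_ratio},
#'   \code{roundness}, \code{solidity}, \code{complexity_index}.
#' @export
shape_descriptors <- function(shape) {
  stopifnot(all(c("area_um2", "perimeter_um", "major_axis_um",
                  "minor_axis_um", "convex_area_um2") %in% names(shape)))
  A <- shape$area_um2
  P <- shape$perimeter_um
  data.frame(
    circularity = clamp(4 * pi * A / P^2, 0, 1),
    aspect_ratio = shape$major_axis_um / shape$minor_axis_um,
    roundness = 4 * A / (pi * shape$major_axis_um^2),
    solidity = clamp(A / shape$convex_area_um2, 0, 1),
    complexity_index = P / A
  )
}

#' Count cell processes and estimate the soma
#'
#' The soma is taken as the maximal inscribed disk of the mask (centre and
#' radius from the distance transform).  Pixels of the mask lying outside
#' the soma disk (expanded by \code{soma_expand}) are labelled into
#' connected components; each component whose radial extent beyond the
#' expanded disk exceeds \code{k} times the soma radius counts as one
#' process.  Note that the two poles of a strongly elongated (rod-like)
#' soma protrude past its inscribed disk and are counted as processes;
#' this is intentional, because it is the downstream classifier that
#' separates "has processes + length-to-width >= 3" (polarized) from
#' ">= 3 processes" (ramified).
#'
#' @param mask logical or 0/1 matrix, one connected region.
#' @param pixel_size_um micrometres per pixel.
#' @param k minimum process length as a fraction of the soma radius.
#' @param soma_expand multiplicative margin on the soma disk before a
#'   pixel is considered outside the soma.
#' @return list with \code{n_processes}, \code{soma_radius_um},
#'   \code{soma_center_um} (x, y).
#' @export
count_processes <- function(mask, pixel_size_um = 1, k = 0.5,
                            soma_expand = 1.15) {
  stopifnot(is.matrix(mask), pixel_size_um > 0, k > 0, soma_expand >= 1)
  m <- mask > 0
  if (!any(m)) stop("empty region", call. = FALSE)
  d <- EBImage::distmap((mask > 0) * 1)
  if (max(d) <= 0) stop("degenerate region: skeleton/soma undefined",
                        call. = FALSE)
  ctr <- which(d == max(d), arr.ind = TRUE)[1, ]
  soma_r <- max(d)

  px <- which(m, arr.ind = TRUE)
  radial <- sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
  cutoff <- soma_expand * soma_r
  outside <- radial > cutoff
  n_proc <- 0L
  if (any(outside)) {
    om <- matrix(0, nrow(m), ncol(m))
    om[px[outside, , drop = FALSE]] <- 1
    lab <- EBImage::bwlabel(om)
    labs <- lab[px[outside, , drop = FALSE]]
    ext <- tapply(radial[outside] - cutoff, labs, max)
    n_proc <- sum(ext > k * soma_r)
  }
  list(
    n_processes = as.integer(n_proc),
    soma_radius_um = soma_r * pixel_size_um,
    soma_center_um = c(x = unname(ctr[1]) * pixel_size_um,
                       y = unname(ctr[2]) * pixel_size_um)
  )
}

#' Classify cells into the three morphotypes
#'
#' Decision order: no processes -> round/amoeboid; otherwise aspect ratio
#' >= \code{ar_threshold} -> polarized/rod-like; otherwise >=
#' \code{min_processes} processes -> ramified.  Cells with 1-2 processes
#' and aspect ratio below the threshold fall outside the three-class
#' taxonomy and are assigned the \code{fallback} class with
#' \code{flagged = TRUE}, which keeps the binary grouping
#' [round/amoeboid] vs [polarized + ramified] conservative.
#'
#' @param aspect_ratio numeric vector (>= 1).
#' @param n_processes integer vector, same length.
#' @param ar_threshold length-to-width ratio defining polarized cells.
#' @param min_processes process count defining ramified cells.
#' @param fallback class assigned to taxonomy gaps.
#' @return data.frame with \code{morphotype} (factor over the three
#'   labels) and \code{flagged} (logical).
#' @export
classify_morphotype <- function(aspect_ratio, n_processes, ar_threshold = 3,
                                min_processes = 3,
                                fallback = "round_amoeboid") {
  stopifnot(length(aspect_ratio) == length(n_processes),
            fallback %in% MORPHOTYPES)
  lab <- ifelse(n_processes == 0L, "round_amoeboid",
         ifelse(aspect_ratio >= ar_threshold, "polarized",
         ifelse(n_processes >= min_processes, "ramified", NA_character_)))
  flagged <- is.na(lab)
  lab[flagged] <- fallback
  data.frame(morphotype = factor(lab, levels = MORPHOTYPES),
             flagged = flagged)
}

#' Measure every cell in a label raster
#'
#' Runs \code{\link{measure_cell}}, \code{\link{count_processes}},
#' \code{\link{shape_descriptors}} and \code{\link{classify_morphotype}}
#' for each labelled region and returns one tidy row per cell.  Cells
#' touching the raster border are excluded by default since truncated
#' geometry corrupts the descriptors.
#'
#' @param labels integer matrix (0 = background, k = cell id) or an object
#'   from \code{\link{generate_roi}} (its \code{labels} and
#'   \code{intensity} are used).
#' @param pixel_size_um micrometres per pixel; taken from the ROI object
#'   if one is supplied.
#' @param intensity optional intensity raster.
#' @param exclude_border drop cells touching the raster border.
#' @param process_k,ar_threshold,min_processes passed to
#'   \code{\link{count_processes}} / \code{\link{classify_morphotype}}.
#' @return data.frame, one row per measured cell.
#' @export
measure_roi <- function(labels, pixel_size_um = 1, intensity = NULL,
                        exclude_border = TRUE, process_k = 0.5,
                        ar_threshold = 3, min_processes = 3) {
  if (inherits(labels, "roi_image")) {
    roi <- labels
    labels <- roi$labels
    pixel_size_um <- roi$pixel_size_um
    if (is.null(intensity)) intensity <- roi$intensity
  }
  stopifnot(is.matrix(labels))
  nr <- nrow(labels); nc <- ncol(labels)
  # single scan of the raster, pixels grouped by label
  px_all <- which(labels > 0L)
  ids_all <- labels[px_all]
  rows_all <- (px_all - 1L) %% nr + 1L
  cols_all <- (px_all - 1L) %/% nr + 1L
  by_id <- split(seq_along(ids_all), ids_all)
  ids <- as.integer(names(by_id))
  out <- vector("list", length(ids))
  kept <- 0L
  for (j in seq_along(ids)) {
    id <- ids[j]
    sel <- by_id[[j]]
    rs <- rows_all[sel]; cs <- cols_all[sel]
    r1 <- min(rs); r2 <- max(rs)
    c1 <- min(cs); c2 <- max(cs)
    if (exclude_border && (r1 == 1L || c1 == 1L || r2 == nr || c2 == nc)) next
    pr1 <- max(1L, r1 - 3L); pr2 <- min(nr, r2 + 3L)
    pc1 <- max(1L, c1 - 3L); pc2 <- min(nc, c2 + 3L)
    sub <- matrix(FALSE, pr2 - pr1 + 1L, pc2 - pc1 + 1L)
    sub[cbind(rs - pr1 + 1L, cs - pc1 + 1L)] <- TRUE
    subint <- if (is.null(intensity)) NULL else intensity[pr1:pr2, pc1:pc2]
    geom <- measure_cell(sub, pixel_size_um, intensity = subint, cell_id = id)
    geom$centroid_x_um <- geom$centroid_x_um + (pr1 - 1L) * pixel_size_um
    geom$centroid_y_um <- geom$centroid_y_um + (pc1 - 1L) * pixel_size_um
    proc <- count_processes(sub, pixel_size_um, k = process_k)
    kept <- kept + 1L
    out[[kept]] <- c(unlist(geom, use.names = FALSE),
                     proc$n_processes, proc$soma_radius_um)
  }
  if (kept == 0L) {
    return(data.frame(cell_id = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), major_axis_um = numeric(),
                      minor_axis_um = numeric(), convex_area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      mean_intensity = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), roundness = numeric(),
                      solidity = numeric(), complexity_index = numeric(),
                      n_processes = integer(), soma_radius_um = numeric(),
                      morphotype = factor(character(), levels = MORPHOTYPES),
                      flagged = logical()))
  }
  mat <- do.call(rbind, out[seq_len(kept)])
  res <- data.frame(
    cell_id = as.integer(mat[, 1]), area_um2 = mat[, 2],
    perimeter_um = mat[, 3], major_axis_um = mat[, 4],
    minor_axis_um = mat[, 5], convex_area_um2 = mat[, 6],
    centroid_x_um = mat[, 7], centroid_y_um = mat[, 8],
    mean_intensity = mat[, 9])
  res <- cbind(res, shape_descriptors(res))
  res$n_processes <- as.integer(mat[, 10])
  res$soma_radius_um <- mat[, 11]
  cls <- classify_morphotype(res$aspect_ratio, res$n_processes,
                             ar_threshold = ar_threshold,
                             min_processes = min_processes)
  res$morphotype <- cls$morphotype
  res$flagged <- cls$flagged
  res
}
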