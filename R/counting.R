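# Automated nuclei counting in a DAPI-like channel, emulating the usual
# blur -> global threshold -> fill holes -> watershed split -> size filter
# chain of an image-analysis macro.  All parameters are exposed; fidelity
# target is count accuracy, not identity of any particular macro's steps.

#' Count nuclei in a single-channel raster
#'
#' @param nuclei numeric matrix, intensities in [0, 1] (0 = background).
#' @param pixel_size_um micrometres per pixel.
#' @param sigma Gaussian smoothing sd in pixels before thresholding.
#' @param threshold either \code{"otsu"} (default) or a numeric global
#'   threshold on the smoothed image.
#' @param watershed split touching blobs by a distance-transform
#'   watershed (default TRUE).
#' @param size_range_um2 c(min, max) retained object area; objects outside
#'   are discarded.
#' @return list of class \code{count_result}: \code{n_cells},
#'   \code{centroids} (matrix, um), \code{density_per_mm2},
#'   \code{labels} (the post-filter label raster).  A blank raster gives
#'   a zero count, not an error.
#' @export
count_nuclei <- function(nuclei, pixel_size_um = 1, sigma = 2,
                         threshold = "otsu", watershed = TRUE,
                         size_range_um2 = c(10, 500)) {
  stopifnot(is.matrix(nuclei), pixel_size_um > 0, sigma >= 0,
            length(size_range_um2) == 2L,
            size_range_um2[1] <= size_range_um2[2])
  area_mm2 <- prod(dim(nuclei)) * pixel_size_um^2 / 1e6
  empty <- list(n_cells = 0L,
                centroids = matrix(numeric(), 0L, 2L,
                                   dimnames = list(NULL, c("x_um", "y_um"))),
                density_per_mm2 = 0,
                labels = matrix(0L, nrow(nuclei), ncol(nuclei)))
  class(empty) <- "count_result"
  if (!any(nuclei > 0)) return(empty)

  img <- EBImage::Image(nuclei)
  sm <- if (sigma > 0) EBImage::gblur(img, sigma = sigma) else img
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(sm, range = c(0, max(1, max(sm))))
  } else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  bw <- sm > thr
  if (!any(bw)) return(empty)
  bw <- EBImage::fillHull(bw)
  lab <- if (watershed) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- as.matrix(lab)

  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * pixel_size_um^2 >= size_range_um2[1] &
                sizes * pixel_size_um^2 <= size_range_um2[2])
  if (length(keep) == 0L) return(empty)

  px <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[px]
  inkeep <- ids %in% keep
  px <- px[inkeep, , drop = FALSE]
  ids <- ids[inkeep]
  cen_x <- tapply(px[, 1], ids, mean) * pixel_size_um
  cen_y <- tapply(px[, 2], ids, mean) * pixel_size_um
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  out_lab[px] <- match(ids, keep)

  res <- list(
    n_cells = length(keep),
    centroids = cbind(x_um = as.numeric(cen_x), y_um = as.numeric(cen_y)),
    density_per_mm2 = length(keep) / area_mm2,
    labels = out_lab
  )
  class(res) <- "count_result"
  res
}

#' Assign nucleus centroids to cells and flag multinucleation
#'
#' Each centroid is assigned to the cell label of the raster pixel under
#' it; centroids falling on background are unassigned (with a warning).
#' The ROI-level flag is TRUE when any cell carries >= 2 nuclei.
#'
#' @param labels integer cell-label raster.
#' @param centroids matrix of centroids in micrometres
#'   (columns x_um, y_um), or a \code{count_result}.
#' @param pixel_size_um micrometres per pixel of \code{labels}.
#' @return list: \code{per_cell} data.frame (cell_id, n_nuclei),
#'   \code{multinucleated} logical ROI flag, \code{n_unassigned}.
#' @export
nuclei_per_cell <- function(labels, centroids, pixel_size_um = 1) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  if (inherits(centroids, "count_result")) {
    if (!is.null(centroids$labels) &&
        !identical(dim(centroids$labels), dim(labels))) {
      stop("label raster and nuclei raster have different shapes: ",
           paste(dim(labels), collapse = "x"), " vs ",
           paste(dim(centroids$labels), collapse = "x"), call. = FALSE)
    }
    centroids <- centroids$centroids
  }
  ids <- sort(unique(labels[labels > 0L]))
  counts <- stats::setNames(integer(length(ids)), ids)
  unassigned <- 0L
  if (nrow(centroids) > 0L) {
    r <- clamp(round(centroids[, 1] / pixel_size_um), 1L, nrow(labels))
    c <- clamp(round(centroids[, 2] / pixel_size_um), 1L, ncol(labels))
    hit <- labels[cbind(r, c)]
    unassigned <- sum(hit == 0L)
    if (unassigned > 0L) {
      warning(unassigned, " centroid(s) fell on background and were not ",
              "assigned to any cell", call. = FALSE)
    }
    tb <- table(hit[hit > 0L])
    counts[names(tb)] <- as.integer(tb)
  }
  list(
    per_cell = data.frame(cell_id = as.integer(ids),
                          n_nuclei = as.integer(counts)),
    multinucleated = any(counts >= 2L),
    n_unassigned = unassigned
  )
}
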