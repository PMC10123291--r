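# Reading and writing the on-disk formats: 16-bit TIFF label/nuclei
# rasters, JSON ground truth, CSV plate tables.

#' Write a synthetic ROI to disk
#'
#' Writes \code{labels.tif} (16-bit label raster), \code{nuclei.tif} and
#' \code{intensity.tif} (16-bit, intensities scaled from [0, 1]) plus
#' \code{truth.json} (ground truth and pixel size).  Requires the
#' \pkg{tiff} package.
#'
#' @param roi \code{roi_image} from \code{\link{generate_roi}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_roi <- function(roi, dir) {
  stopifnot(inherits(roi, "roi_image"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF rasters",
         call. = FALSE)
  }
  if (max(roi$labels) > 65535L) {
    stop("more than 65535 labels cannot be stored in 16-bit TIFF",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(roi$labels / 65535, file.path(dir, "labels.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(clamp(roi$nuclei, 0, 1), file.path(dir, "nuclei.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(clamp(roi$intensity, 0, 1),
                  file.path(dir, "intensity.tif"), bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = roi$pixel_size_um,
         roi_area_um2 = roi$roi_area_um2,
         truth = roi$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an ROI written by \code{\link{write_roi}}
#'
#' @param dir directory holding \code{labels.tif}, \code{nuclei.tif},
#'   \code{intensity.tif} and \code{truth.json}.
#' @return \code{roi_image} object.
#' @export
read_roi <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF rasters",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  labels <- round(tiff::readTIFF(file.path(dir, "labels.tif")) * 65535)
  storage.mode(labels) <- "integer"
  nuclei <- tiff::readTIFF(file.path(dir, "nuclei.tif"))
  intensity <- tiff::readTIFF(file.path(dir, "intensity.tif"))
  structure(list(labels = labels, nuclei = nuclei, intensity = intensity,
                 pixel_size_um = meta$pixel_size_um,
                 roi_area_um2 = meta$roi_area_um2,
                 truth = as.data.frame(meta$truth)),
            class = "roi_image")
}

#' Write a simulated plate to CSV
#'
#' @param plate \code{plate_data} from
#'   \code{\link{generate_cytokine_experiment}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(plate$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE)
  utils::write.csv(plate$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(plate$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a plate written by \code{\link{write_plate}}
#'
#' @param dir directory holding the three CSV tables.
#' @return \code{plate_data} object.
#' @export
read_plate <- function(dir) {
  out <- list(
    standards = utils::read.csv(file.path(dir, "standards.csv")),
    samples = utils::read.csv(file.path(dir, "samples.csv")),
    truth = utils::read.csv(file.path(dir, "truth.csv")))
  class(out) <- "plate_data"
  out
}
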