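# Synthetic single-cell and ROI image generator.
#
# Shape grammar: the soma is a noisy ellipse (radius modulated by a few
# random Fourier harmonics); processes are tapered, straight protrusions
# anchored inside the soma at jittered angular positions.  This is the
# minimal model that reproduces the three morphotypes: a round/amoeboid
# cell is a mildly noisy disk, a polarized cell is an elongated rod
# (length-to-width ratio >= 3, processes only at the poles), a ramified
# cell is a compact soma with >= 3 long thin processes.

#' Shape parameters for one synthetic cell
#'
#' Defaults per morphotype (sizes in um, chosen as realistic for cultured
#' murine microglia; the taxonomy constraints are enforced):
#' round/amoeboid: soma radius 12, no processes, elongation <= 1.3;
#' polarized: soma radius 9, elongation >= 3, 2 polar processes;
#' ramified: soma radius 7, 5 processes of length ~22 um.
#'
#' @param morphotype one of \code{morphotype_levels()}.
#' @param soma_radius_um equivalent soma radius (> 0).
#' @param n_processes number of processes (>= 0; >= 3 for ramified).
#' @param process_length_um mean process length.
#' @param process_width_um process base width.
#' @param elongation soma axis ratio (>= 1; >= 3 for polarized).
#' @param boundary_noise relative amplitude of the soma boundary
#'   modulation (>= 0).
#' @return list of class \code{shape_params}.
#' @export
shape_params <- function(morphotype = "round_amoeboid",
                         soma_radius_um = NULL,
                         n_processes = NULL,
                         process_length_um = NULL,
                         process_width_um = NULL,
                         elongation = NULL,
                         boundary_noise = 0.06) {
  morphotype <- match.arg(morphotype, MORPHOTYPES)
  defaults <- switch(morphotype,
    round_amoeboid = list(soma = 12, nproc = 0L, plen = 0, pwid = 0,
                          elong = 1.15),
    polarized = list(soma = 9, nproc = 2L, plen = 10, pwid = 4,
                     elong = 3.5),
    ramified = list(soma = 7, nproc = 5L, plen = 22, pwid = 4.5,
                    elong = 1.2))
  p <- list(
    morphotype = morphotype,
    soma_radius_um = soma_radius_um %||% defaults$soma,
    n_processes = as.integer(n_processes %||% defaults$nproc),
    process_length_um = process_length_um %||% defaults$plen,
    process_width_um = process_width_um %||% defaults$pwid,
    elongation = elongation %||% defaults$elong,
    boundary_noise = boundary_noise
  )
  if (p$soma_radius_um <= 0) stop("soma_radius_um must be > 0", call. = FALSE)
  if (p$n_processes < 0L) stop("n_processes must be >= 0", call. = FALSE)
  if (p$elongation < 1) stop("elongation must be >= 1", call. = FALSE)
  if (p$boundary_noise < 0) stop("boundary_noise must be >= 0", call. = FALSE)
  if (morphotype == "round_amoeboid" && p$n_processes != 0L)
    stop("round/amoeboid cells have no processes", call. = FALSE)
  if (morphotype == "polarized" && p$elongation < 3)
    stop("polarized cells require elongation >= 3", call. = FALSE)
  if (morphotype == "ramified" && p$n_processes < 3L)
    stop("ramified cells require >= 3 processes", call. = FALSE)
  class(p) <- "shape_params"
  p
}

# Render a tapered straight process into a logical grid (TRUE where the
# distance to the segment is below the local half width, linearly tapered
# from base to 30% at the tip).
.render_process <- function(mask, x0, y0, theta, len, width) {
  x1 <- x0 + len * cos(theta)
  y1 <- y0 + len * sin(theta)
  half <- width / 2
  r1 <- max(1L, floor(min(x0, x1) - half - 1)); r2 <- min(nrow(mask), ceiling(max(x0, x1) + half + 1))
  c1 <- max(1L, floor(min(y0, y1) - half - 1)); c2 <- min(ncol(mask), ceiling(max(y0, y1) + half + 1))
  if (r1 > r2 || c1 > c2) return(mask)
  xs <- r1:r2; ys <- c1:c2
  gx <- matrix(xs, length(xs), length(ys))
  gy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  t <- ((gx - x0) * vx + (gy - y0) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  dx <- gx - (x0 + t * vx); dy <- gy - (y0 + t * vy)
  d2 <- dx * dx + dy * dy
  wloc <- half * (1 - 0.7 * t)
  mask[r1:r2, c1:c2] <- mask[r1:r2, c1:c2] | (d2 <= wloc * wloc)
  mask
}

#' Generate one synthetic cell mask
#'
#' Pure function of (params, seed): identical inputs give bit-identical
#' masks.  The mask is rendered on a raster just large enough to contain
#' the cell (or \code{raster_px} if supplied).
#'
#' @param params \code{\link{shape_params}} object.
#' @param seed integer seed.
#' @param pixel_size_um micrometres per pixel.
#' @param raster_px optional c(rows, cols) raster size; an error is raised
#'   if the requested shape cannot fit.
#' @return list of class \code{synthetic_cell}: \code{mask} (logical
#'   matrix), \code{truth} (morphotype, n_processes, soma radius and
#'   centre in pixels).
#' @export
generate_cell_shape <- function(params, seed, pixel_size_um = 1,
                                raster_px = NULL) {
  stopifnot(inherits(params, "shape_params"), pixel_size_um > 0)
  u <- pixel_size_um
  soma_r <- params$soma_radius_um / u
  plen <- params$process_length_um / u
  pwid <- params$process_width_um / u
  a <- soma_r * sqrt(params$elongation)   # major semi-axis, area-preserving
  b <- soma_r / sqrt(params$elongation)
  extent <- (a * (1 + 2.5 * params$boundary_noise) +
             (if (params$n_processes > 0L) plen * 1.25 + pwid else 0)) + 3
  need <- 2L * ceiling(extent) + 3L
  if (is.null(raster_px)) raster_px <- c(need, need)
  if (any(raster_px < need)) {
    stop("raster ", paste(raster_px, collapse = "x"),
         " too small for requested shape (needs >= ", need, ")",
         call. = FALSE)
  }
  with_seed(seed, {
    cx <- (raster_px[1] + 1) / 2
    cy <- (raster_px[2] + 1) / 2
    phi0 <- stats::runif(1, 0, pi)
    # smooth angular boundary modulation from 4 random harmonics
    nh <- 4L
    amp <- stats::rnorm(nh, 0, 1) * params$boundary_noise / sqrt(nh)
    pha <- stats::runif(nh, 0, 2 * pi)

    # soma computed only inside its bounding box (cheaper than full grid)
    smax <- a * (1 + 2.5 * params$boundary_noise) + 1
    r1 <- max(1L, floor(cx - smax)); r2 <- min(raster_px[1], ceiling(cx + smax))
    c1 <- max(1L, floor(cy - smax)); c2 <- min(raster_px[2], ceiling(cy + smax))
    xs <- r1:r2; ys <- c1:c2
    gx <- matrix(xs - cx, length(xs), length(ys))
    gy <- matrix(ys - cy, length(xs), length(ys), byrow = TRUE)
    # rotate into soma frame
    rx <- gx * cos(phi0) + gy * sin(phi0)
    ry <- -gx * sin(phi0) + gy * cos(phi0)
    r <- sqrt(rx * rx + ry * ry)
    th <- atan2(ry, rx)
    rell <- (a * b) / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    mod <- 1
    for (h in seq_len(nh)) mod <- mod + amp[h] * cos((h + 1) * th + pha[h])
    mask <- matrix(FALSE, raster_px[1], raster_px[2])
    mask[r1:r2, c1:c2] <- r <= rell * pmax(mod, 0.55)

    np <- params$n_processes
    if (np > 0L) {
      if (params$morphotype == "polarized") {
        # polar placement (in soma frame angles 0 and pi), small jitter
        base_th <- rep(c(0, pi), length.out = np)
        jit <- stats::runif(np, -0.25, 0.25)
      } else {
        base_th <- (seq_len(np) - 1) * 2 * pi / np + stats::runif(1, 0, 2 * pi)
        jit <- stats::runif(np, -0.3, 0.3) * pi / np
      }
      th_p <- base_th + jit
      lens <- plen * stats::runif(np, 0.85, 1.15)
      for (i in seq_len(np)) {
        # anchor well inside the soma (boundary modulation never dips
        # below 0.55 * the unmodulated radius) so processes stay attached
        rb <- (a * b) / sqrt((b * cos(th_p[i]))^2 + (a * sin(th_p[i]))^2)
        ax <- 0.5 * rb * cos(th_p[i]); ay <- 0.5 * rb * sin(th_p[i])
        # back to raster frame
        wx <- cx + ax * cos(phi0) - ay * sin(phi0)
        wy <- cy + ax * sin(phi0) + ay * cos(phi0)
        wth <- th_p[i] + phi0
        mask <- .render_process(mask, wx, wy, wth,
                                lens[i] + 0.5 * rb, pwid)
      }
    }
    # boundary modulation can leave stray isolated pixels; the generator
    # contract is a single connected mask, so keep the largest component
    lab <- EBImage::bwlabel(mask * 1)
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0L])
      mask <- lab == which.max(sizes)
    }
    structure(list(
      mask = mask,
      truth = list(morphotype = params$morphotype,
                   n_processes = params$n_processes,
                   soma_radius_px = soma_r,
                   center_px = c(cx, cy)),
      pixel_size_um = u
    ), class = "synthetic_cell")
  })
}

#' Sample morphotype labels from a mixture
#'
#' @param mixture numeric length-3 vector of proportions
#'   (round/amoeboid, polarized, ramified); must sum to 1.
#' @param n number of cells.
#' @param seed integer seed.
#' @return character vector of labels.
#' @export
sample_morphotypes <- function(mixture, n, seed) {
  stopifnot(length(mixture) == 3L, all(mixture >= 0),
            abs(sum(mixture) - 1) < 1e-8, n >= 0)
  if (n == 0L) return(character(0))
  with_seed(seed, sample(MORPHOTYPES, n, replace = TRUE, prob = mixture))
}

#' Generate a synthetic ROI image with ground truth
#'
#' Places \code{n_cells} non-overlapping synthetic cells (morphotypes
#' drawn from \code{mixture}) into a label raster, adds one nucleus blob
#' per cell at the soma centre (a configurable fraction of ROIs carries
#' one binucleated cell), and renders an intensity raster with per-cell
#' lognormal brightness.  Default raster 1000 x 1000 px at 1 um/px
#' (~1 mm^2 field).
#'
#' @param mixture morphotype proportions (round, polarized, ramified).
#' @param n_cells number of cells (>= 0).
#' @param seed integer seed.
#' @param pixel_size_um micrometres per pixel.
#' @param roi_px c(rows, cols) raster size.
#' @param multinucleated_prob probability that the ROI contains one
#'   binucleated cell (default 0.05).
#' @param size_scale multiplies all per-morphotype default sizes.
#' @param max_tries placement retries per cell before a placement error.
#' @return object of class \code{roi_image}: \code{labels} (integer
#'   matrix), \code{nuclei} (numeric matrix in [0, 1]), \code{intensity},
#'   \code{pixel_size_um}, \code{roi_area_um2} and a \code{truth}
#'   data.frame (cell_id, morphotype, n_processes, n_nuclei, centre).
#' @export
generate_roi <- function(mixture, n_cells, seed, pixel_size_um = 1,
                         roi_px = c(1000L, 1000L),
                         multinucleated_prob = 0.05,
                         size_scale = 1, max_tries = 200L) {
  stopifnot(n_cells >= 0, pixel_size_um > 0, length(roi_px) == 2L)
  labels <- matrix(0L, roi_px[1], roi_px[2])
  nuclei <- matrix(0, roi_px[1], roi_px[2])
  intensity <- matrix(0, roi_px[1], roi_px[2])
  roi_area_um2 <- prod(roi_px) * pixel_size_um^2
  truth <- data.frame(cell_id = integer(), morphotype = character(),
                      n_processes = integer(), n_nuclei = integer(),
                      center_x_um = numeric(), center_y_um = numeric(),
                      stringsAsFactors = FALSE)
  obj <- structure(list(labels = labels, nuclei = nuclei,
                        intensity = intensity,
                        pixel_size_um = pixel_size_um,
                        roi_area_um2 = roi_area_um2, truth = truth),
                   class = "roi_image")
  if (n_cells == 0L) return(obj)

  types <- sample_morphotypes(mixture, n_cells, seed)
  multi_cell <- with_seed(child_seed(seed, 777L), {
    if (stats::runif(1) < multinucleated_prob) sample.int(n_cells, 1L) else 0L
  })

  # per-cell randomness is drawn in small self-contained blocks so the
  # large rasters are only ever mutated at reference count 1 (in place)
  nuc_centers <- list()
  truth_rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    p <- shape_params(types[i])
    p$soma_radius_um <- p$soma_radius_um * size_scale
    p$process_length_um <- p$process_length_um * size_scale
    cell <- generate_cell_shape(p, seed = child_seed(seed, i),
                                pixel_size_um = pixel_size_um)
    cm <- cell$mask
    h <- nrow(cm); w <- ncol(cm)
    if (h > roi_px[1] || w > roi_px[2]) {
      stop("ROI raster too small for generated cell", call. = FALSE)
    }
    draw <- with_seed(child_seed(seed, 100000L + i), list(
      r0 = sample.int(roi_px[1] - h + 1L, max_tries, replace = TRUE),
      c0 = sample.int(roi_px[2] - w + 1L, max_tries, replace = TRUE),
      bright = stats::rlnorm(1, log(0.7), 0.2),
      nuc_ang = stats::runif(1, 0, 2 * pi)))
    idx0 <- which(cm, arr.ind = TRUE)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- draw$r0[try]; c0 <- draw$c0[try]
      cand <- cbind(idx0[, 1] + r0 - 1L, idx0[, 2] + c0 - 1L)
      if (!any(labels[cand] != 0L)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not place cell ", i, " without overlap after ",
           max_tries, " tries; reduce n_cells or enlarge roi_px",
           call. = FALSE)
    }
    labels[cand] <- i
    intensity[cand] <- min(draw$bright, 1)
    ctr <- c(cell$truth$center_px[1] + r0 - 1,
             cell$truth$center_px[2] + c0 - 1)
    n_nuc <- if (i == multi_cell) 2L else 1L
    rad <- max(2.5, 0.45 * cell$truth$soma_radius_px)
    nuc_centers[[i]] <- if (n_nuc == 1L) {
      cbind(ctr[1], ctr[2], rad)
    } else {
      off <- rad * 1.15
      dd <- c(cos(draw$nuc_ang), sin(draw$nuc_ang))
      rbind(c(ctr + off * dd, rad), c(ctr - off * dd, rad))
    }
    truth_rows[[i]] <- c(p$n_processes, n_nuc, ctr[1] * pixel_size_um,
                         ctr[2] * pixel_size_um)
  }
  nuclei <- .render_nuclei(nuclei, do.call(rbind, nuc_centers))
  obj$labels <- labels
  obj$nuclei <- nuclei
  obj$intensity <- intensity
  tm <- do.call(rbind, truth_rows)
  obj$truth <- data.frame(cell_id = seq_len(n_cells), morphotype = types,
                          n_processes = as.integer(tm[, 1]),
                          n_nuclei = as.integer(tm[, 2]),
                          center_x_um = tm[, 3], center_y_um = tm[, 4],
                          stringsAsFactors = FALSE)
  obj
}

# Render nucleus blobs (rows of `centers`: x, y, radius) into the nuclei
# raster in one pass.  Blobs are radial-falloff disks (peak ~0.9) so a
# watershed on the blurred image can separate touching nuclei.
.render_nuclei <- function(nuclei, centers) {
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  for (j in seq_len(nrow(centers))) {
    x0 <- centers[j, 1]; y0 <- centers[j, 2]; rad <- centers[j, 3]
    r1 <- max(1L, floor(x0 - rad - 1)); r2 <- min(nr, ceiling(x0 + rad + 1))
    c1 <- max(1L, floor(y0 - rad - 1)); c2 <- min(nc, ceiling(y0 + rad + 1))
    xs <- r1:r2; ys <- c1:c2
    gx <- matrix(xs, length(xs), length(ys))
    gy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
    d <- sqrt((gx - x0)^2 + (gy - y0)^2)
    blob <- pmax(0, 0.9 * (1 - (d / rad)^2))
    nuclei[r1:r2, c1:c2] <- pmax(nuclei[r1:r2, c1:c2], blob)
  }
  nuclei
}
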