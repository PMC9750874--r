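#' Chromogenic image processing
#'
#' Converts registered chromogenic rounds into a single-cell feature table:
#' hematoxylin stain separation, AEC extraction through the CMYK yellow
#' channel, watershed nuclear segmentation, per-cell mean intensities in a
#' well-centered frame, and binary coverage statistics.
#'
#' Images are numeric arrays: `H x W x 3` RGB in `[0, 1]` (or 8-/16-bit
#' integer ranges, normalised on entry), single channels as `H x W`
#' matrices with rows running down the image.
#'
#' @name imaging
NULL

normalise_rgb <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  mx <- max(image)
  if (mx > 1) image <- image / if (mx > 255) 65535 else 255
  image
}

#' Ruifrok-Johnston stain vectors
#'
#' Unit optical-density absorption vectors (rows) for hematoxylin, eosin
#' and a DAB-like residual, the standard basis for chromogenic color
#' deconvolution.
#'
#' @return 3 x 3 matrix with rows `hematoxylin`, `eosin`, `residual`.
#' @export
default_stain_matrix <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.072, 0.990, 0.105),
             residual    = c(0.268, 0.570, 0.776))
  sweep(m, 1, sqrt(rowSums(m^2)), "/")
}

#' Color-deconvolve an RGB image into stain optical densities
#'
#' Per-pixel optical density `OD = -log10(I)` is projected onto the stain
#' basis by inverting the stain matrix (Ruifrok-Johnston convention).
#'
#' @param image RGB array.
#' @param stain_matrix 3 x 3 matrix of unit stain OD vectors (rows).
#' @return `H x W x 3` array of stain concentrations (OD units), dimnames
#'   carrying the stain names.
#' @export
deconvolve_stains <- function(image, stain_matrix = default_stain_matrix()) {
  image <- normalise_rgb(image)
  inv <- tryCatch(solve(stain_matrix),
                  error = function(e) stop("singular stain matrix"))
  eps <- 1e-6
  od <- -log10(pmax(image, eps))
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% inv
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stain_matrix))
  out
}

#' Extract the hematoxylin optical-density channel
#'
#' @param image RGB array of a hematoxylin-stained round.
#' @param stain_matrix Stain basis; hematoxylin must be the first row.
#' @return `H x W` matrix of hematoxylin OD.
#' @export
separate_hematoxylin <- function(image, stain_matrix = default_stain_matrix()) {
  deconvolve_stains(image, stain_matrix)[, , 1L]
}

#' Extract AEC signal as the CMYK yellow channel
#'
#' The red-brown AEC chromogen is separated into the yellow channel of the
#' RGB-to-CMYK transform, which improves sensitivity over red-channel
#' readouts: per pixel, `K = 1 - max(r, g, b)` and
#' `Y = (1 - b - K) / (1 - K)` (0 where `K = 1`). A total function; gray
#' pixels map to 0 and output is always within `[0, 1]`.
#'
#' @param image RGB array (range `[0, 1]` or integer 8-/16-bit).
#' @return `H x W` matrix of yellow intensities in `[0, 1]`.
#' @export
extract_aec_yellow <- function(image) {
  image <- normalise_rgb(image)
  d <- dim(image)[1:2]
  r <- as.vector(image[, , 1L])
  g <- as.vector(image[, , 2L])
  b <- as.vector(image[, , 3L])
  k <- 1 - pmax(r, g, b)
  y <- numeric(length(k))
  ok <- k < 1
  y[ok] <- (1 - b[ok] - k[ok]) / (1 - k[ok])
  matrix(pmin(pmax(y, 0), 1), d[1], d[2])
}

#' Segment nuclei from a hematoxylin OD channel
#'
#' Threshold (Otsu by default), morphological noise removal (opening, i.e.
#' erosion then dilation), then a seeded watershed to split touching
#' nuclei: seeds are local maxima of the Gaussian-smoothed in-mask
#' intensity with a configurable minimum separation (intensity maxima
#' resolve nucleus pairs whose merged binary footprint has only a single
#' distance-transform ridge), and labels grow from the seeds over the
#' foreground by intensity-guided propagation. Objects under `min_area`
#' are removed and labels renumbered 1..n in raster order, so the result
#' is deterministic.
#'
#' @param od_channel `H x W` matrix (hematoxylin OD or any nuclear signal).
#' @param threshold Numeric threshold, or `NULL` for Otsu on the channel.
#' @param min_area Minimum object area (px).
#' @param opening_radius Radius (px) of the opening brush; 0 disables.
#' @param seed_separation Minimum seed separation (px): the radius of the
#'   window within which only the strongest intensity maximum seeds a
#'   nucleus.
#' @param pixel_size_um Pixel scale used to report centroids in um.
#' @return An object of class `nuclear_mask`: list with `labels` (integer
#'   matrix), `centroids` (n x 2 matrix, image um: x right, y up from the
#'   bottom edge), `n`, and `pixel_size_um`.
#' @export
segment_nuclei <- function(od_channel, threshold = NULL, min_area = 8L,
                           opening_radius = 1L, seed_separation = 3L,
                           pixel_size_um = 1) {
  od <- as.matrix(od_channel)
  if (all(!is.finite(od)) || max(od) <= min(od)) {
    return(new_nuclear_mask(matrix(0L, nrow(od), ncol(od)), pixel_size_um))
  }
  if (is.null(threshold))
    threshold <- otsu_threshold(od, range = range(od))
  bw <- od > threshold
  if (!any(bw))
    return(new_nuclear_mask(matrix(0L, nrow(od), ncol(od)), pixel_size_um))
  # EBImage works x-by-y; transpose in and out
  img <- EBImage::Image(t(bw) * 1)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    img <- EBImage::opening(img, brush)
  }
  odi <- EBImage::Image(t(od))
  height <- EBImage::gblur(odi, sigma = 1) * img
  win <- EBImage::makeBrush(2L * as.integer(seed_separation) + 1L,
                            shape = "disc")
  seeds <- (height >= EBImage::dilate(height, win) - 1e-9) & (img > 0)
  seeds <- EBImage::bwlabel(EBImage::Image(seeds * 1))
  ws <- EBImage::propagate(odi, seeds = seeds, mask = img > 0)
  labels <- t(EBImage::imageData(ws))
  storage.mode(labels) <- "integer"
  # drop undersized objects, relabel contiguously in raster order
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  ord <- unique(as.vector(labels))
  ord <- ord[ord > 0L]
  ord <- ord[ord %in% keep]
  remap[ord] <- seq_along(ord)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  new_nuclear_mask(labels, pixel_size_um)
}

new_nuclear_mask <- function(labels, pixel_size_um) {
  n <- max(labels, 0L)
  centroids <- matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("x_um", "y_um")))
  if (n > 0L) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    row <- (idx - 1L) %% nrow(labels) + 1L
    col <- (idx - 1L) %/% nrow(labels) + 1L
    cx <- tapply(col, lab, mean)
    cy <- tapply(row, lab, mean)
    centroids <- cbind(x_um = (as.numeric(cx) - 0.5) * pixel_size_um,
                       y_um = (nrow(labels) - as.numeric(cy) + 0.5) * pixel_size_um)
  }
  structure(list(labels = labels, centroids = centroids, n = n,
                 pixel_size_um = pixel_size_um),
            class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("Nuclear mask: %d cells over %d x %d px (%.2f um/px)\n",
              x$n, nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  invisible(x)
}

channel_scale <- function(channel, bit_depth = NULL) {
  if (!is.null(bit_depth)) return(2^bit_depth - 1)
  if (is.integer(channel) || max(channel, na.rm = TRUE) > 1)
    return(if (max(channel, na.rm = TRUE) > 255) 65535 else 255)
  1
}

#' Measure per-cell mean intensities
#'
#' One row per mask label: the centroid transformed into the well frame and,
#' per channel, the mean pixel intensity over the label's footprint scaled
#' to `[0, 1]` by the channel's fixed dtype maximum (255 for 8-bit, 65535
#' for 16-bit; never per-image min-max, so values are comparable across
#' images for gating).
#'
#' @param mask A [segment_nuclei()] result.
#' @param channels Named list of `H x W` intensity matrices.
#' @param frame Optional [well_frame()] (um, image coordinates: x right,
#'   y up); when given, centroids are reported in the well frame.
#' @param bit_depth Optional integer forcing the dtype scale of all
#'   channels.
#' @return Cell table: `cell_id`, `x_um`, `y_um`, one column per channel.
#' @export
measure_cells <- function(mask, channels, frame = NULL, bit_depth = NULL) {
  stopifnot(inherits(mask, "nuclear_mask"))
  labels <- mask$labels
  out <- data.frame(cell_id = seq_len(mask$n),
                    x_um = mask$centroids[, 1],
                    y_um = mask$centroids[, 2])
  if (!is.null(frame)) out <- to_well_frame(out, frame)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(dim(ch) == dim(labels)))
      stop("channel '", nm, "' dimensions do not match the mask")
    scale <- channel_scale(ch, bit_depth)
    means <- tapply(as.numeric(ch[idx]) / scale, lab, mean)
    out[[nm]] <- as.numeric(means[as.character(out$cell_id)])
  }
  out
}

#' Fraction of a region covered by supra-threshold signal
#'
#' Binarises the channel at `threshold` and returns the mean of the binary
#' pixels inside the region — the "binary coverage" readout used for
#' death-marker (for example CC3) quantification in the assay region. The
#' binarisation threshold is a required, assay-specific parameter.
#'
#' @param signal `H x W` intensity matrix.
#' @param region Logical matrix of the same dimensions, or a k x 2 polygon
#'   in pixel coordinates (col, row).
#' @param threshold Binarisation threshold (strictly-greater convention).
#' @return Coverage fraction in `[0, 1]`.
#' @export
binary_coverage <- function(signal, region, threshold) {
  signal <- as.matrix(signal)
  if (is.matrix(region) && !is.logical(region) && ncol(region) == 2L) {
    cc <- col(signal); rr <- row(signal)
    region <- matrix(point_in_polygon(as.vector(cc), as.vector(rr),
                                      region[, 1], region[, 2]),
                     nrow(signal), ncol(signal))
  }
  if (!is.logical(region) || !all(dim(region) == dim(signal)))
    stop("region must be a logical mask matching the signal, or a polygon")
  if (!any(region)) stop("empty region: no pixels to quantify")
  mean(signal[region] > threshold)
}
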