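#' Rendering parameters for synthetic chromogenic images
#'
#' @param pixel_size_um Pixel scale (um/px).
#' @param nucleus_radius_um Rendered nuclear radius (um).
#' @param hematoxylin_od Peak nuclear optical density in the hematoxylin
#'   round.
#' @param aec_od Peak AEC optical density for a marker intensity of 1.
#' @param noise_sd Gaussian pixel noise added to each RGB channel.
#' @param margin_um Blank margin added around the arena so that cells at
#'   the arena edge render (and segment) completely.
#' @return A list of parameters.
#' @export
render_params <- function(pixel_size_um = 2, nucleus_radius_um = 4,
                          hematoxylin_od = 0.9, aec_od = 1.0,
                          noise_sd = 0, margin_um = 3 * nucleus_radius_um) {
  stopifnot(pixel_size_um > 0, nucleus_radius_um > 0, margin_um >= 0)
  list(pixel_size_um = pixel_size_um, nucleus_radius_um = nucleus_radius_um,
       hematoxylin_od = hematoxylin_od, aec_od = aec_od, noise_sd = noise_sd,
       margin_um = margin_um)
}

# AEC is a red-brown chromogen: absorbs green/blue, transmits red.
aec_od_vector <- function() {
  v <- c(0.15, 0.70, 0.70)
  v / sqrt(sum(v^2))
}

# Accumulate per-cell Gaussian optical-density blobs into an OD map.
# Returns the od matrix (rows = y from top) for the given per-cell peak ODs.
splat_od <- function(centers_px, od_peak, dims, sigma_px, cut = 2.5) {
  od <- matrix(0, dims[1], dims[2])
  r <- ceiling(cut * sigma_px * 1.5)
  for (i in seq_len(nrow(centers_px))) {
    if (od_peak[i] <= 0) next
    r0 <- centers_px[i, 1]; c0 <- centers_px[i, 2]
    rows <- max(1L, floor(r0 - r)):min(dims[1], ceiling(r0 + r))
    cols <- max(1L, floor(c0 - r)):min(dims[2], ceiling(c0 + r))
    if (!length(rows) || !length(cols)) next
    dr <- outer(rows - r0, rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols - c0)
    od[rows, cols] <- od[rows, cols] +
      od_peak[i] * exp(-(dr^2 + dc^2) / (2 * sigma_px^2))
  }
  od
}

od_to_rgb <- function(od, stain_vec, noise_sd = 0) {
  rgb <- array(0, dim = c(nrow(od), ncol(od), 3L))
  for (k in 1:3) rgb[, , k] <- 10^(-od * stain_vec[k])
  if (noise_sd > 0)
    rgb <- rgb + stats::rnorm(length(rgb), 0, noise_sd)
  pmin(pmax(rgb, 0), 1)
}

#' Render a synthetic scene as chromogenic image rounds
#'
#' Produces a hematoxylin-stained nuclear round, one AEC round per requested
#' marker (each cell tinted red-brown in proportion to its marker
#' intensity), and a ground-truth label mask whose labels match the scene's
#' `cell_id`s row for row. Nuclei are Gaussian optical-density blobs
#' converted to RGB transmittance through the stain's absorption vector
#' (Beer-Lambert), so the rendered images invert exactly under
#' [separate_hematoxylin()].
#'
#' Image rows run from the arena's y maximum downwards (standard image
#' orientation); [measure_cells()] undoes this when reporting micrometer
#' coordinates.
#'
#' @param scene An `imd_scene` from [generate_scene()].
#' @param markers Markers to render as AEC rounds (default: none).
#' @param params [render_params()].
#' @return List with `hematoxylin` (H x W x 3 RGB array in `[0, 1]`), `aec`
#'   (named list of RGB arrays), `mask` (integer label matrix; 0 =
#'   background, labels = `cell_id`), `overlapping` (cell ids whose nuclear
#'   discs touch another cell's disc), `params` and `bbox_um` (the um
#'   extent of the image, arena plus margin; the image's lower-left pixel
#'   corner sits at `(bbox_um[1], bbox_um[3])`).
#' @export
render_chromogenic <- function(scene, markers = character(0),
                               params = render_params()) {
  stopifnot(inherits(scene, "imd_scene"))
  a <- scene$config$arena + c(-1, 1, -1, 1) * params$margin_um
  px <- params$pixel_size_um
  dims <- c(ceiling((a[4] - a[3]) / px), ceiling((a[2] - a[1]) / px))
  cells <- scene$cells
  # um -> pixel (row from top, col from left), cell centers at pixel centers
  rows <- (a[4] - cells$y_um) / px + 0.5
  cols <- (cells$x_um - a[1]) / px + 0.5
  centers <- cbind(rows, cols)
  sigma_px <- params$nucleus_radius_um / (1.5 * px)

  n <- nrow(cells)
  hema_od <- splat_od(centers, rep(params$hematoxylin_od, n), dims, sigma_px)
  hematoxylin <- od_to_rgb(hema_od, default_stain_matrix()[1, ],
                           params$noise_sd)

  aec <- lapply(markers, function(m) {
    if (is.null(cells[[m]])) stop("marker column missing from scene: ", m)
    od <- splat_od(centers, params$aec_od * cells[[m]], dims, sigma_px)
    od_to_rgb(od, aec_od_vector(), params$noise_sd)
  })
  names(aec) <- markers

  # ground-truth mask: nuclear discs, nearest center wins on overlap
  mask <- matrix(0L, dims[1], dims[2])
  best <- matrix(Inf, dims[1], dims[2])
  r_px <- params$nucleus_radius_um / px
  overlap <- logical(n)
  for (i in seq_len(n)) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rows_i <- max(1L, floor(r0 - r_px)):min(dims[1], ceiling(r0 + r_px))
    cols_i <- max(1L, floor(c0 - r_px)):min(dims[2], ceiling(c0 + r_px))
    if (!length(rows_i) || !length(cols_i)) next
    dr <- outer(rows_i - r0, rep(1, length(cols_i)))
    dc <- outer(rep(1, length(rows_i)), cols_i - c0)
    d2 <- dr^2 + dc^2
    inside <- d2 <= r_px^2
    sub_mask <- mask[rows_i, cols_i, drop = FALSE]
    sub_best <- best[rows_i, cols_i, drop = FALSE]
    taken <- inside & sub_mask > 0L
    if (any(taken)) {
      overlap[i] <- TRUE
      overlap[unique(sub_mask[taken])] <- TRUE
    }
    win <- inside & d2 < sub_best
    sub_mask[win] <- cells$cell_id[i]
    sub_best[win] <- d2[win]
    mask[rows_i, cols_i] <- sub_mask
    best[rows_i, cols_i] <- sub_best
  }

  list(hematoxylin = hematoxylin, aec = aec, mask = mask,
       overlapping = cells$cell_id[overlap], params = params,
       bbox_um = a)
}

#' Write rendered rounds to TIFF files
#'
#' @param rendered Result of [render_chromogenic()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_rendered_rounds <- function(rendered, dir, prefix = "round") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0(prefix, "_hematoxylin.tiff"))
  EBImage::writeImage(EBImage::Image(aperm(rendered$hematoxylin, c(2, 1, 3)),
                                     colormode = "Color"), p, type = "tiff")
  paths <- c(paths, p)
  for (m in names(rendered$aec)) {
    pm <- file.path(dir, paste0(prefix, "_aec_", m, ".tiff"))
    EBImage::writeImage(EBImage::Image(aperm(rendered$aec[[m]], c(2, 1, 3)),
                                       colormode = "Color"), pm, type = "tiff")
    paths <- c(paths, pm)
  }
  pmask <- file.path(dir, paste0(prefix, "_mask.tiff"))
  EBImage::writeImage(EBImage::Image(t(rendered$mask) / 65535), pmask,
                      type = "tiff", bits.per.sample = 16L)
  paths <- c(paths, pmask)
  invisible(paths)
}
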