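#' Select the assay region around the well
#'
#' The assay region is the first `n_target` cells on the release side
#' (y > 0 in the well frame), taken nearest-first by Euclidean distance to
#' the well, after removing excluded (deformed/folded tissue) cells. The
#' published protocol analyses 3,000-5,000 cells per assay area; targets
#' outside that range are allowed but flagged with a warning.
#'
#' @param table Cell table with `x_um`/`y_um` (well frame, unless `frame`
#'   is supplied).
#' @param n_target Number of cells to select.
#' @param frame Optional [well_frame()] applied to the table first.
#' @param exclusion Optional logical vector (TRUE = excluded) or predicate
#'   `function(table)` returning one.
#' @return The selected subset, ordered nearest-first, with attributes
#'   `shortfall` (TRUE when fewer than `n_target` cells were available —
#'   also raised as a warning) and `max_distance_um`.
#' @export
select_assay_region <- function(table, n_target = 4000L, frame = NULL,
                                exclusion = NULL) {
  n_target <- as.integer(n_target)
  if (is.na(n_target) || n_target <= 0L) stop("n_target must be positive")
  if (n_target < 3000L || n_target > 5000L)
    warning("n_target outside the standard 3,000-5,000 cell assay window")
  if (!is.null(frame)) table <- to_well_frame(table, frame)
  if (is.function(exclusion)) exclusion <- exclusion(table)
  if (is.null(exclusion)) exclusion <- rep(FALSE, nrow(table))
  eligible <- table$y_um > 0 & !exclusion
  sub <- table[eligible, , drop = FALSE]
  d <- sqrt(sub$x_um^2 + sub$y_um^2)
  ord <- order(d)
  take <- head(ord, n_target)
  shortfall <- nrow(sub) < n_target
  if (shortfall)
    warning(sprintf("assay region shortfall: %d of %d requested cells available",
                    nrow(sub), n_target))
  out <- sub[take, , drop = FALSE]
  attr(out, "shortfall") <- shortfall
  attr(out, "max_distance_um") <- if (length(take)) max(d[take]) else NA_real_
  out
}

#' Select a distant matched control region
#'
#' A control region of `n_target` cells far from the drug source, taken
#' farthest-first by distance to the well (emulating the random distant
#' intratumoral control region of the protocol). Cells already used in an
#' assay selection can be excluded.
#'
#' @inheritParams select_assay_region
#' @param exclude_ids `cell_id`s to leave out (typically the assay region).
#' @return The selected subset with a `shortfall` attribute.
#' @export
select_control_region <- function(table, n_target = 4000L, frame = NULL,
                                  exclude_ids = NULL) {
  n_target <- as.integer(n_target)
  if (is.na(n_target) || n_target <= 0L) stop("n_target must be positive")
  if (!is.null(frame)) table <- to_well_frame(table, frame)
  if (!is.null(exclude_ids) && !is.null(table$cell_id))
    table <- table[!table$cell_id %in% exclude_ids, , drop = FALSE]
  d <- sqrt(table$x_um^2 + table$y_um^2)
  ord <- order(d, decreasing = TRUE)
  take <- head(ord, n_target)
  shortfall <- nrow(table) < n_target
  if (shortfall)
    warning(sprintf("control region shortfall: %d of %d requested cells available",
                    nrow(table), n_target))
  out <- table[take, , drop = FALSE]
  attr(out, "shortfall") <- shortfall
  out
}

#' Pair an assay region with its control
#'
#' A replicate of the paired design: one drug reservoir's assay region and
#' its distant control. The pair is valid for paired testing when the total
#' cell counts agree within `max_imbalance` (the protocol matches regions
#' to within 300 cells).
#'
#' @param assay,control Cell tables (typically labelled).
#' @param reservoir_id Replicate identifier.
#' @param max_imbalance Largest tolerated count difference.
#' @return Object of class `region_pair` with a `pairing_valid` flag.
#' @export
region_pair <- function(assay, control, reservoir_id = 1L,
                        max_imbalance = 300L) {
  structure(list(assay = assay, control = control,
                 reservoir_id = reservoir_id,
                 n_assay = nrow(assay), n_control = nrow(control),
                 pairing_valid = abs(nrow(assay) - nrow(control)) <= max_imbalance),
            class = "region_pair")
}

#' @export
print.region_pair <- function(x, ...) {
  cat(sprintf("Region pair (reservoir %s): %d assay vs %d control cells; pairing %s\n",
              as.character(x$reservoir_id), x$n_assay, x$n_control,
              if (x$pairing_valid) "valid" else "INVALID (> 300 cell imbalance)"))
  invisible(x)
}

#' Relative-abundance profile with distance from the well
#'
#' Per bin of distance from the well (restricted to the release side by
#' default), the relative abundance of each series — cells of a type (or
#' marker-positive cells) divided by all cells in the bin — followed by
#' Gaussian smoothing (sigma defaulting to one bin) and a centered moving
#' average (50 um or 100 um windows in the published analyses). The y axis
#' is the per-bin fraction; no per-series rescaling is applied afterwards.
#' Bins containing no cells are reported as `NA` gaps, not zeros.
#'
#' @param table Cell table in the well frame (or supply `frame`).
#' @param labels Factor/character vector of per-cell series membership
#'   (e.g. from [classify_cells()]), or the name of a column of `table`.
#' @param frame Optional [well_frame()].
#' @param bin_width Distance bin width (um).
#' @param max_distance Largest distance profiled; defaults to the 99th
#'   percentile of cell distances.
#' @param sigma Gaussian smoothing sigma (um); default one bin width.
#' @param window Moving-average window (um); a window of one bin is the
#'   identity.
#' @param release_side_only Keep cells with y > 0 only.
#' @return Object of class `profile_curve`: list with `distance_um` (bin
#'   centers), `raw` and `smooth` (bins x series matrices of fractions),
#'   `n_per_bin` and the smoothing parameters.
#' @export
profile_curve <- function(table, labels, frame = NULL, bin_width = 25,
                          max_distance = NULL, sigma = bin_width,
                          window = 50, release_side_only = TRUE) {
  if (!is.null(frame)) table <- to_well_frame(table, frame)
  if (is.character(labels) && length(labels) == 1L && labels %in% names(table))
    labels <- table[[labels]]
  labels <- as.factor(labels)
  if (length(labels) != nrow(table))
    stop("labels must have one entry per cell")
  keep <- if (release_side_only) table$y_um > 0 else rep(TRUE, nrow(table))
  d <- sqrt(table$x_um[keep]^2 + table$y_um[keep]^2)
  lab <- labels[keep]
  if (is.null(max_distance))
    max_distance <- stats::quantile(d, 0.99, names = FALSE)
  edges <- seq(0, max_distance, by = bin_width)
  if (length(edges) < 2L) stop("max_distance must span at least one bin")
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= length(edges) - 1L
  n_bins <- length(edges) - 1L
  counts <- table(factor(bin[ok], levels = seq_len(n_bins)), lab[ok])
  totals <- rowSums(counts)
  raw <- sweep(unclass(counts), 1, totals, "/")
  raw[totals == 0L, ] <- NA_real_
  smooth <- apply(raw, 2, function(col) {
    s <- gaussian_smooth_bins(col, sigma / bin_width)
    moving_average_bins(s, max(1L, round(window / bin_width)))
  })
  structure(list(distance_um = (edges[-1] + edges[-length(edges)]) / 2,
                 raw = raw, smooth = smooth, n_per_bin = as.integer(totals),
                 bin_width = bin_width, sigma = sigma, window = window),
            class = "profile_curve")
}

# NA-aware discrete Gaussian smoothing over bins; weights renormalised over
# observed bins so gaps do not drag estimates toward zero.
gaussian_smooth_bins <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  w <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    wi <- w[j - i + half + 1L]
    xi <- x[j]
    obs <- !is.na(xi)
    if (any(obs)) out[i] <- sum(wi[obs] * xi[obs]) / sum(wi[obs])
  }
  out
}

moving_average_bins <- function(x, width_bins) {
  if (width_bins <= 1L) return(x)
  if (width_bins %% 2L == 0L) width_bins <- width_bins + 1L  # centered
  half <- width_bins %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    xi <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(xi))) NA_real_ else mean(xi, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("Abundance profile: %d bins of %g um x %d series (sigma %g um, window %g um)\n",
              length(x$distance_um), x$bin_width, ncol(x$raw),
              x$sigma, x$window))
  invisible(x)
}

#' @export
plot.profile_curve <- function(x, smoothed = TRUE, ...) {
  m <- if (smoothed) x$smooth else x$raw
  graphics::matplot(x$distance_um, m, type = "l", lty = 1,
                    xlab = "distance from well (um)",
                    ylab = "relative abundance", ...)
  graphics::legend("topright", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Sample random circular regions of interest
#'
#' Uniformly random circle centers inside the region, eroded so that every
#' disc lies fully inside (the published proximity protocol samples
#' circular regions of 175 um diameter within a zone of interest). Seeded
#' and reproducible.
#'
#' @param region Either `c(xmin, xmax, ymin, ymax)` or a k x 2 polygon (um).
#' @param diameter ROI diameter (um).
#' @param n Number of ROIs.
#' @param seed Seed for reproducible sampling.
#' @return n x 2 matrix of ROI centers with attributes `diameter` and
#'   `seed`.
#' @export
sample_rois <- function(region, diameter = 175, n = 4L, seed = 1L) {
  r <- diameter / 2
  if (is.matrix(region) && ncol(region) == 2L && nrow(region) > 2L) {
    vx <- region[, 1]; vy <- region[, 2]
    if (!polygon_is_simple(vx, vy)) stop("region polygon is self-intersecting")
    if (polygon_area(vx, vy) < pi * r^2)
      stop("region too small for the requested ROI diameter")
    bb <- c(range(vx), range(vy))
    inside <- function(x, y) {
      ok <- point_in_polygon(x, y, vx, vy)
      if (!any(ok)) return(ok)
      nv <- length(vx)
      j <- c(seq(2, nv), 1)
      for (i in which(ok)) {
        mind <- min(dist_point_segment(x[i], y[i], vx, vy, vx[j], vy[j]))
        if (mind < r) ok[i] <- FALSE
      }
      ok
    }
  } else if (is.numeric(region) && length(region) == 4L) {
    if (region[2] - region[1] < diameter || region[4] - region[3] < diameter)
      stop("region too small for the requested ROI diameter")
    bb <- region
    inside <- function(x, y)
      x >= region[1] + r & x <= region[2] - r &
      y >= region[3] + r & y <= region[4] - r
  } else stop("region must be a bounding box or a polygon")
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n) {
      m <- max(4L * n, 32L)
      x <- stats::runif(m, bb[1], bb[2])
      y <- stats::runif(m, bb[3], bb[4])
      ok <- inside(x, y)
      centers <- rbind(centers, cbind(x[ok], y[ok]))
      tries <- tries + m
      if (tries > 10000L * n && nrow(centers) == 0L)
        stop("region too small for the requested ROI diameter")
    }
    centers <- centers[seq_len(n), , drop = FALSE]
    colnames(centers) <- c("x_um", "y_um")
    structure(centers, diameter = diameter, seed = seed)
  })
}

#' Pairwise proximity between two cell sets
#'
#' All `|A| * |B|` Euclidean distances between two marker-positive cell
#' sets, their histogram, and the proportion of pairs closer than `cutoff`
#' (50 um by default, the distance at which cells are considered spatially
#' interacting). Symmetric in the two sets.
#'
#' @param setA,setB n x 2 coordinate matrices (um) or data.frames with
#'   `x_um`/`y_um`.
#' @param cutoff Interaction distance (um); the proportion counts pairs
#'   strictly below it.
#' @param breaks Histogram breaks (um); default 25-um bins covering the
#'   data.
#' @return Object of class `proximity_result`: `n_pairs`,
#'   `proportion_below`, `cutoff_um`, histogram `counts`/`breaks`, and
#'   summary statistics of the pair distances.
#' @export
pairwise_proximity <- function(setA, setB, cutoff = 50, breaks = NULL) {
  a <- as_point_matrix(setA)
  b <- as_point_matrix(setB)
  if (nrow(a) == 0L) stop("setA is empty")
  if (nrow(b) == 0L) stop("setB is empty")
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  d <- as.vector(d)
  if (is.null(breaks))
    breaks <- seq(0, max(d, cutoff) + 25, by = 25)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(n_pairs = length(d),
                 proportion_below = mean(d < cutoff),
                 cutoff_um = cutoff,
                 counts = h$counts, breaks = h$breaks,
                 mean_distance_um = mean(d),
                 median_distance_um = stats::median(d)),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Pairwise proximity: %d pairs, %.1f%% closer than %g um (median %.1f um)\n",
              x$n_pairs, 100 * x$proportion_below, x$cutoff_um,
              x$median_distance_um))
  invisible(x)
}

#' @export
plot.proximity_result <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$counts, names.arg = round(mids), space = 0,
                    xlab = "pair distance (um)", ylab = "number of pairs", ...)
  graphics::abline(v = sum(x$breaks <= x$cutoff_um), lty = 2)
  invisible(x)
}
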