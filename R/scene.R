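#' Synthetic microdevice scenes
#'
#' Ground-truthed generator for the cell-table statistics the pipeline
#' assumes around a drug-releasing well: a homogeneous Poisson background of
#' typed cells, drug-recruited cells from an inhomogeneous Poisson process
#' whose intensity decays exponentially with distance from the well,
#' planted compact cell clusters (parent points with Gaussian offspring),
#' and per-marker positive/negative intensity mixtures. Scenes are generated
#' directly in the well frame (well at the origin, release towards +y).
#'
#' @name synthetic-scenes
NULL

#' Default synthetic cell-type mixture
#'
#' Ten cell types matching leaves of the default gating tree, with marker
#' signatures over the 13-marker baseline panel and tissue-like baseline
#' fractions (tumor-dominated, with minority stromal populations of a few
#' percent). Signature markers are positive with probability `p_pos`;
#' off-signature markers with probability `p_offtarget`.
#'
#' @return List of cell-type definitions.
#' @export
default_cell_types <- function() {
  ct <- function(label, fraction, markers)
    list(label = label, fraction = fraction, markers = markers)
  list(
    ct("tumor (Epcam+)",            0.55, c("Epcam")),
    ct("CSF1R+ MHC-II- macrophage", 0.12, c("CD45", "CD11b", "F480", "CSF1R")),
    ct("neutrophil",                0.08, c("CD45", "CD11b", "Ly6G")),
    ct("dendritic cell",            0.05, c("CD45", "CD11c")),
    ct("CD8 T cell",                0.05, c("CD45", "CD3", "CD8")),
    ct("CD4 T cell",                0.05, c("CD45", "CD3", "CD4")),
    ct("endothelial",               0.04, c("CD31")),
    ct("pericyte",                  0.02, c("CD31", "aSMA")),
    ct("fibroblast",                0.02, c("aSMA")),
    ct("mesenchymal",               0.02, character(0))
  )
}

#' Scene configuration
#'
#' Defaults emulate the study conditions: a ~1.2 x 1.2 mm window around the
#' well at 3.5e-3 cells/um^2 (so an assay-region-sized half-window above the
#' well holds 3,000-5,000 cells), the [default_cell_types()] mixture, and
#' Beta intensity mixtures with the negative mode near 0.1 and the positive
#' mode near 0.7.
#'
#' @param arena `c(xmin, xmax, ymin, ymax)` in um, well frame.
#' @param background_density Cells per um^2 of the homogeneous background.
#' @param cell_types List of type definitions (label, fraction, markers,
#'   optional p_pos/p_offtarget overrides); fractions must sum to 1.
#' @param gradients List of recruitment gradients, each
#'   `list(label =, amplitude =, decay_length =)` with `amplitude` the
#'   recruited-process intensity at the well (cells/um^2) and `decay_length`
#'   in um.
#' @param planted_clusters List of planted clusters, each
#'   `list(label =, n_clusters =, cells_per_cluster =, spread_sd =, zone =,
#'   min_separation =)` where `zone` is an optional
#'   `c(xmin, xmax, ymin, ymax)` placement box and `min_separation`
#'   (default 200 um) keeps cluster centers apart so planted microcultures
#'   are spatially distinct.
#' @param upper_half_only Restrict gradients and planted clusters to the
#'   release side (y > 0); the background fills the whole arena.
#' @param markers Marker panel to simulate.
#' @param p_pos,p_offtarget Positivity probabilities for signature and
#'   off-signature markers.
#' @param pos_shape,neg_shape Beta shape pairs of the positive and negative
#'   intensity components (modes 0.7 and 0.1, concentrated enough that the
#'   two populations separate cleanly at chromogenic gating thresholds).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `scene_config` list.
#' @export
scene_config <- function(arena = c(-600, 600, -300, 900),
                         background_density = 3.5e-3,
                         cell_types = default_cell_types(),
                         gradients = list(),
                         planted_clusters = list(),
                         upper_half_only = TRUE,
                         markers = baseline_panel(),
                         p_pos = 0.98, p_offtarget = 0.02,
                         pos_shape = c(15, 7), neg_shape = c(3, 19),
                         seed = 1L) {
  arena <- as.numeric(arena)
  if (length(arena) != 4L || arena[2] <= arena[1] || arena[4] <= arena[3])
    stop("arena must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (!is.finite(background_density) || background_density <= 0)
    stop("background_density must be positive")
  fr <- vapply(cell_types, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("cell type baseline fractions must sum to 1")
  for (g in gradients) {
    if (g$amplitude < 0) stop("gradient amplitude must be >= 0")
    if (g$decay_length <= 0) stop("gradient decay_length must be positive")
  }
  for (pc in planted_clusters)
    if (pc$spread_sd <= 0) stop("planted cluster spread_sd must be positive")
  structure(list(arena = arena, background_density = background_density,
                 cell_types = cell_types, gradients = gradients,
                 planted_clusters = planted_clusters,
                 upper_half_only = upper_half_only, markers = markers,
                 p_pos = p_pos, p_offtarget = p_offtarget,
                 pos_shape = pos_shape, neg_shape = neg_shape,
                 seed = as.integer(seed)),
            class = "scene_config")
}

scene_labels <- function(config)
  vapply(config$cell_types, `[[`, character(1), "label")

#' Generate a synthetic scene
#'
#' @param config A [scene_config()].
#' @return An object of class `imd_scene`: a list with `cells` (the cell
#'   table: `cell_id`, `x_um`, `y_um`, one intensity column per marker),
#'   `truth` (row-matched ground truth: true type, planted-cluster id or
#'   `NA`, point source, and per-marker true positivity columns
#'   `pos_<marker>`), and the generating `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    a <- config$arena
    area <- (a[2] - a[1]) * (a[4] - a[3])
    labels <- scene_labels(config)
    fr <- vapply(config$cell_types, `[[`, numeric(1), "fraction")

    # homogeneous Poisson background over the whole arena
    n_bg <- stats::rpois(1L, config$background_density * area)
    x <- stats::runif(n_bg, a[1], a[2])
    y <- stats::runif(n_bg, a[3], a[4])
    type <- sample(labels, n_bg, replace = TRUE, prob = fr)
    cluster_id <- rep(NA_integer_, n_bg)
    source <- rep("background", n_bg)

    # recruited cells: inhomogeneous Poisson, intensity
    # amplitude * exp(-d / decay_length), by thinning
    grow <- function(xn, yn, tn, cn, sn) {
      x <<- c(x, xn); y <<- c(y, yn); type <<- c(type, tn)
      cluster_id <<- c(cluster_id, cn); source <<- c(source, sn)
    }
    ylo <- if (config$upper_half_only) max(0, a[3]) else a[3]
    sub_area <- (a[2] - a[1]) * (a[4] - ylo)
    for (g in config$gradients) {
      if (g$amplitude <= 0 || sub_area <= 0) next
      n_cand <- stats::rpois(1L, g$amplitude * sub_area)
      cx <- stats::runif(n_cand, a[1], a[2])
      cy <- stats::runif(n_cand, ylo, a[4])
      keep <- stats::runif(n_cand) < exp(-sqrt(cx^2 + cy^2) / g$decay_length)
      grow(cx[keep], cy[keep], rep(g$label, sum(keep)),
           rep(NA_integer_, sum(keep)), rep("gradient", sum(keep)))
    }

    # planted compact clusters: parent centers with Gaussian offspring,
    # centers kept min_separation apart (distinct microcultures)
    next_cluster <- 1L
    placed <- matrix(numeric(0), ncol = 2)
    for (pc in config$planted_clusters) {
      zone <- pc$zone
      if (is.null(zone)) {
        margin <- 4 * pc$spread_sd
        zone <- c(a[1] + 0.1 * (a[2] - a[1]) + margin,
                  a[2] - 0.1 * (a[2] - a[1]) - margin,
                  max(ylo, a[3]) + 0.25 * (a[4] - max(ylo, a[3])),
                  a[4] - 0.25 * (a[4] - max(ylo, a[3])))
      }
      min_sep <- if (is.null(pc$min_separation)) 200 else pc$min_separation
      for (k in seq_len(pc$n_clusters)) {
        for (try in 1:1000) {
          cx0 <- stats::runif(1, zone[1], zone[2])
          cy0 <- stats::runif(1, zone[3], zone[4])
          if (nrow(placed) == 0L ||
              min(sqrt((placed[, 1] - cx0)^2 + (placed[, 2] - cy0)^2)) >= min_sep)
            break
        }
        placed <- rbind(placed, c(cx0, cy0))
        n_off <- pc$cells_per_cluster
        ox <- pmin(pmax(stats::rnorm(n_off, cx0, pc$spread_sd), a[1]), a[2])
        oy <- pmin(pmax(stats::rnorm(n_off, cy0, pc$spread_sd), a[3]), a[4])
        grow(ox, oy, rep(pc$label, n_off),
             rep(next_cluster, n_off), rep("cluster", n_off))
        next_cluster <- next_cluster + 1L
      }
    }

    n <- length(x)
    # per-marker intensities from the type's positive/negative Beta mixture
    intens <- matrix(NA_real_, n, length(config$markers),
                     dimnames = list(NULL, config$markers))
    posit <- matrix(NA, n, length(config$markers),
                    dimnames = list(NULL, config$markers))
    sig <- matrix(FALSE, length(labels), length(config$markers),
                  dimnames = list(labels, config$markers))
    for (ct in config$cell_types)
      sig[ct$label, intersect(ct$markers, config$markers)] <- TRUE
    for (m in config$markers) {
      p <- ifelse(sig[type, m], config$p_pos, config$p_offtarget)
      pos <- stats::runif(n) < p
      v <- numeric(n)
      if (any(pos))
        v[pos] <- stats::rbeta(sum(pos), config$pos_shape[1], config$pos_shape[2])
      if (any(!pos))
        v[!pos] <- stats::rbeta(sum(!pos), config$neg_shape[1], config$neg_shape[2])
      intens[, m] <- pmin(pmax(v, 0), 1)
      posit[, m] <- pos
    }

    cells <- data.frame(cell_id = seq_len(n), x_um = x, y_um = y)
    cells <- cbind(cells, as.data.frame(intens))
    truth <- data.frame(cell_id = seq_len(n), type = type,
                        cluster_id = cluster_id, source = source,
                        stringsAsFactors = FALSE)
    pm <- as.data.frame(posit)
    names(pm) <- paste0("pos_", names(pm))
    truth <- cbind(truth, pm)
    structure(list(cells = cells, truth = truth, config = config),
              class = "imd_scene")
  })
}

#' Generate a null scene
#'
#' The same scene with all recruitment gradients and planted clusters
#' removed: a homogeneous typed Poisson background emulating a pure-carrier
#' (PEG) negative-control region. Used for false-cluster and type-I-error
#' calibration.
#'
#' @param config A [scene_config()].
#' @return An `imd_scene`; see [generate_scene()].
#' @export
generate_null_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  config$gradients <- list()
  config$planted_clusters <- list()
  generate_scene(config)
}

#' @export
print.imd_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d cells, arena [%.0f, %.0f] x [%.0f, %.0f] um, seed %d\n",
              nrow(x$cells), x$config$arena[1], x$config$arena[2],
              x$config$arena[3], x$config$arena[4], x$config$seed))
  cat(sprintf("  %d gradients, %d planted cluster groups\n",
              length(x$config$gradients), length(x$config$planted_clusters)))
  invisible(x)
}

#' Fit an exponential recruitment decay length
#'
#' Poisson regression of annulus counts on distance from the well with a
#' log-area offset: for a recruited process with intensity
#' `A * exp(-d / L)`, the slope of the log intensity is `-1/L`. Annuli are
#' restricted to the release half-plane and must lie inside the arena for
#' the area offset to be exact.
#'
#' @param points n x 2 matrix of recruited-cell coordinates (well frame).
#' @param bin_width Annulus width (um).
#' @param max_distance Largest distance fitted (um).
#' @return List with `decay_length` (um), `amplitude` (cells/um^2 at the
#'   well) and the `glm` fit.
#' @export
fit_gradient_decay <- function(points, bin_width = 25, max_distance = 450) {
  p <- as_point_matrix(points)
  p <- p[p[, 2] > 0, , drop = FALSE]
  d <- sqrt(rowSums(p^2))
  edges <- seq(0, max_distance, by = bin_width)
  counts <- tabulate(findInterval(d[d < max_distance], edges), length(edges) - 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  half_annulus <- pi * (edges[-1]^2 - edges[-length(edges)]^2) / 2
  fit <- stats::glm(counts ~ mids, family = stats::poisson(),
                    offset = log(half_annulus))
  slope <- stats::coef(fit)[["mids"]]
  if (slope >= 0) warning("non-decaying point pattern: decay length is infinite")
  list(decay_length = -1 / slope,
       amplitude = exp(stats::coef(fit)[["(Intercept)"]]),
       fit = fit)
}
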