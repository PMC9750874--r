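#' Hierarchical gating of single-cell intensity tables
#'
#' Image-cytometry style classification: an ordered hierarchy of gates whose
#' leaves carry cell-type labels. Nodes are evaluated root-down in declared
#' order and the first matching child wins, reproducing manual hierarchical
#' gating semantics deterministically. Gates are either 1-D intensity
#' thresholds (positivity = intensity strictly greater than the threshold),
#' boolean combinations of thresholds, or translatable 2-D polygon gates on
#' a marker pair. Cells matching no leaf receive the reserved label
#' `"unclassified"`.
#'
#' @name gating
NULL

UNCLASSIFIED <- "unclassified"

#' The 13-marker baseline discovery panel
#'
#' Column-name-safe spellings of the 13 chromogenic markers used to define
#' the standard cell types (`aSMA` stands for \eqn{\alpha}SMA, `F480` for
#' F4/80, `MHCII` for MHC-II).
#'
#' @return Character vector of 13 marker names.
#' @export
baseline_panel <- function() {
  c("Epcam", "CD45", "CD31", "aSMA", "CD3", "CD4", "CD8",
    "CD11b", "F480", "CSF1R", "CD11c", "Ly6G", "MHCII")
}

# ---- gate construction -----------------------------------------------------

#' Construct a 1-D threshold gate
#'
#' @param marker Marker name.
#' @param threshold Intensity threshold in `[0, 1]`.
#' @param side `"above"` (strictly greater = positive, the default
#'   convention) or `"below"`.
#' @return A gate object.
#' @export
threshold_gate <- function(marker, threshold, side = c("above", "below")) {
  side <- match.arg(side)
  stopifnot(is.character(marker), length(marker) == 1L,
            is.numeric(threshold), length(threshold) == 1L)
  structure(list(type = "threshold", marker = marker,
                 threshold = threshold, side = side), class = "imd_gate")
}

#' Construct a translatable 2-D polygon gate
#'
#' The polygon is anchored at a central vertex; moving the anchor translates
#' the whole gate without changing its shape, which is how gates are ported
#' across staining batches.
#'
#' @param markers Character pair: the x and y markers.
#' @param vertices k x 2 matrix of polygon vertices (intensity units).
#' @param central_vertex Anchor point; defaults to the vertex centroid.
#' @return A gate object.
#' @export
polygon_gate <- function(markers, vertices, central_vertex = NULL) {
  stopifnot(length(markers) == 2L)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be a k x 2 matrix with k >= 3")
  if (!polygon_is_simple(vertices[, 1], vertices[, 2]))
    stop("polygon gate is self-intersecting")
  if (is.null(central_vertex)) central_vertex <- colMeans(vertices)
  structure(list(type = "polygon", markers = as.character(markers),
                 vertices = vertices,
                 central_vertex = as.numeric(central_vertex)),
            class = "imd_gate")
}

#' Translate a polygon gate to a new central vertex
#'
#' @param gate A polygon gate.
#' @param new_center New anchor position.
#' @return The translated gate (shape unchanged).
#' @export
translate_gate <- function(gate, new_center) {
  stopifnot(inherits(gate, "imd_gate"), gate$type == "polygon")
  shift <- as.numeric(new_center) - gate$central_vertex
  gate$vertices <- sweep(gate$vertices, 2, -shift)
  gate$central_vertex <- as.numeric(new_center)
  gate
}

#' Evaluate a polygon gate on intensity pairs
#'
#' Standard even-odd point-in-polygon membership.
#'
#' @param gate A [polygon_gate()].
#' @param points n x 2 matrix of (x marker, y marker) intensities.
#' @return Logical membership vector.
#' @export
evaluate_polygon_gate <- function(gate, points) {
  stopifnot(inherits(gate, "imd_gate"), gate$type == "polygon")
  p <- as_point_matrix(points)
  point_in_polygon(p[, 1], p[, 2], gate$vertices[, 1], gate$vertices[, 2])
}

# Vectorised gate evaluation against a cell table. Returns a logical vector.
evaluate_gate <- function(gate, table) {
  switch(gate$type,
    threshold = {
      x <- table[[gate$marker]]
      if (is.null(x)) stop("marker column missing from table: ", gate$marker)
      if (gate$side == "above") x > gate$threshold else x <= gate$threshold
    },
    all = Reduce(`&`, lapply(gate$conditions, evaluate_gate, table = table)),
    any = Reduce(`|`, lapply(gate$conditions, evaluate_gate, table = table)),
    polygon = {
      for (m in gate$markers)
        if (is.null(table[[m]])) stop("marker column missing from table: ", m)
      evaluate_polygon_gate(gate,
                            cbind(table[[gate$markers[1]]],
                                  table[[gate$markers[2]]]))
    },
    otherwise = rep(TRUE, nrow(table)),
    stop("unknown gate type: ", gate$type)
  )
}

# ---- config parsing --------------------------------------------------------

parse_gate <- function(spec, thresholds) {
  if (is.null(spec) || identical(spec$type, "otherwise"))
    return(structure(list(type = "otherwise"), class = "imd_gate"))
  if (!is.null(spec$type) && spec$type %in% c("all", "any")) {
    conds <- lapply(spec$conditions, parse_gate, thresholds = thresholds)
    return(structure(list(type = spec$type, conditions = conds),
                     class = "imd_gate"))
  }
  if (!is.null(spec$type) && spec$type == "polygon") {
    v <- do.call(rbind, lapply(spec$vertices, as.numeric))
    g <- polygon_gate(unlist(spec$markers), v,
                      central_vertex = if (is.null(spec$central_vertex)) NULL
                                       else as.numeric(spec$central_vertex))
    if (!is.null(spec$central_vertex_at))
      g <- translate_gate(g, as.numeric(spec$central_vertex_at))
    return(g)
  }
  # shorthand 1-D gates: {marker: CD45, side: above[, threshold: 0.4]}
  thr <- spec$threshold
  if (is.null(thr)) thr <- thresholds[[spec$marker]]
  if (is.null(thr)) thr <- thresholds[["default"]]
  if (is.null(thr)) stop("no threshold for marker ", spec$marker)
  threshold_gate(spec$marker, as.numeric(thr),
                 side = if (is.null(spec$side)) "above" else spec$side)
}

parse_node <- function(spec, thresholds) {
  node <- list(gate = parse_gate(spec$gate, thresholds),
               label = spec$label,
               children = lapply(spec$children, parse_node,
                                 thresholds = thresholds))
  if (is.null(node$label) && length(node$children) == 0L)
    stop("gating node with neither a label nor children")
  node
}

collect_leaves <- function(nodes) {
  unlist(lapply(nodes, function(n) {
    if (length(n$children)) collect_leaves(n$children) else n$label
  }))
}

collect_markers <- function(x) {
  if (inherits(x, "imd_gate")) {
    return(switch(x$type,
                  threshold = x$marker,
                  polygon = x$markers,
                  all = ,
                  any = unlist(lapply(x$conditions, collect_markers)),
                  character(0)))
  }
  unlist(lapply(x, function(n)
    c(collect_markers(n$gate), collect_markers(n$children))))
}

#' Load and validate a gating tree configuration
#'
#' Reads a YAML gating hierarchy (see the shipped default at
#' `system.file("extdata", "gating_default.yaml", package = "imdassay")`),
#' validates it (unique leaf labels, markers within the declared panel,
#' simple polygons) and returns a `gating_tree`. The shipped default
#' reconstructs the 17 standard tumor-microenvironment cell types from the
#' 13-marker baseline panel; its `meta$provenance` field marks it as a
#' reconstruction, and users can substitute their own tree.
#'
#' @param path Path to a YAML gating config, or a pre-parsed list.
#' @return An object of class `gating_tree`.
#' @export
load_gating_config <- function(path = default_gating_config_path()) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  thresholds <- cfg$thresholds
  nodes <- lapply(cfg$tree, parse_node, thresholds = thresholds)
  leaves <- collect_leaves(nodes)
  dup <- unique(leaves[duplicated(leaves)])
  if (length(dup))
    stop("duplicate leaf labels in gating config: ", paste(dup, collapse = ", "))
  if (UNCLASSIFIED %in% leaves)
    stop("'", UNCLASSIFIED, "' is reserved and cannot name a leaf")
  markers <- unique(collect_markers(nodes))
  panel <- unlist(cfg$meta$markers)
  if (length(panel)) {
    bad <- setdiff(markers, panel)
    if (length(bad))
      stop("gating config references markers absent from its panel: ",
           paste(bad, collapse = ", "))
  }
  structure(list(meta = cfg$meta, nodes = nodes,
                 leaves = leaves, markers = markers),
            class = "gating_tree")
}

#' @rdname load_gating_config
#' @export
default_gating_config_path <- function() {
  system.file("extdata", "gating_default.yaml", package = "imdassay",
              mustWork = TRUE)
}

#' @export
print.gating_tree <- function(x, ...) {
  cat(sprintf("Gating tree '%s': %d leaf cell types over %d markers\n",
              if (is.null(x$meta$name)) "unnamed" else x$meta$name,
              length(x$leaves), length(x$markers)))
  if (!is.null(x$meta$provenance))
    cat("  provenance:", x$meta$provenance, "\n")
  invisible(x)
}

#' Leaf labels of a gating tree
#' @param tree A `gating_tree`.
#' @return Character vector of leaf cell-type labels (excluding the reserved
#'   `"unclassified"`).
#' @export
gating_leaves <- function(tree) tree$leaves

#' Markers referenced by a gating tree
#' @param tree A `gating_tree`.
#' @return Character vector of distinct marker names.
#' @export
gating_markers <- function(tree) tree$markers

# ---- classification --------------------------------------------------------

assign_labels <- function(nodes, table, mask, labels) {
  for (node in nodes) {
    if (!any(mask)) break
    hit <- mask & evaluate_gate(node$gate, table)
    if (length(node$children)) {
      labels <- assign_labels(node$children, table, hit, labels)
    } else {
      labels[hit] <- node$label
    }
    mask <- mask & !hit
  }
  labels
}

#' Classify cells with a gating tree
#'
#' Each cell receives exactly one leaf label (possibly `"unclassified"`);
#' the assignment depends only on that cell's own intensities, so the result
#' is equivariant under row permutation.
#'
#' @param table A cell table with one numeric column per marker.
#' @param tree A [load_gating_config()] result.
#' @return Factor of length `nrow(table)` with levels
#'   `c(gating_leaves(tree), "unclassified")`.
#' @export
classify_cells <- function(table, tree) {
  stopifnot(inherits(tree, "gating_tree"))
  missing <- setdiff(tree$markers, names(table))
  if (length(missing))
    stop("cell table lacks marker column(s): ", paste(missing, collapse = ", "))
  labels <- rep(UNCLASSIFIED, nrow(table))
  labels <- assign_labels(tree$nodes, table, rep(TRUE, nrow(table)), labels)
  factor(labels, levels = c(tree$leaves, UNCLASSIFIED))
}

# ---- extended phenotypes ---------------------------------------------------

#' Load extended phenotype definitions
#'
#' Extended phenotypes refine the standard taxonomy with additional readout
#' markers (for example antigen-presenting neutrophils, phagocytic DCs, or
#' the Sox9+ cancer stem cell pattern). Each definition carries a marker
#' sign pattern and, optionally, the standard class it refines (`within`),
#' so that every extended-positive cell is also a member of its parent
#' standard class.
#'
#' @param path YAML file of definitions; defaults to the shipped set.
#' @return Named list of definitions.
#' @export
load_phenotype_definitions <- function(path = system.file(
    "extdata", "phenotypes_extended.yaml", package = "imdassay",
    mustWork = TRUE)) {
  cfg <- yaml::read_yaml(path)
  cfg$phenotypes
}

#' Flag extended phenotypes on a classified table
#'
#' @param table Cell table with marker columns.
#' @param labels Standard-type factor from [classify_cells()].
#' @param definitions From [load_phenotype_definitions()].
#' @param thresholds Named threshold list; `default` is used for markers
#'   without their own entry.
#' @return Logical matrix, one column per phenotype.
#' @export
classify_extended <- function(table, labels, definitions,
                              thresholds = list(default = 0.4)) {
  thr <- function(m) {
    t <- thresholds[[m]]
    if (is.null(t)) t <- thresholds[["default"]]
    t
  }
  out <- sapply(definitions, function(def) {
    ok <- rep(TRUE, nrow(table))
    for (p in def$pattern) {
      x <- table[[p$marker]]
      if (is.null(x)) stop("marker column missing from table: ", p$marker)
      ok <- ok & if (isTRUE(p$positive)) x > thr(p$marker) else x <= thr(p$marker)
    }
    if (!is.null(def$within)) ok <- ok & (as.character(labels) %in% def$within)
    ok
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(table),
                                       dimnames = list(NULL, names(definitions)))
  out
}

# ---- data-driven thresholds ------------------------------------------------

#' Derive a positivity threshold from a control tissue
#'
#' Automatic 1-D Otsu threshold on the control table's intensity histogram,
#' mirroring the use of positive-control tissues to set single-parameter
#' positivity cut-offs, with a manual override hook. If the control shows no
#' separable positive population (a single intensity mode), the returned
#' threshold is placed just above the maximum observed intensity and flagged.
#'
#' @param control_table Cell table measured on the control tissue.
#' @param marker Marker column to threshold.
#' @param override Manual threshold; returned as-is (with provenance) when
#'   given.
#' @return Numeric threshold with attributes `marker`, `method` and
#'   `no_positive_population`.
#' @export
threshold_from_control <- function(control_table, marker, override = NULL) {
  x <- control_table[[marker]]
  if (is.null(x)) stop("marker column missing from control table: ", marker)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("control table is empty for marker ", marker)
  if (!is.null(override)) {
    return(structure(override, marker = marker, method = "manual",
                     no_positive_population = FALSE))
  }
  if (diff(range(x)) < .Machine$double.eps)
    stop("degenerate distribution: constant intensities for marker ", marker)
  if (count_intensity_modes(x) < 2L) {
    return(structure(max(x) + 1e-6, marker = marker, method = "otsu",
                     no_positive_population = TRUE))
  }
  structure(otsu_threshold(x), marker = marker, method = "otsu",
            no_positive_population = FALSE)
}

# Count modes of a smoothed fixed-range histogram; used to decide whether a
# control tissue contains a positive population at all.
count_intensity_modes <- function(x, n_bins = 64L, prominence = 0.05) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                     n_bins), nbins = n_bins)
  k <- stats::filter(c(h[1], h[1], h, h[n_bins], h[n_bins]),
                     rep(1 / 5, 5), sides = 2)
  k <- as.numeric(k)[3:(n_bins + 2L)]
  prom <- prominence * max(k)
  # prominence-based peak counting on the smoothed histogram
  modes <- 0L
  rising <- TRUE
  ref <- k[1]
  for (i in seq(2L, n_bins)) {
    if (rising) {
      if (k[i] >= ref) {
        ref <- k[i]
      } else if (ref > prom && k[i] < ref - prom) {
        modes <- modes + 1L
        rising <- FALSE
        ref <- k[i]
      }
    } else {
      if (k[i] <= ref) {
        ref <- k[i]
      } else if (k[i] > ref + prom) {
        rising <- TRUE
        ref <- k[i]
      }
    }
  }
  if (rising && ref > prom) modes <- modes + 1L
  modes
}
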