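# Independent oracles and shared fixtures, deliberately implemented with
# different algorithms/data paths than the package code they check.

# O(n^2) dense-distance-matrix union-find: the reference partition for
# single-linkage distance clustering.
oracle_cluster <- function(points, d_max, min_cells) {
  p <- as.matrix(points)
  n <- nrow(p)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    dm <- as.matrix(stats::dist(p))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (dm[i, j] <= d_max) {
        a <- find(i); b <- find(j)
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  big <- as.integer(names(sizes)[sizes >= min_cells])
  cl <- rep(NA_integer_, n)
  if (length(big)) {
    first <- vapply(big, function(r) which(roots == r)[1L], integer(1))
    big <- big[order(first)]
    for (k in seq_along(big)) cl[roots == big[k]] <- k
  }
  cl
}

# Double-loop pair distances.
oracle_proximity <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  d <- numeric(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    d <- c(d, sqrt(sum((a[i, ] - b[j, ])^2)))
  list(d = d, prop = mean(d < cutoff))
}

# Per-label pixel loop for mean intensities.
oracle_label_means <- function(labels, channel) {
  out <- numeric(max(labels))
  for (k in seq_len(max(labels))) {
    acc <- 0; cnt <- 0L
    for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
      if (labels[i, j] == k) {
        acc <- acc + channel[i, j]
        cnt <- cnt + 1L
      }
    }
    out[k] <- acc / cnt
  }
  out
}

# Study-condition fixtures for the paired enrichment design: a scene large
# enough to hold disjoint assay and control regions with spatial
# separation.
enrichment_scene_config <- function(seed, amplitude = 0, decay_length = 150) {
  scene_config(arena = c(-1000, 1000, -1000, 1000),
               background_density = 1.2e-3,
               gradients = if (amplitude > 0)
                 list(list(label = "dendritic cell", amplitude = amplitude,
                           decay_length = decay_length)) else list(),
               seed = seed)
}

# One triplicate experiment: truth-labelled scenes, real region selectors.
make_region_pairs <- function(seed, amplitude = 0, n_target = 800) {
  lapply(1:3, function(r) {
    s <- generate_scene(enrichment_scene_config(seed * 10 + r, amplitude))
    tab <- s$cells
    tab$label <- s$truth$type
    assay <- suppressWarnings(select_assay_region(tab, n_target = n_target))
    ctrl <- suppressWarnings(select_control_region(
      tab, n_target = n_target, exclude_ids = assay$cell_id))
    region_pair(assay, ctrl, reservoir_id = r)
  })
}

# Types abundant enough that the detectability floor never censors the
# type-I-error calibration.
calibration_types <- c("tumor (Epcam+)", "CSF1R+ MHC-II- macrophage",
                       "neutrophil", "dendritic cell", "CD8 T cell",
                       "CD4 T cell")

# Null-cluster calibration scene (study density, 2% minority type).
null_cluster_points <- function(seed, type = "pericyte") {
  sc <- scene_config(arena = c(-500, 500, 0, 1000),
                     background_density = 3.5e-3, seed = seed)
  s <- generate_null_scene(sc)
  s$cells[s$truth$type == type, c("x_um", "y_um")]
}

# Planted-cluster construction regime: 3 clusters of 15 cells at 8 um
# spread over a sparse same-type background.
planted_cluster_scene <- function(seed) {
  generate_scene(scene_config(
    background_density = 2e-5,
    cell_types = list(list(label = "m", fraction = 1, markers = "CD45")),
    planted_clusters = list(list(label = "m", n_clusters = 3,
                                 cells_per_cluster = 15, spread_sd = 8)),
    seed = seed))
}

cluster_labels_for_ari <- function(x) ifelse(is.na(x), 0L, x)
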