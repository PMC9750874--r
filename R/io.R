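#' Read and validate a single-cell feature table
#'
#' The CSV interchange schema is one row per cell with required columns
#' `cell_id`, `x_um`, `y_um` (coordinates in micrometers) and one numeric
#' intensity column per marker in `[0, 1]`; extra label columns are kept
#' as-is.
#'
#' @param path CSV file.
#' @param markers Marker columns expected; default: every numeric column
#'   beyond the required three that is not a label column.
#' @param bounds_policy What to do with intensities outside `[0, 1]`:
#'   `"clip"` (warn and clip, default) or `"reject"` (error).
#' @return Validated `data.frame`.
#' @export
read_cell_table <- function(path, markers = NULL,
                            bounds_policy = c("clip", "reject")) {
  bounds_policy <- match.arg(bounds_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  validate_cell_table(tab, markers = markers, bounds_policy = bounds_policy)
}

#' @rdname read_cell_table
#' @param table In-memory table to validate against the schema.
#' @export
validate_cell_table <- function(table, markers = NULL,
                                bounds_policy = c("clip", "reject")) {
  bounds_policy <- match.arg(bounds_policy)
  req <- c("cell_id", "x_um", "y_um")
  missing <- setdiff(req, names(table))
  if (length(missing))
    stop("cell table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(names(table)))
    stop("cell table schema error: duplicated column names")
  bad <- which(!is.finite(table$x_um) | !is.finite(table$y_um))
  if (length(bad))
    stop("non-finite coordinates in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (is.null(markers))
    markers <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], req)
  for (m in markers) {
    x <- table[[m]]
    if (is.null(x)) stop("cell table schema error: missing marker column ", m)
    if (!is.numeric(x)) stop("marker column ", m, " is not numeric")
    out <- is.finite(x) & (x < 0 | x > 1)
    if (any(out)) {
      if (bounds_policy == "reject")
        stop("marker ", m, " has ", sum(out), " intensities outside [0, 1]")
      warning("marker ", m, ": clipping ", sum(out),
              " intensities to [0, 1]")
      table[[m]] <- pmin(pmax(x, 0), 1)
    }
  }
  table
}

#' Write a cell table to CSV
#'
#' @param table Cell table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' @param path YAML run config; see [run_pipeline()] for the recognised
#'   fields.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline on synthetic or tabular input
#'
#' Chains the stages end to end — simulate (or read tables), gate, cluster,
#' profile, proximity, enrich — and writes every artifact (CSV tables, a
#' machine-readable JSON summary, and a provenance record with the config
#' hash, seeds and package version) to `out_dir`. Any stage failure aborts
#' with the stage name; artifacts of completed stages are retained.
#'
#' Recognised config fields (all optional beyond `replicates`):
#' \describe{
#'   \item{scene}{arguments for [scene_config()] (synthetic input), or}
#'   \item{input}{list of per-replicate CSV pairs
#'     (`assay`/`control` paths) for tabular input.}
#'   \item{gating}{path to a gating YAML (default: shipped tree).}
#'   \item{n_target}{assay-region size (default 4000).}
#'   \item{cluster}{list(`type`, `d_max`, `min_cells`).}
#'   \item{profile}{list(`bin_width`, `window`).}
#'   \item{proximity}{list(`type_a`, `type_b`, `cutoff`).}
#'   \item{enrichment}{list(`alpha`, `min_count`, `min_prop_pct`).}
#'   \item{replicates}{number of reservoir replicates (default 3).}
#' }
#'
#' @param config Config list or YAML path.
#' @param out_dir Output directory (created).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Invisibly, a list of in-memory stage results plus the summary.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- list(config_hash = config_hash(config), seed = seed,
                  package_version = as.character(utils::packageVersion("imdassay")),
                  stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    summary$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  replicates <- if (is.null(config$replicates)) 3L else as.integer(config$replicates)
  n_target <- if (is.null(config$n_target)) 4000L else as.integer(config$n_target)

  pairs_raw <- stage("data", {
    if (!is.null(config$input)) {
      lapply(seq_along(config$input), function(r) {
        list(assay = read_cell_table(config$input[[r]]$assay),
             control = read_cell_table(config$input[[r]]$control))
      })
    } else {
      sc_args <- if (is.null(config$scene)) list() else config$scene
      lapply(seq_len(replicates), function(r) {
        sc_args$seed <- seed + r
        sc <- do.call(scene_config, sc_args)
        scene <- generate_scene(sc)
        assay <- suppressWarnings(
          select_assay_region(scene$cells, n_target = n_target))
        control <- suppressWarnings(
          select_control_region(scene$cells, n_target = nrow(assay),
                                exclude_ids = assay$cell_id))
        list(assay = assay, control = control)
      })
    }
  })

  tree <- stage("gate", {
    tree <- load_gating_config(
      if (is.null(config$gating)) default_gating_config_path() else config$gating)
    for (r in seq_along(pairs_raw)) {
      pairs_raw[[r]]$assay$label <- classify_cells(pairs_raw[[r]]$assay, tree)
      pairs_raw[[r]]$control$label <- classify_cells(pairs_raw[[r]]$control, tree)
      write_cell_table(pairs_raw[[r]]$assay,
                       file.path(out_dir, sprintf("assay_r%d.csv", r)))
      write_cell_table(pairs_raw[[r]]$control,
                       file.path(out_dir, sprintf("control_r%d.csv", r)))
    }
    tree
  })
  pairs <- lapply(seq_along(pairs_raw), function(r)
    region_pair(pairs_raw[[r]]$assay, pairs_raw[[r]]$control, reservoir_id = r))

  clusters <- stage("cluster", {
    cl_cfg <- config$cluster
    type <- if (is.null(cl_cfg$type)) gating_leaves(tree)[2] else cl_cfg$type
    d_max <- if (is.null(cl_cfg$d_max)) 50 else cl_cfg$d_max
    min_cells <- if (is.null(cl_cfg$min_cells)) 10L else cl_cfg$min_cells
    res <- lapply(pairs, function(p) {
      sub <- p$assay[p$assay$label == type, , drop = FALSE]
      cluster_by_distance(sub[, c("x_um", "y_um")], d_max, min_cells)
    })
    utils::write.csv(data.frame(
      reservoir = seq_along(res),
      type = type,
      n_clusters = vapply(res, `[[`, integer(1), "n_clusters"),
      clustered_fraction = vapply(res, `[[`, numeric(1), "clustered_fraction")),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
    res
  })

  profile <- stage("profile", {
    pr <- config$profile
    bw <- if (is.null(pr$bin_width)) 25 else pr$bin_width
    win <- if (is.null(pr$window)) 50 else pr$window
    prof <- profile_curve(pairs[[1]]$assay, pairs[[1]]$assay$label,
                          bin_width = bw, window = win)
    utils::write.csv(cbind(distance_um = prof$distance_um,
                           as.data.frame(prof$smooth)),
                     file.path(out_dir, "profile.csv"), row.names = FALSE)
    prof
  })

  proximity <- stage("proximity", {
    px <- config$proximity
    type_a <- if (is.null(px$type_a)) gating_leaves(tree)[1] else px$type_a
    type_b <- if (is.null(px$type_b)) gating_leaves(tree)[2] else px$type_b
    cutoff <- if (is.null(px$cutoff)) 50 else px$cutoff
    tab <- pairs[[1]]$assay
    a <- tab[tab$label == type_a, c("x_um", "y_um")]
    b <- tab[tab$label == type_b, c("x_um", "y_um")]
    res <- pairwise_proximity(a, b, cutoff = cutoff)
    utils::write.csv(data.frame(type_a = type_a, type_b = type_b,
                                n_pairs = res$n_pairs,
                                proportion_below = res$proportion_below,
                                cutoff_um = res$cutoff_um),
                     file.path(out_dir, "proximity.csv"), row.names = FALSE)
    res
  })

  enrich <- stage("enrich", {
    en <- config$enrichment
    res <- paired_enrichment_test(
      pairs,
      alpha = if (is.null(en$alpha)) 0.05 else en$alpha,
      min_count = if (is.null(en$min_count)) 12L else en$min_count,
      min_prop_pct = if (is.null(en$min_prop_pct)) 0.75 else en$min_prop_pct)
    write_enrichment_table(res, file.path(out_dir, "enrichment.csv"))
    res
  })

  summary$n_cells <- vapply(pairs, `[[`, integer(1), "n_assay")
  summary$pairing_valid <- vapply(pairs, `[[`, logical(1), "pairing_valid")
  summary$n_clusters <- vapply(clusters, `[[`, integer(1), "n_clusters")
  summary$n_significant <- sum(enrich$significant)
  summary$elapsed_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pairs = pairs, tree = tree, clusters = clusters,
                 profile = profile, proximity = proximity,
                 enrichment = enrich, summary = summary))
}
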