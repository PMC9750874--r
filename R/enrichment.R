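#' Per-type composition percentages
#'
#' `100 * count(type) / total` over a labelled cell table; exclusive
#' standard types therefore sum to 100.
#'
#' @param labels Factor/character vector of per-cell labels, or a labelled
#'   cell table with a `label` column.
#' @param types Types to report (default: factor levels / observed labels).
#' @return Named numeric vector of percentages.
#' @export
composition_percentages <- function(labels, types = NULL) {
  if (is.data.frame(labels)) {
    if (is.null(labels$label)) stop("table has no 'label' column")
    labels <- labels$label
  }
  if (length(labels) == 0L) stop("empty table: no cells to tally")
  if (is.null(types))
    types <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  counts <- table(factor(labels, levels = types))
  pct <- 100 * as.numeric(counts) / length(labels)
  names(pct) <- types
  pct
}

#' Paired assay-vs-control enrichment test
#'
#' For each cell type, per-reservoir composition differences
#' `d_i = %assay_i - %control_i` are tested with a paired one-tailed
#' t-test (alternative: assay > control, the direction of drug-induced
#' enrichment), df = n - 1. A noise floor discriminates real enrichment
#' from counting noise: a type is detectable only if its mean assay count
#' is at least `min_count` (published: 12 cells) and its mean assay
#' proportion at least `min_prop_pct` (published: 0.75%); both constants
#' are honored as stated and both conditions are required by default.
#' Types failing the floor are reported with the p-value masked to `NA`
#' (status `"below_floor"`) and are never flagged significant. Zero-variance
#' differences give status `"degenerate"` with `NA` p (no fabricated
#' zeros). No multiple-testing correction is applied by default, matching
#' the per-type reporting convention; Benjamini-Hochberg is available via
#' `p_adjust = "BH"`.
#'
#' @param pairs List of [region_pair()] objects (protocol default: 3
#'   reservoirs).
#' @param types Types to test; default: union of observed labels.
#' @param label_col Column of the region tables holding labels.
#' @param alpha Significance level.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion, behind this flag only).
#' @param min_count,min_prop_pct Detectability floor on the assay region.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return Object of class `enrichment_table`: a data.frame with one row
#'   per type (`pct_assay`, `pct_control`, `mean_diff`, `t`, `df`,
#'   `p_value`, `p_raw`, `detectable`, `status`, `significant`,
#'   `n_replicates`), with test settings in attributes.
#' @export
paired_enrichment_test <- function(pairs, types = NULL, label_col = "label",
                                   alpha = 0.05,
                                   alternative = c("greater", "less"),
                                   min_count = 12L, min_prop_pct = 0.75,
                                   p_adjust = "none") {
  alternative <- match.arg(alternative)
  if (length(pairs) < 2L)
    stop("need at least two region pairs for a paired test")
  get_labels <- function(tab) {
    if (is.null(tab[[label_col]]))
      stop("region table has no '", label_col, "' column")
    tab[[label_col]]
  }
  if (is.null(types)) {
    all_lab <- unlist(lapply(pairs, function(p)
      c(as.character(get_labels(p$assay)), as.character(get_labels(p$control)))))
    first <- get_labels(pairs[[1]]$assay)
    types <- if (is.factor(first)) levels(first) else sort(unique(all_lab))
  }
  n <- length(pairs)
  pa <- pc <- ca <- matrix(NA_real_, n, length(types))
  for (i in seq_len(n)) {
    pa[i, ] <- composition_percentages(get_labels(pairs[[i]]$assay), types)
    pc[i, ] <- composition_percentages(get_labels(pairs[[i]]$control), types)
    ca[i, ] <- as.numeric(table(factor(get_labels(pairs[[i]]$assay),
                                       levels = types)))
  }

  res <- data.frame(type = types,
                    pct_assay = colMeans(pa),
                    pct_control = colMeans(pc),
                    mean_diff = colMeans(pa - pc),
                    t = NA_real_, df = n - 1L,
                    p_raw = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  status <- rep("ok", length(types))
  for (k in seq_along(types)) {
    d <- pa[, k] - pc[, k]
    if (stats::sd(d) < .Machine$double.eps^0.5) {
      status[k] <- "degenerate"
      next
    }
    tt <- stats::t.test(pa[, k], pc[, k], paired = TRUE,
                        alternative = alternative)
    res$t[k] <- unname(tt$statistic)
    res$p_raw[k] <- tt$p.value
  }
  res$p_raw <- stats::p.adjust(res$p_raw, method = p_adjust)
  res$detectable <- colMeans(ca) >= min_count & res$pct_assay >= min_prop_pct
  res$status <- ifelse(res$detectable, status, "below_floor")
  res$p_value <- ifelse(res$detectable, res$p_raw, NA_real_)
  res$significant <- res$detectable & !is.na(res$p_value) & res$p_value <= alpha
  res$n_replicates <- n
  structure(res, class = c("enrichment_table", "data.frame"),
            alpha = alpha, alternative = alternative,
            min_count = min_count, min_prop_pct = min_prop_pct,
            p_adjust = p_adjust)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Paired enrichment over %d replicates (one-tailed %s, alpha = %g; floor: count >= %d & %.2f%%)\n",
              x$n_replicates[1], attr(x, "alternative"), attr(x, "alpha"),
              attr(x, "min_count"), attr(x, "min_prop_pct")))
  df <- as.data.frame(x)
  df$pct_assay <- round(df$pct_assay, 2)
  df$pct_control <- round(df$pct_control, 2)
  df$mean_diff <- round(df$mean_diff, 2)
  df$t <- round(df$t, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df[, c("type", "pct_assay", "pct_control", "mean_diff", "t",
               "p_value", "status", "significant")], row.names = FALSE)
  invisible(x)
}

#' Assemble heatmap-ready enrichment matrices
#'
#' Aligns per-treatment enrichment tables into two matrices over
#' treatments x types: mean assay percentage and a significance tier
#' (0 = not significant or masked, then 1/2/3 for p <= 0.05 / 0.01 /
#' 0.001), the standard side-by-side display. Treatments must share one
#' type axis; rows and columns are ordered by a declared sort key so the
#' layout is stable under input permutation.
#'
#' @param tables Named list of [paired_enrichment_test()] results, one per
#'   treatment.
#' @param sort_types `"declared"` (first table's order) or `"alphabetical"`.
#' @return Object of class `enrichment_heatmap`: list with `mean_pct` and
#'   `significance` matrices.
#' @export
enrichment_heatmap <- function(tables, sort_types = c("declared", "alphabetical")) {
  sort_types <- match.arg(sort_types)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (one name per treatment)")
  type_sets <- lapply(tables, function(t) t$type)
  base <- type_sets[[1]]
  for (i in seq_along(type_sets)) {
    extra <- setdiff(type_sets[[i]], base)
    miss <- setdiff(base, type_sets[[i]])
    if (length(extra) || length(miss))
      stop("type sets differ for treatment '", names(tables)[i], "': ",
           if (length(extra)) paste("extra:", paste(extra, collapse = ", ")),
           if (length(miss)) paste(" missing:", paste(miss, collapse = ", ")))
  }
  types <- if (sort_types == "alphabetical") sort(base) else base
  treatments <- sort(names(tables))
  tier <- function(p) {
    ifelse(is.na(p), 0L, ifelse(p <= 0.001, 3L, ifelse(p <= 0.01, 2L,
           ifelse(p <= 0.05, 1L, 0L))))
  }
  mean_pct <- matrix(NA_real_, length(treatments), length(types))
  significance <- matrix(0L, length(treatments), length(types))
  for (i in seq_along(treatments)) {
    tab <- tables[[treatments[i]]]
    m <- match(types, tab$type)
    mean_pct[i, ] <- tab$pct_assay[m]
    significance[i, ] <- ifelse(tab$significant[m], tier(tab$p_value[m]), 0L)
  }
  dimnames(mean_pct) <- dimnames(significance) <- list(treatments, types)
  structure(list(mean_pct = mean_pct, significance = significance),
            class = "enrichment_heatmap")
}

#' @export
print.enrichment_heatmap <- function(x, ...) {
  cat("Enrichment heatmap:", nrow(x$mean_pct), "treatment(s) x",
      ncol(x$mean_pct), "type(s)\n")
  invisible(x)
}

#' @export
plot.enrichment_heatmap <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  draw <- function(m, main) {
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                    axes = FALSE, xlab = "", ylab = "", main = main,
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE))
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
  }
  draw(x$mean_pct, "mean % of cells")
  draw(x$significance, "significance tier")
  invisible(x)
}

#' Export an enrichment table to CSV
#'
#' @param x An `enrichment_table`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_enrichment_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
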