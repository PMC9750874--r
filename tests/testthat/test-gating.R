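tree <- load_gating_config()

test_that("the shipped gating tree has the standard taxonomy cardinalities", {
  expect_length(gating_leaves(tree), 17L)
  expect_length(gating_markers(tree), 13L)
  expect_setequal(gating_markers(tree), baseline_panel())
  expect_false("unclassified" %in% gating_leaves(tree))
})

test_that("malformed gating configs are rejected with informative errors", {
  cfg <- yaml::read_yaml(default_gating_config_path())
  dup <- cfg
  dup$tree[[length(dup$tree) + 1L]] <- list(label = "dendritic cell",
                                            gate = list(marker = "CD11c",
                                                        side = "above"))
  expect_error(load_gating_config(dup), "duplicate leaf.*dendritic cell")
  alien <- cfg
  alien$tree[[2]]$gate$marker <- "CD99"
  expect_error(load_gating_config(alien), "CD99")
  reserved <- cfg
  reserved$tree[[2]]$label <- "unclassified"
  expect_error(load_gating_config(reserved), "reserved")
})

test_that("classification follows the lineage hierarchy", {
  cell <- function(...) {
    row <- as.list(setNames(rep(0.05, 13), baseline_panel()))
    row[names(list(...))] <- list(...)
    as.data.frame(row)
  }
  tab <- rbind(
    cell(CD45 = 0.9, CD11b = 0.8, F480 = 0.8, CSF1R = 0.9, MHCII = 0.1),
    cell(CD11c = 0.9),
    cell(Epcam = 0.9),
    cell(CD45 = 0.9, CD3 = 0.8, CD8 = 0.9),
    cell(CD31 = 0.8, aSMA = 0.7),
    cell())
  tab[6, ] <- 0  # all-zero intensities
  got <- as.character(classify_cells(tab, tree))
  expect_equal(got, c("CSF1R+ MHC-II- macrophage", "dendritic cell",
                      "tumor (Epcam+)", "CD8 T cell", "pericyte",
                      "unclassified"))
})

test_that("standard labels partition every cell exactly once", {
  s <- generate_scene(scene_config(seed = 6))
  lab <- classify_cells(s$cells, tree)
  expect_equal(length(lab), nrow(s$cells))
  expect_true(all(!is.na(lab)))
  expect_setequal(levels(lab), c(gating_leaves(tree), "unclassified"))
  counts <- table(lab)
  expect_equal(sum(counts), nrow(s$cells))
})

test_that("classification is equivariant under row permutation", {
  s <- generate_scene(scene_config(seed = 14))
  lab <- classify_cells(s$cells, tree)
  perm <- sample(nrow(s$cells))
  expect_identical(classify_cells(s$cells[perm, ], tree), lab[perm])
})

test_that("missing marker columns are reported by name", {
  s <- generate_scene(scene_config(seed = 1))
  broken <- s$cells[, setdiff(names(s$cells), "Ly6G")]
  expect_error(classify_cells(broken, tree), "Ly6G")
})

test_that("polygon gates give standard point-in-polygon membership", {
  sq <- polygon_gate(c("CD4", "CD8"),
                     rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_true(evaluate_polygon_gate(sq, rbind(c(0.5, 0.5))))
  expect_false(evaluate_polygon_gate(sq, rbind(c(1.5, 0.5))))
})

test_that("polygon gate membership matches an independent point-in-polygon oracle", {
  set.seed(90)
  v <- rbind(c(0.1, 0.1), c(0.9, 0.2), c(0.7, 0.9), c(0.4, 0.6), c(0.15, 0.8))
  g <- polygon_gate(c("CD4", "CD8"), v)
  pts <- cbind(runif(1000), runif(1000))
  got <- evaluate_polygon_gate(g, pts)
  oracle <- as.logical(mgcv::in.out(rbind(v, v[1, ]), pts))
  expect_identical(got, oracle)
})

test_that("translating a gate around its central vertex translates membership", {
  v <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  g <- polygon_gate(c("CD4", "CD8"), v)
  set.seed(4)
  pts <- cbind(runif(300, -1, 3), runif(300, -1, 3))
  delta <- c(0.37, -0.41)
  g2 <- translate_gate(g, g$central_vertex + delta)
  expect_identical(evaluate_polygon_gate(g2, sweep(pts, 2, -delta)),
                   evaluate_polygon_gate(g, pts))
  expect_equal(g2$vertices - g$vertices,
               matrix(delta, nrow(v), 2, byrow = TRUE))
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_gate(c("CD4", "CD8"), bowtie), "self-intersecting")
})

test_that("control-derived thresholds separate a bimodal mixture", {
  set.seed(11)
  ctrl <- data.frame(m = c(rbeta(1600, 3, 19), rbeta(400, 15, 7)))
  thr <- threshold_from_control(ctrl, "m")
  expect_gt(thr, 0.15)  # above the negative mode
  expect_lt(thr, 0.65)  # below the positive mode
  expect_false(attr(thr, "no_positive_population"))
  # recovered positive fraction within two points of the planted 20%
  expect_lt(abs(mean(ctrl$m > thr) - 0.2), 0.02)
})

test_that("an all-negative control is flagged with a threshold above the data", {
  set.seed(12)
  neg <- data.frame(m = rbeta(1500, 3, 19))
  thr <- threshold_from_control(neg, "m")
  expect_true(attr(thr, "no_positive_population"))
  expect_gt(thr, max(neg$m))
})

test_that("degenerate controls and manual overrides behave as documented", {
  expect_error(threshold_from_control(data.frame(m = rep(0.3, 50)), "m"),
               "degenerate")
  thr <- threshold_from_control(data.frame(m = runif(10)), "m",
                                override = 0.42)
  expect_equal(as.numeric(thr), 0.42)
  expect_equal(attr(thr, "method"), "manual")
})

test_that("extended phenotypes are strict refinements of standard types", {
  defs <- load_phenotype_definitions()
  s <- generate_scene(scene_config(seed = 19))
  tab <- s$cells
  tab$PyMT <- runif(nrow(tab))
  tab$Ki67 <- runif(nrow(tab))
  tab$Sox9 <- runif(nrow(tab))
  lab <- classify_cells(tab, tree)
  flags <- classify_extended(tab, lab, defs)
  apn <- flags[, "antigen-presenting neutrophil"]
  expect_true(all(lab[apn] %in% c("neutrophil", "antigen-presenting neutrophil")))
  pdc <- flags[, "phagocytic DC"]
  expect_true(all(lab[pdc] == "dendritic cell"))
  # the shipped CSC pattern is the verbatim one (CD45+); the alternate flips it
  csc_def <- defs$csc
  m <- vapply(csc_def$pattern, `[[`, character(1), "marker")
  p <- vapply(csc_def$pattern, function(x) isTRUE(x$positive), logical(1))
  expect_true(p[m == "CD45"])
  expect_false(vapply(defs$csc_alt$pattern,
                      function(x) isTRUE(x$positive), logical(1))[m == "CD45"])
})
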