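test_that("assay region selection equals the sort-and-truncate oracle", {
  s <- generate_scene(scene_config(seed = 40))
  tab <- s$cells
  sel <- suppressWarnings(select_assay_region(tab, n_target = 500))
  above <- tab[tab$y_um > 0, ]
  d <- sqrt(above$x_um^2 + above$y_um^2)
  oracle_ids <- above$cell_id[order(d)][1:500]
  expect_identical(sel$cell_id, oracle_ids)
  expect_false(attr(sel, "shortfall"))
})

test_that("a shortfall returns all eligible cells and flags it", {
  tab <- data.frame(cell_id = 1:20,
                    x_um = runif(20, -50, 50),
                    y_um = c(runif(12, 1, 100), runif(8, -100, -1)))
  expect_warning(sel <- select_assay_region(tab, n_target = 3000),
                 "shortfall")
  expect_equal(nrow(sel), 12L)
  expect_true(attr(sel, "shortfall"))
  expect_error(suppressWarnings(select_assay_region(tab, n_target = 0)),
               "positive")
})

test_that("exclusion masks remove deformed-region cells before selection", {
  tab <- data.frame(cell_id = 1:100, x_um = rep(0, 100), y_um = 1:100)
  sel <- suppressWarnings(
    select_assay_region(tab, n_target = 10,
                        exclusion = tab$cell_id <= 5))
  expect_identical(sel$cell_id, 6:15)
})

test_that("region pairing enforces the 300-cell matching window", {
  a <- data.frame(cell_id = 1:4000, x_um = 0, y_um = 1)
  c1 <- data.frame(cell_id = 1:3800, x_um = 0, y_um = 1)
  c2 <- data.frame(cell_id = 1:3600, x_um = 0, y_um = 1)
  expect_true(region_pair(a, c1)$pairing_valid)
  expect_false(region_pair(a, c2)$pairing_valid)
})

test_that("profiles are flat for uniform composition and sum to one per bin", {
  s <- generate_null_scene(scene_config(arena = c(-800, 800, 0, 1600),
                                        background_density = 2e-3, seed = 44))
  tab <- s$cells
  tab$label <- factor(s$truth$type)
  prof <- profile_curve(tab, "label", bin_width = 100, max_distance = 800)
  sums <- rowSums(prof$raw)
  expect_true(all(abs(sums[prof$n_per_bin > 0] - 1) < 1e-9))
  tumor <- prof$raw[, "tumor (Epcam+)"]
  n <- prof$n_per_bin
  p <- 0.55
  ok <- n > 0
  expect_true(all(abs(tumor[ok] - p) < 4 * sqrt(p * (1 - p) / n[ok]) + 0.02))
})

test_that("a one-bin moving average with no blur is the identity", {
  s <- generate_null_scene(scene_config(seed = 45))
  tab <- s$cells
  tab$label <- factor(s$truth$type)
  prof <- profile_curve(tab, "label", bin_width = 50, sigma = 0, window = 50,
                        max_distance = 600)
  expect_equal(prof$smooth, prof$raw, tolerance = 1e-12)
})

test_that("smoothed profiles of recruited cells decrease away from the well", {
  sc <- scene_config(arena = c(-700, 700, 0, 700), background_density = 1e-3,
                     cell_types = list(
                       list(label = "tumor (Epcam+)", fraction = 1,
                            markers = "Epcam"),
                       list(label = "dendritic cell", fraction = 0,
                            markers = c("CD45", "CD11c"))),
                     gradients = list(list(label = "dendritic cell",
                                           amplitude = 2e-2,
                                           decay_length = 150)),
                     seed = 46)
  s <- generate_scene(sc)
  tab <- s$cells
  tab$label <- factor(s$truth$type)
  prof <- profile_curve(tab, "label", bin_width = 50, window = 100,
                        max_distance = 600)
  dc <- prof$smooth[, "dendritic cell"]
  within_3L <- prof$distance_um <= 450
  expect_true(all(diff(dc[within_3L]) < 0))
})

test_that("empty distance bins become gaps, not zeros", {
  tab <- data.frame(cell_id = 1:40,
                    x_um = 0,
                    y_um = c(runif(20, 1, 100), runif(20, 301, 400)),
                    label = "a")
  prof <- profile_curve(tab, "label", bin_width = 100, sigma = 0, window = 100,
                        max_distance = 400, release_side_only = TRUE)
  expect_true(all(is.na(prof$raw[2:3, ])))
  expect_false(anyNA(prof$raw[c(1, 4), ]))
})

test_that("ROI sampling is reproducible and respects the region boundary", {
  box <- c(0, 1000, 0, 600)
  r1 <- sample_rois(box, diameter = 175, n = 6, seed = 9)
  r2 <- sample_rois(box, diameter = 175, n = 6, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1[, 1] >= 87.5 & r1[, 1] <= 912.5))
  expect_true(all(r1[, 2] >= 87.5 & r1[, 2] <= 512.5))
  tri <- rbind(c(0, 0), c(400, 0), c(200, 350))
  rp <- sample_rois(tri, diameter = 100, n = 5, seed = 2)
  for (i in 1:5) {
    expect_true(mgcv::in.out(rbind(tri, tri[1, ]), rp[i, , drop = FALSE]))
    edges <- rbind(tri, tri[1, ])
    for (e in 1:3) {
      d <- imdassay:::dist_point_segment(rp[i, 1], rp[i, 2],
                                         edges[e, 1], edges[e, 2],
                                         edges[e + 1, 1], edges[e + 1, 2])
      expect_gte(d, 50)
    }
  }
  expect_error(sample_rois(c(0, 100, 0, 100), diameter = 175, n = 1),
               "too small")
})

test_that("ROI centers are uniform over the eroded region", {
  rois <- sample_rois(c(0, 800, 0, 800), diameter = 100, n = 10000, seed = 3)
  # chi-square over a 4 x 4 partition of the eroded square [50, 750]^2
  gx <- cut(rois[, 1], seq(50, 750, length.out = 5))
  gy <- cut(rois[, 2], seq(50, 750, length.out = 5))
  tab <- table(gx, gy)
  p <- stats::chisq.test(as.vector(tab))$p.value
  expect_gt(p, 0.001)
})

test_that("pairwise proximity handles the canonical single-pair cases", {
  r1 <- pairwise_proximity(rbind(c(0, 0)), rbind(c(0, 10)), cutoff = 50)
  expect_equal(r1$proportion_below, 1)
  expect_equal(r1$n_pairs, 1L)
  r2 <- pairwise_proximity(rbind(c(0, 0)), rbind(c(0, 100)), cutoff = 50)
  expect_equal(r2$proportion_below, 0)
  expect_error(pairwise_proximity(matrix(numeric(0), ncol = 2),
                                  rbind(c(0, 0))), "setA")
  expect_error(pairwise_proximity(rbind(c(0, 0)),
                                  matrix(numeric(0), ncol = 2)), "setB")
})

test_that("proximity statistics equal a double loop and are symmetric", {
  set.seed(50)
  a <- cbind(runif(30, 0, 300), runif(30, 0, 300))
  b <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  got <- pairwise_proximity(a, b, cutoff = 50)
  oracle <- oracle_proximity(a, b, 50)
  expect_equal(got$n_pairs, 30L * 40L)
  expect_equal(got$proportion_below, oracle$prop)
  expect_equal(got$counts,
               graphics::hist(oracle$d, breaks = got$breaks,
                              plot = FALSE)$counts)
  swapped <- pairwise_proximity(b, a, cutoff = 50)
  expect_equal(swapped$proportion_below, got$proportion_below)
  expect_equal(swapped$n_pairs, got$n_pairs)
})
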