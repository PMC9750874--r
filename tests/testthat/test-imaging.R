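test_that("AEC yellow extraction handles the canonical pixels", {
  px <- function(r, g, b) array(c(r, g, b) / 255, dim = c(1, 1, 3))
  expect_equal(as.numeric(extract_aec_yellow(px(255, 255, 255))), 0)
  expect_equal(as.numeric(extract_aec_yellow(px(255, 255, 0))), 1)
  expect_equal(as.numeric(extract_aec_yellow(px(0, 0, 0))), 0)  # K = 1 case
  expect_equal(as.numeric(extract_aec_yellow(px(128, 128, 128))), 0)  # gray
})

test_that("AEC yellow equals the closed-form CMYK formula on random pixels", {
  set.seed(5)
  img <- array(runif(40 * 30 * 3), dim = c(40, 30, 3))
  got <- extract_aec_yellow(img)
  oracle <- matrix(NA_real_, 40, 30)
  for (i in 1:40) for (j in 1:30) {
    r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
    k <- 1 - max(r, g, b)
    oracle[i, j] <- if (k >= 1) 0 else (1 - b - k) / (1 - k)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("stain deconvolution inverts the Beer-Lambert model", {
  m <- default_stain_matrix()
  white <- array(1, dim = c(1, 1, 3))
  expect_lt(max(abs(deconvolve_stains(white))), 1e-5)
  # a pixel synthesized as pure hematoxylin at OD 1 comes back as (1, 0, 0)
  pure <- array(10^(-m[1, ]), dim = c(1, 1, 3))
  conc <- deconvolve_stains(pure)
  expect_equal(as.numeric(conc[1, 1, 1]), 1, tolerance = 1e-6)
  expect_lt(max(abs(conc[1, 1, 2:3])), 1e-6)
  expect_error(deconvolve_stains(white, matrix(1, 3, 3)), "singular")
})

test_that("deconvolution matches a per-pixel linear-algebra oracle", {
  set.seed(6)
  img <- array(runif(15 * 12 * 3, 0.05, 1), dim = c(15, 12, 3))
  m <- default_stain_matrix()
  got <- deconvolve_stains(img)
  for (i in c(1, 7, 15)) for (j in c(1, 5, 12)) {
    od <- -log10(pmax(img[i, j, ], 1e-6))
    expect_equal(as.numeric(got[i, j, ]), as.numeric(qr.solve(t(m), od)),
                 tolerance = 1e-9)
  }
})

make_blob_image <- function(centers, dims = c(120, 120), sigma = 2.7, A = 0.9) {
  m <- matrix(0, dims[1], dims[2])
  rs <- row(m); cs <- col(m)
  for (k in seq_len(nrow(centers)))
    m <- m + A * exp(-((rs - centers[k, 1])^2 + (cs - centers[k, 2])^2) /
                       (2 * sigma^2))
  m
}

test_that("well-separated nuclei are each segmented once", {
  centers <- as.matrix(expand.grid(seq(15, 105, by = 18), seq(15, 105, by = 18)))
  img <- make_blob_image(centers)
  mk <- segment_nuclei(img)
  expect_equal(mk$n, nrow(centers))
})

test_that("blank images give empty masks, not errors", {
  mk <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(mk$n, 0L)
  expect_true(all(mk$labels == 0L))
})

test_that("a touching nucleus pair is split into two labels", {
  img <- make_blob_image(rbind(c(20, 17), c(20, 23)), dims = c(40, 40))
  mk <- segment_nuclei(img)
  expect_equal(mk$n, 2L)
})

test_that("per-cell means follow the dtype-maximum scaling contract", {
  img <- make_blob_image(rbind(c(10, 10), c(30, 30)), dims = c(40, 40))
  mk <- segment_nuclei(img)
  uniform <- matrix(0.5, 40, 40)
  tab <- measure_cells(mk, list(m = uniform))
  expect_equal(tab$m, rep(0.5, mk$n))
  eight_bit <- matrix(255L, 40, 40)
  tab8 <- measure_cells(mk, list(m = eight_bit))
  expect_equal(tab8$m, rep(1, mk$n))
  expect_error(measure_cells(mk, list(m = matrix(0, 10, 10))), "dimensions")
})

test_that("per-cell means equal a brute-force pixel loop and survive relabeling", {
  img <- make_blob_image(rbind(c(12, 14), c(30, 8), c(22, 30)),
                         dims = c(40, 40))
  mk <- segment_nuclei(img)
  set.seed(8)
  channel <- matrix(runif(40 * 40), 40, 40)
  tab <- measure_cells(mk, list(m = channel))
  expect_equal(tab$m, oracle_label_means(mk$labels, channel),
               tolerance = 1e-12)
  # permuting label ids must not change which pixels belong to which cell
  perm <- sample(mk$n)
  mk2 <- mk
  mk2$labels[mk$labels > 0L] <- perm[mk$labels[mk$labels > 0L]]
  mk2$centroids <- mk$centroids[order(perm), , drop = FALSE]
  tab2 <- measure_cells(mk2, list(m = channel))
  expect_equal(sort(tab2$m), sort(tab$m), tolerance = 1e-12)
})

test_that("binary coverage equals an independent pixel count", {
  set.seed(9)
  signal <- matrix(runif(30 * 30), 30, 30)
  region <- matrix(TRUE, 30, 30)
  expect_equal(binary_coverage(signal, region, -1), 1)
  expect_equal(binary_coverage(signal, region, 2), 0)
  thr <- 0.6
  cnt <- 0L; tot <- 0L
  sub <- matrix(FALSE, 30, 30); sub[5:20, 8:25] <- TRUE
  for (i in 1:30) for (j in 1:30) if (sub[i, j]) {
    tot <- tot + 1L
    if (signal[i, j] > thr) cnt <- cnt + 1L
  }
  expect_equal(binary_coverage(signal, sub, thr), cnt / tot)
  expect_error(binary_coverage(signal, matrix(FALSE, 30, 30), 0.5), "empty")
})

test_that("round registration recovers identity and constructed shifts", {
  s <- generate_scene(scene_config(arena = c(-150, 150, -150, 150),
                                   background_density = 5e-4,
                                   upper_half_only = FALSE, seed = 2))
  img <- render_chromogenic(s, params = render_params(pixel_size_um = 1))$hematoxylin
  reg0 <- register_rounds(list(img, img))
  expect_lt(abs(reg0$transforms[[2]][3, 1]), 0.1)
  expect_lt(abs(reg0$transforms[[2]][3, 2]), 0.1)
  # shift by (5, 3) px (columns right, rows down)
  h <- dim(img)[1]; w <- dim(img)[2]
  mov <- array(1, dim = dim(img))
  mov[4:h, 6:w, ] <- img[1:(h - 3), 1:(w - 5), ]
  reg <- register_rounds(list(img, mov))
  expect_lt(abs(reg$transforms[[2]][3, 1] - (-5)), 1)
  expect_lt(abs(reg$transforms[[2]][3, 2] - (-3)), 1)
  expect_lt(reg$residuals_px[2], 1)
  # the resampled round overlays the reference
  warped <- reg$aligned[[2]]
  expect_lt(mean(abs(warped[10:(h - 10), 10:(w - 10), 1] -
                     img[10:(h - 10), 10:(w - 10), 1])), 0.02)
})

test_that("featureless rounds raise a registration failure", {
  set.seed(10)
  a <- array(runif(80 * 80 * 3), dim = c(80, 80, 3))
  b <- array(runif(80 * 80 * 3), dim = c(80, 80, 3))
  expect_error(register_rounds(list(a, b)), "registration failure")
})

test_that("rendered truth-positive cells show higher extracted AEC yellow", {
  s <- generate_scene(scene_config(arena = c(-150, 150, -150, 150),
                                   background_density = 5e-4,
                                   upper_half_only = FALSE, seed = 3))
  r <- render_chromogenic(s, markers = "CD45",
                          params = render_params(pixel_size_um = 1))
  yel <- extract_aec_yellow(r$aec$CD45)
  pos_mask <- r$mask %in% s$cells$cell_id[s$truth$pos_CD45]
  neg_mask <- r$mask %in% s$cells$cell_id[!s$truth$pos_CD45] & r$mask > 0
  expect_gt(mean(yel[pos_mask]), mean(yel[matrix(neg_mask, nrow(yel))]))
  # the mask labels the scene rows one to one
  expect_setequal(setdiff(unique(as.vector(r$mask)), 0L), s$cells$cell_id)
})

test_that("an empty scene renders to a blank image and empty mask", {
  sc <- scene_config(arena = c(0, 50, 0, 50), background_density = 1e-9,
                     upper_half_only = FALSE, seed = 1)
  s <- generate_scene(sc)
  s$cells <- s$cells[0, ]
  s$truth <- s$truth[0, ]
  r <- render_chromogenic(s, params = render_params(pixel_size_um = 1))
  expect_true(all(r$mask == 0L))
  expect_true(all(abs(r$hematoxylin - 1) < 1e-12))
})
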