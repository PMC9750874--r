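#' Co-register chromogenic image rounds
#'
#' Feature-based alignment of iteratively stained rounds to a reference
#' round: blob features (nuclear-scale objects) are detected in each round,
#' matched to the reference by iterative closest point, and a rigid
#' transform is estimated (Kabsch); if the rigid residual exceeds
#' `max_residual_px` the model escalates to affine. Transforms are returned
#' for audit alongside the residual displacement of matched features.
#'
#' @param rounds List of RGB arrays (or `H x W` gray matrices), all the same
#'   dimensions.
#' @param reference Index of the reference round.
#' @param min_features Minimum matched features; fewer is a registration
#'   failure.
#' @param max_residual_px Residual (px) above which rigid escalates to
#'   affine, and above which (post-affine) registration fails.
#' @return List with `aligned` (list of arrays resampled onto the reference
#'   grid), `transforms` (list of 3 x 2 matrices mapping round pixel
#'   coordinates `(x, y, 1)` to reference coordinates), `residuals_px` and
#'   `models` (`"identity"`, `"rigid"` or `"affine"`).
#' @export
register_rounds <- function(rounds, reference = 1L, min_features = 6L,
                            max_residual_px = 5) {
  if (length(rounds) < 2L) stop("need at least two rounds to register")
  dims <- lapply(rounds, function(r) dim(r)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all rounds must share dimensions")
  feats <- lapply(seq_along(rounds), function(i) {
    f <- detect_blob_features(rounds[[i]])
    if (nrow(f) < min_features)
      stop("registration failure: insufficient features in round ", i)
    f
  })
  ref <- feats[[reference]]
  out <- list(aligned = vector("list", length(rounds)),
              transforms = vector("list", length(rounds)),
              residuals_px = numeric(length(rounds)),
              models = character(length(rounds)))
  for (i in seq_along(rounds)) {
    if (i == reference) {
      out$aligned[[i]] <- rounds[[i]]
      out$transforms[[i]] <- rbind(diag(2), c(0, 0))
      out$residuals_px[i] <- 0
      out$models[i] <- "identity"
      next
    }
    est <- estimate_transform(feats[[i]], ref, min_features, max_residual_px)
    if (est$residual > max_residual_px)
      stop("registration failure: residual ", round(est$residual, 2),
           " px in round ", i)
    out$transforms[[i]] <- est$m
    out$residuals_px[i] <- est$residual
    out$models[i] <- est$model
    out$aligned[[i]] <- warp_to_reference(rounds[[i]], est$m)
  }
  out
}

# Blob features: threshold the darkness of the round (1 - gray), label
# connected components, return centroids (x = col, y = row) of objects in a
# nuclear size range.
detect_blob_features <- function(image, min_area = 6L, max_area = 2000L) {
  gray <- if (length(dim(image)) == 3L) {
    img <- normalise_rgb(image)
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else as.matrix(image)
  dark <- max(gray) - gray
  if (max(dark) - min(dark) < 1e-8)
    return(matrix(numeric(0), ncol = 2))
  thr <- otsu_threshold(dark, range = range(dark))
  bw <- EBImage::Image(t(dark > thr) * 1)
  bw <- EBImage::opening(bw, EBImage::makeBrush(3L, shape = "disc"))
  lab <- t(EBImage::imageData(EBImage::bwlabel(bw)))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(matrix(numeric(0), ncol = 2))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (!length(keep)) return(matrix(numeric(0), ncol = 2))
  idx <- which(lab > 0L)
  l <- lab[idx]
  sel <- l %in% keep
  idx <- idx[sel]; l <- l[sel]
  row <- (idx - 1L) %% nrow(lab) + 1L
  col <- (idx - 1L) %/% nrow(lab) + 1L
  cbind(x = as.numeric(tapply(col, l, mean)),
        y = as.numeric(tapply(row, l, mean)))
}

# ICP: translate-initialise on feature centroids, iterate nearest-neighbour
# matching + Kabsch rigid estimation; escalate to affine least squares when
# the rigid residual stays above the tolerance.
estimate_transform <- function(moving, ref, min_features, max_residual_px) {
  kabsch <- function(a, b) {
    # rigid a -> b
    ca <- colMeans(a); cb <- colMeans(b)
    h <- t(sweep(a, 2, ca)) %*% sweep(b, 2, cb)
    s <- svd(h)
    r <- s$v %*% t(s$u)
    if (det(r) < 0) {
      s$v[, 2] <- -s$v[, 2]
      r <- s$v %*% t(s$u)
    }
    list(r = r, t = cb - as.numeric(r %*% ca))
  }
  apply_rt <- function(p, rt) sweep(p %*% t(rt$r), 2, -rt$t)
  rt <- list(r = diag(2), t = colMeans(ref) - colMeans(moving))
  matched <- NULL
  for (iter in 1:30) {
    cur <- apply_rt(moving, rt)
    nn <- nearest_neighbours(cur, ref)
    trim <- nn$dist <= max(3 * stats::median(nn$dist), 1e-6)
    if (sum(trim) < min_features) break
    matched <- list(a = moving[trim, , drop = FALSE],
                    b = ref[nn$index[trim], , drop = FALSE])
    rt_new <- kabsch(matched$a, matched$b)
    delta <- max(abs(rt_new$r - rt$r)) + max(abs(rt_new$t - rt$t))
    rt <- rt_new
    if (delta < 1e-8) break
  }
  if (is.null(matched) || nrow(matched$a) < min_features)
    stop("registration failure: insufficient matched features")
  resid <- function(pred, b) mean(sqrt(rowSums((pred - b)^2)))
  pred <- apply_rt(matched$a, rt)
  r_rigid <- resid(pred, matched$b)
  m <- rbind(t(rt$r), rt$t)
  model <- "rigid"
  if (r_rigid > max_residual_px) {
    # affine least squares on the matched pairs
    x <- cbind(matched$a, 1)
    beta <- tryCatch(solve(t(x) %*% x, t(x) %*% matched$b),
                     error = function(e) NULL)
    if (!is.null(beta)) {
      r_aff <- resid(x %*% beta, matched$b)
      if (r_aff < r_rigid) {
        m <- beta
        model <- "affine"
        r_rigid <- r_aff
      }
    }
  }
  list(m = m, residual = r_rigid, model = model,
       n_matched = nrow(matched$a))
}

nearest_neighbours <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  index <- max.col(-d2, ties.method = "first")
  list(index = index, dist = sqrt(d2[cbind(seq_len(nrow(a)), index)]))
}

# Resample a round onto the reference grid given the 3 x 2 forward transform
# (moving px -> reference px); nearest-neighbour interpolation.
warp_to_reference <- function(image, m) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  # invert the affine map: reference -> moving
  a <- rbind(cbind(t(m[1:2, ]), m[3, ]), c(0, 0, 1))
  inv <- solve(a)
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w), 1)
  src <- grid %*% t(inv)
  sx <- round(src[, 1]); sy <- round(src[, 2])
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  take <- function(plane) {
    out <- matrix(0, h, w)
    out[cbind(grid[ok, 2], grid[ok, 1])] <- plane[cbind(sy[ok], sx[ok])]
    out
  }
  if (length(d) == 3L) {
    out <- array(0, dim = d)
    for (k in seq_len(d[3])) out[, , k] <- take(image[, , k])
    out
  } else take(as.matrix(image))
}
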