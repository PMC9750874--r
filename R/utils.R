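# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded operations (scene generation, ROI sampling) do not perturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to run unseeded.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# points argument normalisation: accepts an n x 2 matrix, a data.frame with
# x/y or x_um/y_um columns, and returns an n x 2 numeric matrix.
as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_um", "y_um") %in% names(points)))
      points <- cbind(points$x_um, points$y_um)
    else if (all(c("x", "y") %in% names(points)))
      points <- cbind(points$x, points$y)
    else stop("data.frame points must have columns x_um/y_um or x/y")
  }
  points <- as.matrix(points)
  if (length(points) == 0L) return(matrix(numeric(0), ncol = 2))
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix of coordinates")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  unname(points)
}

#' 1-D Otsu threshold
#'
#' Histogram-based two-class threshold minimising intra-class intensity
#' variance, computed on a fixed-range histogram so results are comparable
#' across samples.
#'
#' @param x Numeric vector of intensities.
#' @param n_bins Number of histogram bins.
#' @param range Intensity range spanned by the histogram.
#' @return Threshold on the scale of `x` (a bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256L, range = c(0, 1)) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to threshold")
  if (diff(range(x)) < .Machine$double.eps)
    stop("degenerate distribution: all intensities are equal")
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  edges[k + 1L]
}

# Ray-casting point-in-polygon (even-odd rule), vectorised over points.
# Points exactly on an edge are resolved by the crossing parity and are not
# guaranteed either way; gates should not place cells on polygon borders.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

# Proper-crossing test for two closed segments; shared endpoints of adjacent
# polygon edges are not counted as intersections.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  if (n < 3L) return(FALSE)
  seg <- function(i) list(c(vx[i], vy[i]),
                          c(vx[i %% n + 1L], vy[i %% n + 1L]))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      a <- seg(i); b <- seg(j)
      if (segments_cross(a[[1]], a[[2]], b[[1]], b[[2]])) return(FALSE)
    }
  }
  TRUE
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- pmax(vx^2 + vy^2, .Machine$double.xmin)
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

# md5 of a canonical (sorted-key JSON) serialisation; used for provenance.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
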