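#' Implantable microdevice geometry
#'
#' Describes the cylindrical drug-delivery implant: a resin cylinder whose
#' outer surface carries open reservoirs ("wells") that each release one drug
#' or drug combination into the surrounding tissue by passive diffusion.
#' Defaults are the manufactured geometry: a 5.5 mm x 750 um cylinder with 18
#' reservoirs of 200 um diameter x 250 um depth. All lengths are micrometers.
#'
#' @param length Device length (um).
#' @param diameter Device diameter (um).
#' @param n_reservoirs Number of drug reservoirs.
#' @param reservoir_diameter Reservoir opening diameter (um).
#' @param reservoir_depth Reservoir depth (um).
#' @return An object of class `device_geometry`.
#' @examples
#' device_geometry()
#' @export
device_geometry <- function(length = 5500, diameter = 750, n_reservoirs = 18L,
                            reservoir_diameter = 200, reservoir_depth = 250) {
  vals <- c(length = length, diameter = diameter,
            reservoir_diameter = reservoir_diameter,
            reservoir_depth = reservoir_depth)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all device dimensions must be positive and finite")
  n_reservoirs <- as.integer(n_reservoirs)
  if (is.na(n_reservoirs) || n_reservoirs < 1L)
    stop("n_reservoirs must be a positive integer")
  structure(list(length = length, diameter = diameter,
                 n_reservoirs = n_reservoirs,
                 reservoir_diameter = reservoir_diameter,
                 reservoir_depth = reservoir_depth),
            class = "device_geometry")
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("Microdevice: %.0f um x %.0f um cylinder, %d reservoirs (%.0f um dia x %.0f um deep)\n",
              x$length, x$diameter, x$n_reservoirs,
              x$reservoir_diameter, x$reservoir_depth))
  invisible(x)
}

#' Systemic-dose to reservoir-concentration calibration table
#'
#' The reservoir drug load is calibrated so that the local tissue exposure
#' recapitulates a systemic dose: doses of 0-1, 1-2, 2-4 and >4 mg/kg
#' translate to 20, 25, 30 and 40 percent drug in the PEG carrier. Shared
#' band endpoints are resolved lower-inclusive/upper-exclusive, except that
#' 4 mg/kg belongs to the 30% band because the last band is strictly
#' ">4 mg/kg".
#'
#' @return A `data.frame` with columns `dose_low`, `dose_high`, `low_open`,
#'   `high_closed` and `peg_percent`, one row per contiguous band covering
#'   `[0, Inf)`.
#' @export
default_dose_bands <- function() {
  data.frame(
    dose_low    = c(0, 1, 2, 4),
    dose_high   = c(1, 2, 4, Inf),
    low_open    = c(FALSE, FALSE, FALSE, TRUE),
    high_closed = c(FALSE, FALSE, TRUE, FALSE),
    peg_percent = c(20, 25, 30, 40)
  )
}

validate_dose_bands <- function(table) {
  req <- c("dose_low", "dose_high", "low_open", "high_closed", "peg_percent")
  if (!all(req %in% names(table)))
    stop("dose band table must have columns: ", paste(req, collapse = ", "))
  o <- order(table$dose_low)
  table <- table[o, , drop = FALSE]
  if (table$dose_low[1] != 0 || table$low_open[1])
    stop("dose bands must start at a closed 0")
  if (!is.infinite(table$dose_high[nrow(table)]))
    stop("dose bands must be open-ended")
  n <- nrow(table)
  if (n > 1L) {
    if (any(table$dose_high[-n] != table$dose_low[-1]))
      stop("dose bands must be contiguous")
    # at each interior edge exactly one of the adjoining bands owns the point
    owns_upper <- table$high_closed[-n]
    owns_lower <- !table$low_open[-1]
    if (any(owns_upper == owns_lower))
      stop("dose band endpoints must be owned by exactly one band")
  }
  table
}

#' Map a systemic dose to the reservoir PEG drug concentration
#'
#' A monotone non-decreasing step function of dose. Vectorised.
#'
#' @param dose Systemic dose(s) in mg/kg; must be non-negative.
#' @param table Band table as produced by [default_dose_bands()].
#' @return Percent drug in PEG for each dose.
#' @examples
#' dose_to_peg_fraction(c(0.5, 1, 3, 10))  # 20 25 30 40
#' @export
dose_to_peg_fraction <- function(dose, table = default_dose_bands()) {
  table <- validate_dose_bands(table)
  if (any(!is.finite(dose) & !is.infinite(dose)) || any(dose < 0))
    stop("dose must be non-negative (mg/kg)")
  vapply(dose, function(d) {
    hit <- (d > table$dose_low | (!table$low_open & d == table$dose_low)) &
           (d < table$dose_high | (table$high_closed & d == table$dose_high))
    table$peg_percent[which(hit)[1]]
  }, numeric(1))
}

#' Well-centered coordinate frame
#'
#' A rigid frame that places the drug-releasing well at the origin with the
#' release direction along +y, the convention used by every downstream
#' spatial analysis ("coordinate [0,0] identifies the drug source; release is
#' upward").
#'
#' @param well_center Well position `(x, y)` in image coordinates (um).
#' @param release_direction Direction of drug release; normalised internally.
#' @return An object of class `well_frame`.
#' @export
well_frame <- function(well_center = c(0, 0), release_direction = c(0, 1)) {
  well_center <- as.numeric(well_center)
  release_direction <- as.numeric(release_direction)
  if (length(well_center) != 2L || any(!is.finite(well_center)))
    stop("well_center must be a finite (x, y) pair")
  nrm <- sqrt(sum(release_direction^2))
  if (length(release_direction) != 2L || !is.finite(nrm) || nrm < 1e-12)
    stop("release_direction must be a non-zero (x, y) vector")
  structure(list(well_center = well_center,
                 release_direction = release_direction / nrm),
            class = "well_frame")
}

#' @export
print.well_frame <- function(x, ...) {
  cat(sprintf("Well frame: center (%.1f, %.1f) um, release direction (%.3f, %.3f)\n",
              x$well_center[1], x$well_center[2],
              x$release_direction[1], x$release_direction[2]))
  invisible(x)
}

#' Transform points into the well frame
#'
#' Applies the rigid (distance-preserving) transform that maps the well
#' center to `(0, 0)` and the release direction to `+y`.
#'
#' @param points An n x 2 matrix (um) or a data.frame with `x_um`/`y_um`
#'   (or `x`/`y`) columns.
#' @param frame A [well_frame()].
#' @return An n x 2 matrix of well-frame coordinates (um); for data.frame
#'   input, the same data.frame with `x_um`/`y_um` replaced.
#' @export
to_well_frame <- function(points, frame) {
  if (!inherits(frame, "well_frame")) stop("frame must be a well_frame")
  df <- if (is.data.frame(points)) points else NULL
  p <- as_point_matrix(points)
  u <- frame$release_direction
  # rotation taking u to (0, 1); proper since |u| = 1
  rot <- matrix(c(u[2], -u[1], u[1], u[2]), 2, 2, byrow = TRUE)
  out <- sweep(p, 2, frame$well_center) %*% t(rot)
  if (!is.null(df)) {
    xcol <- if ("x_um" %in% names(df)) "x_um" else "x"
    ycol <- if ("y_um" %in% names(df)) "y_um" else "y"
    df[[xcol]] <- out[, 1]
    df[[ycol]] <- out[, 2]
    return(df)
  }
  out
}
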