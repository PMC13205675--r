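#' AFM height map
#'
#' Grid of surface heights from AFM force mapping. `NA` entries mark masked
#' points and are excluded from all statistics.
#'
#' @param Z Numeric matrix of heights.
#' @param pixel_spacing Grid spacing in micrometres.
#' @param units Height unit label (default "nm").
#' @return Object of class `height_map`.
#' @export
height_map <- function(Z, pixel_spacing = 5, units = "nm") {
  Z <- as.matrix(Z)
  if (!length(Z)) stop("height_map: empty grid", call. = FALSE)
  if (any(is.infinite(Z))) stop("height_map: heights must be finite or NA", call. = FALSE)
  structure(list(Z = Z, pixel_spacing = as.numeric(pixel_spacing), units = units),
            class = "height_map")
}

#' AFM Young's-modulus map
#'
#' @param E Numeric matrix of Young's moduli in kPa; entries must be
#'   non-negative (or NA for masked points).
#' @param pixel_spacing Grid spacing in micrometres.
#' @return Object of class `stiffness_map`.
#' @export
stiffness_map <- function(E, pixel_spacing = 5) {
  E <- as.matrix(E)
  if (!length(E)) stop("stiffness_map: empty grid", call. = FALSE)
  if (any(is.infinite(E)) || any(E < 0, na.rm = TRUE)) {
    stop("stiffness_map: moduli must be finite and >= 0", call. = FALSE)
  }
  structure(list(E = E, pixel_spacing = as.numeric(pixel_spacing)),
            class = "stiffness_map")
}

#' Surface roughness Sa of a height map
#'
#' Dispersion of surface heights about the mean height Z_avg over the N
#' unmasked grid points. Two renderings are provided: the root-mean-square
#' deviation `sqrt(mean((Z - Z_avg)^2))` (default, `variant = "rms"`) and
#' the ISO arithmetic-mean deviation `mean(|Z - Z_avg|)`
#' (`variant = "mean_abs"`). The rms reading is the default because a plain
#' mean of squared deviations would carry squared length units.
#'
#' @param map A `height_map` (or bare numeric matrix).
#' @param variant `"rms"` or `"mean_abs"`.
#' @return Object of class `roughness_result`: `sa`, `n_points`, `z_avg`,
#'   `formula_variant`, `masked_fraction`.
#' @export
compute_sa <- function(map, variant = c("rms", "mean_abs")) {
  variant <- match.arg(variant)
  Z <- if (inherits(map, "height_map")) map$Z else as.matrix(map)
  z <- Z[!is.na(Z)]
  if (!length(z)) stop("compute_sa: empty or fully masked map", call. = FALSE)
  z_avg <- mean(z)
  dev <- z - z_avg
  sa <- switch(variant,
               rms = sqrt(mean(dev^2)),
               mean_abs = mean(abs(dev)))
  structure(list(sa = sa, n_points = length(z), z_avg = z_avg,
                 formula_variant = variant,
                 masked_fraction = 1 - length(z) / length(Z)),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("<roughness_result> Sa = %.6g (%s) over N = %d points, Z_avg = %.6g\n",
              x$sa, x$formula_variant, x$n_points, x$z_avg))
  invisible(x)
}

#' Check the invariance properties of Sa
#'
#' Sa is translation-invariant (`Sa(Z + d) = Sa(Z)`) and absolutely
#' homogeneous (`Sa(c * Z) = |c| * Sa(Z)`). Both are asserted for both
#' formula variants to a relative tolerance of 1e-9.
#'
#' @param map A `height_map`.
#' @param c Scale factor.
#' @param d Height offset.
#' @return `data.frame` report with one row per (variant, property);
#'   column `ok` indicates whether the identity held.
#' @export
sa_properties_check <- function(map, c = 2.5, d = 10) {
  stopifnot(inherits(map, "height_map"))
  rows <- list()
  for (v in c("rms", "mean_abs")) {
    base <- compute_sa(map, v)$sa
    shifted <- compute_sa(height_map(map$Z + d, map$pixel_spacing, map$units), v)$sa
    scaled <- compute_sa(height_map(map$Z * c, map$pixel_spacing, map$units), v)$sa
    tol <- 1e-9 * max(base, .Machine$double.eps)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, property = "translation", expected = base, observed = shifted,
      ok = abs(shifted - base) <= tol)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, property = "homogeneity", expected = abs(c) * base, observed = scaled,
      ok = abs(scaled - abs(c) * base) <= 1e-9 * max(abs(c) * base, .Machine$double.eps))
  }
  do.call(rbind, rows)
}

#' Summary statistics of a Young's-modulus map
#'
#' Masked-aware location and spread statistics plus a histogram, in kPa.
#'
#' @param map A `stiffness_map`.
#' @param breaks Histogram bin edges in kPa, or a rule accepted by
#'   [graphics::hist()] (default "Sturges").
#' @return List: `mean`, `median`, `sd`, `quartiles`, `n`,
#'   `masked_fraction`, `histogram` (data.frame of bin edges and counts).
#' @export
modulus_summary <- function(map, breaks = "Sturges") {
  stopifnot(inherits(map, "stiffness_map"))
  e <- map$E[!is.na(map$E)]
  if (!length(e)) stop("modulus_summary: empty or fully masked map", call. = FALSE)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  list(mean = mean(e), median = stats::median(e),
       sd = if (length(e) > 1L) stats::sd(e) else NA_real_,
       quartiles = stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE),
       n = length(e), masked_fraction = 1 - length(e) / length(map$E),
       histogram = data.frame(lower = utils::head(h$breaks, -1),
                              upper = utils::tail(h$breaks, -1),
                              count = h$counts))
}

#' Extract a 1-D profile from a height map
#'
#' Returns one row or column of the grid with physical coordinates derived
#' from the pixel spacing.
#'
#' @param map A `height_map`.
#' @param axis `"row"` or `"col"`.
#' @param index 1-based row/column index.
#' @return `data.frame` with `distance_um` and `height`.
#' @export
extract_profile <- function(map, axis = c("row", "col"), index = 1L) {
  stopifnot(inherits(map, "height_map"))
  axis <- match.arg(axis)
  index <- as.integer(index)
  if (axis == "row") {
    if (index < 1L || index > nrow(map$Z)) stop("extract_profile: row index out of range", call. = FALSE)
    h <- map$Z[index, ]
  } else {
    if (index < 1L || index > ncol(map$Z)) stop("extract_profile: column index out of range", call. = FALSE)
    h <- map$Z[, index]
  }
  data.frame(distance_um = (seq_along(h) - 1) * map$pixel_spacing, height = h)
}

#' Expected AFM grid geometry from extent and step
#'
#' For force mapping over a square grid of side `extent_um` sampled every
#' `step_um` with both endpoints included, the number of sample points per
#' axis is `floor(extent/step) + 1`. A 50 um extent at a 5 um step gives 11
#' points per axis.
#'
#' @param extent_um Grid side length in micrometres (default 50).
#' @param step_um Sampling step in micrometres (default 5).
#' @return List: `points_per_axis`, `n_points` (full grid), `extent_um`,
#'   `step_um`.
#' @export
grid_from_spec <- function(extent_um = 50, step_um = 5) {
  if (extent_um <= 0 || step_um <= 0) {
    stop("grid_from_spec: extent and step must be > 0", call. = FALSE)
  }
  if (step_um > extent_um) {
    warning("grid_from_spec: step exceeds extent; a single sample point per axis")
  }
  ppa <- as.integer(floor(extent_um / step_um)) + 1L
  list(points_per_axis = ppa, n_points = ppa^2,
       extent_um = extent_um, step_um = step_um)
}
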