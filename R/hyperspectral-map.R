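#' Hyperspectral Raman map
#'
#' Container for a spatial grid of Raman spectra: a channels-by-pixels
#' intensity matrix together with its wavenumber axis and grid geometry.
#' Pixels are stored in row-major order with y as the outer index and x as
#' the inner index, i.e. pixel `p = (iy - 1) * nx + ix`.
#'
#' @param wavenumbers Numeric vector of strictly increasing wavenumbers
#'   (cm^-1), one per spectral channel.
#' @param A Numeric matrix, `length(wavenumbers)` rows (channels) by
#'   `nx * ny` columns (pixels), arbitrary intensity units.
#' @param nx,ny Grid dimensions (pixels along x and y).
#' @param x_step,y_step Spatial step sizes in micrometres.
#'
#' @return An object of class `hyperspectral_map` with fields
#'   `wavenumbers`, `A`, `nx`, `ny`, `x_step`, `y_step`.
#' @export
hyperspectral_map <- function(wavenumbers, A, nx, ny, x_step = 1, y_step = 1) {
  wavenumbers <- as.numeric(wavenumbers)
  A <- as.matrix(A)
  if (length(wavenumbers) < 2L) {
    stop("hyperspectral_map: need at least 2 spectral channels", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("hyperspectral_map: wavenumber axis must be finite and strictly increasing",
         call. = FALSE)
  }
  if (nrow(A) != length(wavenumbers)) {
    stop("hyperspectral_map: nrow(A) must equal length(wavenumbers)", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L || ncol(A) != nx * ny) {
    stop("hyperspectral_map: ncol(A) must equal nx * ny (>= 1)", call. = FALSE)
  }
  if (any(!is.finite(A))) {
    stop("hyperspectral_map: intensities must be finite", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, A = A, nx = nx, ny = ny,
         x_step = as.numeric(x_step), y_step = as.numeric(y_step)),
    class = "hyperspectral_map"
  )
}

#' @export
print.hyperspectral_map <- function(x, ...) {
  cat(sprintf(
    "<hyperspectral_map> %d channels (%.1f-%.1f cm^-1), %d x %d pixels (steps %.3g x %.3g um)\n",
    length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
    x$nx, x$ny, x$x_step, x$y_step))
  invisible(x)
}

#' Linear pixel index for grid coordinates
#'
#' Maps `(ix, iy)` grid coordinates (1-based) to the column index of the
#' pixel in the intensity matrix, under the package's row-major, y-outer
#' ordering.
#'
#' @param ix,iy 1-based pixel coordinates along x and y.
#' @param nx Number of pixels along x.
#' @return Integer linear pixel index.
#' @export
pixel_index <- function(ix, iy, nx) {
  (as.integer(iy) - 1L) * as.integer(nx) + as.integer(ix)
}

#' Single Raman spectrum
#'
#' @param wavenumbers Strictly increasing numeric axis (cm^-1).
#' @param intensities Finite numeric intensities, same length.
#' @return Object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("raman_spectrum: axis and intensities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("raman_spectrum: wavenumber axis must be finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("raman_spectrum: intensities must be finite", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

# trapezoidal quadrature weights for a (possibly non-uniform) axis
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trapz_weights: need at least two points", call. = FALSE)
  d <- diff(x)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}
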