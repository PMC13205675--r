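#' Truncate a spectrum or map to a wavenumber range
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi` (closed
#' interval), preserving channel order. The fingerprint window used for
#' ovarian tissue analysis is 400-2000 cm^-1.
#'
#' @param x A `raman_spectrum` or `hyperspectral_map`.
#' @param lo,hi Range bounds in cm^-1, `lo < hi`.
#' @return Object of the same class restricted to the range.
#' @export
truncate_range <- function(x, lo = 400, hi = 2000) {
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("truncate_range: need finite lo < hi", call. = FALSE)
  }
  UseMethod("truncate_range")
}

#' @export
truncate_range.raman_spectrum <- function(x, lo = 400, hi = 2000) {
  keep <- x$wavenumbers >= lo & x$wavenumbers <= hi
  if (sum(keep) < 2L) {
    stop("truncate_range: fewer than 2 channels fall in [lo, hi]", call. = FALSE)
  }
  raman_spectrum(x$wavenumbers[keep], x$intensities[keep])
}

#' @export
truncate_range.hyperspectral_map <- function(x, lo = 400, hi = 2000) {
  keep <- x$wavenumbers >= lo & x$wavenumbers <= hi
  if (sum(keep) < 2L) {
    stop("truncate_range: fewer than 2 channels fall in [lo, hi]", call. = FALSE)
  }
  hyperspectral_map(x$wavenumbers[keep], x$A[keep, , drop = FALSE],
                    x$nx, x$ny, x$x_step, x$y_step)
}

# median across 8 stacked matrices using a Batcher sorting network on whole
# matrices (median of 8 = mean of the 4th and 5th order statistics); avoids
# an apply() over n*m cells.
.median8 <- function(slabs) {
  stopifnot(length(slabs) == 8L)
  pairs <- list(
    c(1,2), c(3,4), c(5,6), c(7,8),
    c(1,3), c(2,4), c(5,7), c(6,8),
    c(2,3), c(6,7),
    c(1,5), c(2,6), c(3,7), c(4,8),
    c(3,5), c(4,6),
    c(2,3), c(4,5), c(6,7)
  )
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    lo <- pmin(slabs[[i]], slabs[[j]])
    hi <- pmax(slabs[[i]], slabs[[j]])
    slabs[[i]] <- lo; slabs[[j]] <- hi
  }
  (slabs[[4]] + slabs[[5]]) / 2
}

# neighbourhood-median reference spectrum for every pixel: the 8 spatial
# neighbours of the 3x3 window, centre excluded so the reference is
# independent of the pixel's own noise (an included centre puts an atom at
# zero in the residuals and deflates their MAD). Borders are mirrored, which
# never maps a neighbour onto the centre itself.
.neighbourhood_median <- function(A, nx, ny) {
  mirror <- function(i, n) {
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
    if (n == 1L) i[] <- 1L
    i
  }
  ixg <- rep(seq_len(nx), times = ny)
  iyg <- rep(seq_len(ny), each = nx)
  slabs <- vector("list", 8L)
  s <- 0L
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dx == 0L && dy == 0L) next
      s <- s + 1L
      jx <- mirror(ixg + dx, nx)
      jy <- mirror(iyg + dy, ny)
      slabs[[s]] <- A[, pixel_index(jx, jy, nx), drop = FALSE]
    }
  }
  .median8(slabs)
}

#' Remove cosmic-ray spikes from a hyperspectral map
#'
#' Cosmic rays hit single detector channels of single pixels; they are
#' flagged by comparing each pixel's spectrum against the median spectrum of
#' its 3x3 spatial neighbourhood. A channel is flagged when its positive
#' residual against that median exceeds `z_threshold` robust standard
#' deviations (1.4826 x per-channel MAD of the residuals across pixels) and
#' the residual is spectrally isolated: the mean residual of the two
#' adjacent channels stays below half the centre residual. The isolation
#' test rejects genuine band structure, which is several channels wide,
#' where a cosmic-ray event hits a single channel. Flagged values are
#' replaced by the neighbourhood median. For a single-pixel map (no neighbours) a
#' within-spectrum running-median filter is used instead and a message is
#' emitted.
#'
#' @param map A `hyperspectral_map`.
#' @param z_threshold Positive robust z-score cutoff (default 8).
#' @param neighborhood Spatial window; only the default 3x3 window is
#'   implemented.
#' @return List with `map` (despiked `hyperspectral_map`) and `spike_mask`
#'   (logical channels-by-pixels matrix of flagged entries).
#' @export
remove_cosmic_spikes <- function(map, z_threshold = 8, neighborhood = 3L) {
  stopifnot(inherits(map, "hyperspectral_map"))
  if (!is.numeric(z_threshold) || z_threshold <= 0) {
    stop("remove_cosmic_spikes: z_threshold must be > 0", call. = FALSE)
  }
  if (neighborhood != 3L) {
    stop("remove_cosmic_spikes: only a 3x3 neighborhood is implemented", call. = FALSE)
  }
  A <- map$A
  n <- nrow(A); m <- ncol(A)
  if (m == 1L) {
    message("remove_cosmic_spikes: single-pixel map; falling back to within-spectrum median filter")
    ref <- stats::runmed(A[, 1], k = 5L)
    resid <- A[, 1] - ref
    sc <- stats::mad(resid)
    if (sc <= 0) sc <- stats::sd(resid)
    mask <- matrix(sc > 0 & resid > z_threshold * sc, ncol = 1L)
    A[mask[, 1], 1] <- ref[mask[, 1]]
    out <- map; out$A <- A
    return(list(map = out, spike_mask = mask))
  }
  ref <- .neighbourhood_median(A, map$nx, map$ny)
  resid <- A - ref
  # robust per-channel scale of the spatial residual across pixels
  med <- apply(resid, 1L, stats::median)
  sc <- 1.4826 * apply(abs(resid - med), 1L, stats::median)
  sc[sc <= 0] <- Inf  # flat channels carry no evidence of spikes
  # shape criterion: a cosmic ray is one channel wide, so the residual at
  # the two adjacent channels must stay below half the centre residual;
  # genuine band structure (several channels wide) is rejected by this
  neigh <- (resid[c(2L, seq_len(n - 1L)), , drop = FALSE] +
              resid[c(2:n, n - 1L), , drop = FALSE]) / 2
  mask <- (resid > z_threshold * sc) & (neigh < 0.5 * resid)
  A[mask] <- ref[mask]
  out <- map; out$A <- A
  list(map = out, spike_mask = mask)
}

# SNIP clipping recurrence on a channels-by-pixels matrix (columns are
# independent spectra). Half-window grows 1..M; the clipping average is only
# taken where both offset neighbours exist, which makes linear spectra exact
# fixed points.
.snip_matrix <- function(Y, max_half_window, use_lls = FALSE) {
  n <- nrow(Y)
  M <- as.integer(max_half_window)
  if (M < 1L || M >= n / 2) {
    stop("snip_baseline: max_half_window must be >= 1 and < n/2", call. = FALSE)
  }
  if (use_lls) {
    if (any(Y < 0)) stop("snip_baseline: LLS transform requires non-negative intensities",
                         call. = FALSE)
    Y <- log(log(sqrt(Y + 1) + 1) + 1)
  }
  for (m in seq_len(M)) {
    idx <- (m + 1L):(n - m)
    avg <- (Y[idx - m, , drop = FALSE] + Y[idx + m, , drop = FALSE]) / 2
    Y[idx, ] <- pmin(Y[idx, , drop = FALSE], avg)
  }
  if (use_lls) {
    Y <- (exp(exp(Y) - 1) - 1)^2 - 1
  }
  Y
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: for half-windows
#' m = 1..M each intensity is replaced by the minimum of itself and the mean
#' of its two neighbours at distance m, which strips peaks while following
#' the smooth fluorescence background. Channels whose m-neighbours fall
#' outside the spectrum are left untouched at that m, so constant and linear
#' spectra are exact fixed points. An optional log-log-square-root (LLS)
#' compression can be applied around the clipping loop to protect weak peaks
#' sitting on intense backgrounds; it requires non-negative input.
#'
#' The returned baseline never exceeds the input spectrum.
#'
#' @param spectrum A `raman_spectrum`.
#' @param max_half_window Largest clipping half-window M in channels;
#'   must satisfy `1 <= M < n/2`. Default 40.
#' @param use_lls Apply the LLS compress/decompress transform (default FALSE).
#' @return A `raman_spectrum` holding the baseline estimate.
#' @export
snip_baseline <- function(spectrum, max_half_window = 40L, use_lls = FALSE) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  b <- .snip_matrix(matrix(spectrum$intensities, ncol = 1L), max_half_window, use_lls)
  raman_spectrum(spectrum$wavenumbers, b[, 1])
}

#' Subtract a baseline from a spectrum
#'
#' Differences the two spectra and clips the result at zero from below
#' (downstream factorization requires non-negative intensities). The number
#' of clipped channels is attached as attribute `n_clipped`.
#'
#' @param spectrum,baseline `raman_spectrum` objects on the same axis.
#' @return Baseline-corrected `raman_spectrum` (attribute `n_clipped`).
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(baseline, "raman_spectrum"))
  if (!isTRUE(all.equal(spectrum$wavenumbers, baseline$wavenumbers))) {
    stop("subtract_baseline: spectra are on different wavenumber axes", call. = FALSE)
  }
  d <- spectrum$intensities - baseline$intensities
  n_clipped <- sum(d < 0)
  d[d < 0] <- 0
  out <- raman_spectrum(spectrum$wavenumbers, d)
  attr(out, "n_clipped") <- n_clipped
  out
}

# Savitzky-Golay smoothing of every column of a matrix, using the central
# filter in the interior and the least-squares edge filters of
# signal::sgolay at the first/last (w-1)/2 channels (exact polynomial
# reproduction everywhere).
.sg_matrix <- function(Y, window = 9L, order = 3L) {
  n <- nrow(Y)
  w <- as.integer(window); p <- as.integer(order)
  if (w %% 2L != 1L || w < 3L) stop("savitzky_golay: window must be odd and >= 3", call. = FALSE)
  if (p >= w) stop("savitzky_golay: order must be < window", call. = FALSE)
  if (n < w) stop("savitzky_golay: spectrum shorter than the window", call. = FALSE)
  Fm <- signal::sgolay(p = p, n = w)  # w x w: row r filters position r of a window
  h <- (w - 1L) %/% 2L
  centre <- Fm[h + 1L, ]
  out <- matrix(0, n, ncol(Y))
  # interior: plain convolution with the central filter
  for (j in seq_len(w)) {
    rows <- (h + 1L):(n - h)
    out[rows, ] <- out[rows, , drop = FALSE] +
      centre[j] * Y[rows + (j - h - 1L), , drop = FALSE]
  }
  # edges: dedicated least-squares filters over the first/last window
  out[1:h, ] <- Fm[1:h, , drop = FALSE] %*% Y[1:w, , drop = FALSE]
  out[(n - h + 1L):n, ] <- Fm[(h + 2L):w, , drop = FALSE] %*% Y[(n - w + 1L):n, , drop = FALSE]
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the 9-point window used for
#' Raman noise reduction. Edge channels are smoothed with the dedicated
#' least-squares edge filters, so polynomials up to the fit order are
#' reproduced exactly over the whole spectrum.
#'
#' @param spectrum A `raman_spectrum`.
#' @param window Odd window length in channels (default 9).
#' @param order Polynomial order, `order < window` (default 3).
#' @return Smoothed `raman_spectrum`.
#' @export
savitzky_golay <- function(spectrum, window = 9L, order = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  y <- .sg_matrix(matrix(spectrum$intensities, ncol = 1L), window, order)
  raman_spectrum(spectrum$wavenumbers, y[, 1])
}

#' Area normalization
#'
#' Scales a spectrum so that its trapezoidal integral over the wavenumber
#' axis equals 1, correcting intensity variations from focus drift. A
#' non-positive integral signals a dead pixel and is an error.
#'
#' @param spectrum A `raman_spectrum`.
#' @return Unit-area `raman_spectrum`.
#' @export
area_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  a <- sum(trapz_weights(spectrum$wavenumbers) * spectrum$intensities)
  if (!is.finite(a) || a <= 0) {
    stop("area_normalize: non-positive spectral area (dead pixel)", call. = FALSE)
  }
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / a)
}

#' Default Raman preprocessing configuration
#'
#' @param lo,hi Truncation range in cm^-1.
#' @param z_threshold Cosmic-spike robust z cutoff.
#' @param snip_half_window SNIP maximum half-window (channels).
#' @param snip_lls Use the LLS transform inside SNIP.
#' @param sg_window,sg_order Savitzky-Golay window and polynomial order.
#' @return Named list of preprocessing parameters.
#' @export
preprocess_config <- function(lo = 400, hi = 2000, z_threshold = 8,
                              snip_half_window = 40L, snip_lls = FALSE,
                              sg_window = 9L, sg_order = 3L) {
  list(lo = lo, hi = hi, z_threshold = z_threshold,
       snip_half_window = as.integer(snip_half_window), snip_lls = snip_lls,
       sg_window = as.integer(sg_window), sg_order = as.integer(sg_order))
}

#' Full Raman preprocessing chain for a hyperspectral map
#'
#' Applies, in fixed order: truncation to the fingerprint range, cosmic
#' spike removal, per-pixel SNIP baseline estimation and subtraction (with
#' zero clipping), per-pixel Savitzky-Golay smoothing (re-clipped at zero),
#' and per-pixel area normalization. The chain is a pure function of the
#' input and configuration.
#'
#' @param map A `hyperspectral_map`.
#' @param config List from [preprocess_config()].
#' @return A preprocessed `hyperspectral_map`; attributes `spike_mask`
#'   (logical matrix) and `n_clipped` (channels clipped at zero) record what
#'   the chain did.
#' @export
preprocess_map <- function(map, config = preprocess_config()) {
  stopifnot(inherits(map, "hyperspectral_map"))
  map <- truncate_range(map, config$lo, config$hi)
  sp <- remove_cosmic_spikes(map, z_threshold = config$z_threshold)
  map <- sp$map
  base <- .snip_matrix(map$A, config$snip_half_window, config$snip_lls)
  Y <- map$A - base
  n_clipped <- sum(Y < 0)
  Y[Y < 0] <- 0
  Y <- .sg_matrix(Y, config$sg_window, config$sg_order)
  n_clipped <- n_clipped + sum(Y < 0)
  Y[Y < 0] <- 0
  w <- trapz_weights(map$wavenumbers)
  areas <- as.numeric(crossprod(w, Y))
  dead <- which(!is.finite(areas) | areas <= 0)
  if (length(dead)) {
    stop(sprintf("preprocess_map: non-positive spectral area at pixel(s) %s (dead pixel)",
                 paste(utils::head(dead, 5L), collapse = ", ")), call. = FALSE)
  }
  Y <- sweep(Y, 2L, areas, "/")
  out <- map; out$A <- Y
  attr(out, "spike_mask") <- sp$spike_mask
  attr(out, "n_clipped") <- n_clipped
  out
}
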