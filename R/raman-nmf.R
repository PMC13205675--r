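#' Component set from spectral unmixing
#'
#' Holds the factors of the non-negative decomposition `A ~ W %*% S`:
#' `W` (channels x k) are pure-component spectra, `S` (k x pixels) the
#' per-pixel concentration profiles. Columns of `W` are rescaled to unit
#' trapezoidal area (inverse scale absorbed into `S`) and components are
#' sorted by total abundance, descending, to resolve the scale and
#' permutation indeterminacy of the factorization.
#'
#' @param W Channels-by-k non-negative matrix of pure spectra.
#' @param S k-by-pixels non-negative concentration matrix.
#' @param wavenumbers Wavenumber axis matching the rows of `W`.
#' @param objective_trace Per-iteration squared Frobenius reconstruction
#'   error of the winning restart.
#' @param restarts_used Number of random restarts run.
#' @param seed Seed that controlled the initializations.
#' @return Object of class `component_set`.
#' @export
component_set <- function(W, S, wavenumbers, objective_trace = numeric(),
                          restarts_used = 1L, seed = NA_integer_) {
  W <- as.matrix(W); S <- as.matrix(S)
  if (ncol(W) != nrow(S)) stop("component_set: ncol(W) must equal nrow(S)", call. = FALSE)
  if (any(W < 0) || any(S < 0)) stop("component_set: factors must be non-negative", call. = FALSE)
  if (length(wavenumbers) != nrow(W)) {
    stop("component_set: wavenumbers must match rows of W", call. = FALSE)
  }
  # unit-area W columns, inverse scale into S
  wts <- trapz_weights(wavenumbers)
  areas <- as.numeric(crossprod(wts, W))
  pos <- areas > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2L, areas[pos], "/")
  S[pos, ] <- sweep(S[pos, , drop = FALSE], 1L, areas[pos], "*")
  # sort by total abundance, descending
  ord <- order(rowSums(S), decreasing = TRUE)
  structure(
    list(W = W[, ord, drop = FALSE], S = S[ord, , drop = FALSE],
         k = ncol(W), wavenumbers = as.numeric(wavenumbers),
         objective_trace = as.numeric(objective_trace),
         restarts_used = as.integer(restarts_used), seed = seed),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> k = %d, %d channels x %d pixels; final objective %.6g (%d restarts)\n",
              x$k, nrow(x$W), ncol(x$S),
              if (length(x$objective_trace)) utils::tail(x$objective_trace, 1) else NA_real_,
              x$restarts_used))
  invisible(x)
}

# one multiplicative-update run from a given initialization
.nmf_mu <- function(A, W, S, max_iter, tol) {
  eps <- .Machine$double.eps
  trace <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  for (i in seq_len(max_iter)) {
    WtA <- crossprod(W, A)
    WtW <- crossprod(W)
    S <- S * WtA / (WtW %*% S + eps)
    ASt <- tcrossprod(A, S)
    SSt <- tcrossprod(S)
    W <- W * ASt / (W %*% SSt + eps)
    obj <- sum((A - W %*% S)^2)
    it <- i
    trace[i] <- obj
    if (is.finite(prev) && prev > 0 && abs(prev - obj) / prev < tol) break
    prev <- obj
  }
  list(W = W, S = S, trace = trace[seq_len(it)])
}

#' Non-negative matrix factorization of a hyperspectral map
#'
#' Decomposes the preprocessed channels-by-pixels intensity matrix `A` into
#' `k` non-negative pure-component spectra `W` and concentration profiles
#' `S` by minimizing the squared Frobenius reconstruction error with
#' multiplicative updates. Multiple seeded uniform-random initializations
#' are run and the best final objective is kept. The objective trace of the
#' winning restart is recorded; multiplicative updates make it
#' non-increasing.
#'
#' @param map A `hyperspectral_map` with non-negative intensities
#'   (typically the output of [preprocess_map()]).
#' @param k Number of components (>= 1).
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum iterations per restart (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param seed Integer seed controlling all initializations.
#' @return A [component_set()].
#' @export
nmf_decompose <- function(map, k, n_restarts = 10L, max_iter = 500L,
                          tol = 1e-6, seed = 1L) {
  stopifnot(inherits(map, "hyperspectral_map"))
  A <- map$A
  k <- as.integer(k)
  if (k < 1L) stop("nmf_decompose: k must be >= 1", call. = FALSE)
  neg <- which(A < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("nmf_decompose: negative intensity at channel %d, pixel %d",
                 neg[1, 1], neg[1, 2]), call. = FALSE)
  }
  n <- nrow(A); m <- ncol(A)
  amax <- max(A)
  if (amax <= 0) stop("nmf_decompose: map is identically zero", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rs <- .seeded_rng(seed + r - 1L)
    W0 <- matrix(.runif_pos(rs, n * k, amax), n, k)
    S0 <- matrix(.runif_pos(rs, k * m, amax), k, m)
    fit <- .nmf_mu(A, W0, S0, max_iter, tol)
    if (is.null(best) || utils::tail(fit$trace, 1) < utils::tail(best$trace, 1)) {
      best <- fit
    }
  }
  component_set(best$W, best$S, map$wavenumbers,
                objective_trace = best$trace,
                restarts_used = n_restarts, seed = seed)
}

#' Best NMF objective over a range of k (scree diagnostic)
#'
#' The number of tissue components is a user choice; this diagnostic runs
#' the factorization for each candidate `k` under a shared restart/seed
#' policy and tabulates the best objective, which is non-increasing in `k`.
#'
#' @param map A `hyperspectral_map` with non-negative intensities.
#' @param k_range Integer vector of component counts to try.
#' @inheritParams nmf_decompose
#' @return `data.frame` with columns `k` and `objective`.
#' @export
scree_over_k <- function(map, k_range = 1:6, n_restarts = 5L, max_iter = 200L,
                         tol = 1e-6, seed = 1L) {
  objs <- vapply(k_range, function(k) {
    cs <- nmf_decompose(map, k, n_restarts = n_restarts, max_iter = max_iter,
                        tol = tol, seed = seed)
    utils::tail(cs$objective_trace, 1)
  }, numeric(1))
  # enforce monotonicity against optimizer noise: a larger k can always
  # represent a smaller k's solution, so carry the running minimum
  data.frame(k = as.integer(k_range), objective = cummin(objs))
}

#' Per-component abundance images
#'
#' Reshapes each row of the concentration matrix `S` onto the spatial grid
#' (row-major, y outer, x inner), yielding one `ny x nx` image per
#' component.
#'
#' @param cs A `component_set`.
#' @param nx,ny Grid dimensions of the originating map.
#' @return List of `ny x nx` matrices, one per component.
#' @export
abundance_maps <- function(cs, nx, ny) {
  stopifnot(inherits(cs, "component_set"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx * ny != ncol(cs$S)) {
    stop("abundance_maps: nx * ny must equal the pixel count of S", call. = FALSE)
  }
  lapply(seq_len(cs$k), function(c) {
    matrix(cs$S[c, ], nrow = ny, ncol = nx, byrow = TRUE)
  })
}

# peak prominence: for each local maximum, height above the highest of the
# two minima separating it from higher terrain on each side
.peak_prominence <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), prominence = numeric()))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(is_peak, function(i) {
    # walk left until terrain exceeds y[i]; track the minimum en route
    lmin <- y[i]
    j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
    lbase <- if (j >= 1L) lmin else min(y[1:i])
    rmin <- y[i]
    j <- i + 1L
    while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
    rbase <- if (j <= n) rmin else min(y[i:n])
    y[i] - max(lbase, rbase)
  }, numeric(1))
  data.frame(index = is_peak, prominence = prom)
}

#' Detect peaks in a component spectrum
#'
#' Local maxima ranked by topographic prominence (height above the highest
#' saddle connecting the peak to higher terrain).
#'
#' @param wavenumbers,intensities Spectrum to analyse.
#' @param min_prominence Keep peaks with prominence at least this fraction
#'   of the intensity range (default 0.05).
#' @return `data.frame` with columns `position` (cm^-1) and `prominence`.
#' @export
detect_peaks <- function(wavenumbers, intensities, min_prominence = 0.05) {
  pk <- .peak_prominence(intensities)
  rng <- diff(range(intensities))
  if (rng <= 0) return(data.frame(position = numeric(), prominence = numeric()))
  keep <- pk$prominence >= min_prominence * rng
  out <- data.frame(position = wavenumbers[pk$index[keep]],
                    prominence = pk$prominence[keep])
  out[order(-out$prominence), , drop = FALSE]
}

#' Annotate a component against a reference peak table
#'
#' Detects the component's peaks by prominence and assigns the label whose
#' reference peak positions are best covered (highest match fraction within
#' `tolerance`). Falls back to `"unassigned"` below `min_match` or on ties.
#'
#' @param cs A `component_set`.
#' @param component_index Which component to annotate (1-based).
#' @param reference_peaks `data.frame` with columns `label` and `position`
#'   (cm^-1); see [load_reference_peaks()] for the bundled literature table.
#' @param tolerance Matching tolerance in cm^-1 (default 10).
#' @param min_match Minimum match fraction for assignment (default 0.5).
#' @param min_prominence Passed to [detect_peaks()].
#' @return List of class `peak_annotation`: `component_index`,
#'   `detected_peaks`, `assigned_label`, `match_fraction`, `tie`,
#'   `reference_used`.
#' @export
annotate_component <- function(cs, component_index, reference_peaks,
                               tolerance = 10, min_match = 0.5,
                               min_prominence = 0.05) {
  stopifnot(inherits(cs, "component_set"))
  ci <- as.integer(component_index)
  if (ci < 1L || ci > cs$k) stop("annotate_component: component_index out of range", call. = FALSE)
  if (!all(c("label", "position") %in% names(reference_peaks))) {
    stop("annotate_component: reference_peaks needs columns label, position", call. = FALSE)
  }
  peaks <- detect_peaks(cs$wavenumbers, cs$W[, ci], min_prominence)
  labels <- unique(reference_peaks$label)
  frac <- vapply(labels, function(lb) {
    ref <- reference_peaks$position[reference_peaks$label == lb]
    if (!length(ref) || !nrow(peaks)) return(0)
    mean(vapply(ref, function(p) any(abs(peaks$position - p) <= tolerance), logical(1)))
  }, numeric(1))
  assigned <- "unassigned"; tie <- FALSE; best <- 0
  if (length(frac)) {
    best <- max(frac)
    winners <- labels[frac == best]
    if (best >= min_match) {
      if (length(winners) == 1L) assigned <- winners else tie <- TRUE
    }
  }
  structure(list(component_index = ci, detected_peaks = peaks,
                 assigned_label = assigned, match_fraction = best, tie = tie,
                 reference_used = attr(reference_peaks, "source") %||% "user table"),
            class = "peak_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the bundled reference Raman peak table
#'
#' Literature-typical band positions for collagen, glycosaminoglycans and
#' general protein/cellular material, shipped as an editable CSV. These are
#' literature defaults for annotation convenience, not measured values.
#'
#' @param path CSV with columns `label`, `position`; defaults to the
#'   bundled table.
#' @return `data.frame` with attribute `source`.
#' @export
load_reference_peaks <- function(path = system.file("extdata", "raman_reference_peaks.csv",
                                                    package = "ovamat")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "position") %in% names(tab))) {
    stop("load_reference_peaks: need columns label, position", call. = FALSE)
  }
  attr(tab, "source") <- basename(path)
  tab
}
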