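# Synthetic-data generators. Every generator consumes an explicit spec with
# an explicit seed, returns the latent ground truth alongside the data, and
# never touches the caller's RNG state.

.check_finite <- function(x, what) {
  if (any(!is.finite(unlist(x)))) {
    stop(sprintf("%s: non-finite parameter(s)", what), call. = FALSE)
  }
}

#' Specification for a synthetic Raman hyperspectral phantom
#'
#' Pure-component spectra are sums of Gaussian bands (sufficient for
#' recovery testing; measured tissue spectra are empirical); spatial
#' abundance fields are smooth Gaussian blobs placed at distinct grid
#' positions so components are spatially separable, mirroring the
#' cell-versus-matrix contrast of tissue maps. A slowly varying polynomial
#' background per pixel emulates fluorescence, Gaussian noise the shot
#' noise, and rare large single-channel positive outliers the cosmic rays.
#'
#' @param n_components Number of pure components.
#' @param peak_tables List (length `n_components`) of data.frames with
#'   columns `center` (cm^-1), `width` (Gaussian sigma, cm^-1), `height`
#'   (a.u., >= 0). `NULL` uses a bundled 3-component default (collagen-,
#'   GAG- and cell-like band positions).
#' @param nx,ny Grid size in pixels.
#' @param x_step,y_step Grid step in micrometres.
#' @param wavenumber_axis Strictly increasing axis in cm^-1 (default
#'   400-2000 at 2 cm^-1, 801 channels).
#' @param abundance_fields Optional list of `ny x nx` non-negative matrices;
#'   `NULL` generates smooth blobs.
#' @param baseline_scale Typical background magnitude relative to the peak
#'   signal (0 disables the baseline).
#' @param noise_sd Gaussian noise standard deviation; `NULL` sets 1% of the
#'   maximum noiseless signal.
#' @param spike_rate Per-(channel, pixel) cosmic-spike probability.
#' @param spike_magnitude Additive spike height; `NULL` sets 25 x noise_sd
#'   (well above a detection threshold of 8 robust standard deviations, as
#'   real cosmic-ray events are).
#' @param seed Integer seed.
#' @return List of class `raman_phantom_spec`.
#' @export
raman_phantom_spec <- function(n_components = 3L, peak_tables = NULL,
                               nx = 50L, ny = 40L, x_step = 1, y_step = 1,
                               wavenumber_axis = seq(400, 2000, by = 2),
                               abundance_fields = NULL,
                               baseline_scale = 0.3, noise_sd = NULL,
                               spike_rate = 0.001, spike_magnitude = NULL,
                               seed = 1L) {
  if (is.null(peak_tables)) {
    peak_tables <- .default_peak_tables()[seq_len(n_components)]
    if (n_components > 3L) stop("raman_phantom_spec: supply peak_tables for more than 3 components",
                                call. = FALSE)
  }
  if (length(peak_tables) != n_components) {
    stop("raman_phantom_spec: need one peak table per component", call. = FALSE)
  }
  for (pt in peak_tables) {
    if (!all(c("center", "width", "height") %in% names(pt))) {
      stop("raman_phantom_spec: peak tables need columns center, width, height", call. = FALSE)
    }
    .check_finite(pt, "raman_phantom_spec")
    if (any(pt$height < 0) || any(pt$width <= 0)) {
      stop("raman_phantom_spec: peak heights must be >= 0 and widths > 0", call. = FALSE)
    }
  }
  .check_finite(list(wavenumber_axis, baseline_scale, spike_rate, seed),
                "raman_phantom_spec")
  if (any(diff(wavenumber_axis) <= 0)) {
    stop("raman_phantom_spec: wavenumber axis must be strictly increasing", call. = FALSE)
  }
  if (spike_rate < 0 || spike_rate > 1) {
    stop("raman_phantom_spec: spike_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(abundance_fields)) {
    if (length(abundance_fields) != n_components) {
      stop("raman_phantom_spec: need one abundance field per component", call. = FALSE)
    }
    for (f in abundance_fields) {
      if (!all(dim(f) == c(ny, nx))) stop("raman_phantom_spec: abundance fields must be ny x nx",
                                          call. = FALSE)
      if (any(f < 0) || any(!is.finite(f))) {
        stop("raman_phantom_spec: abundance fields must be finite and >= 0", call. = FALSE)
      }
    }
  }
  structure(list(n_components = as.integer(n_components), peak_tables = peak_tables,
                 nx = as.integer(nx), ny = as.integer(ny),
                 x_step = x_step, y_step = y_step,
                 wavenumber_axis = as.numeric(wavenumber_axis),
                 abundance_fields = abundance_fields,
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 spike_rate = spike_rate, spike_magnitude = spike_magnitude,
                 seed = as.integer(seed)),
            class = "raman_phantom_spec")
}

# literature-typical band positions: collagen-like, glycosaminoglycan-like,
# generic protein/cell-like
.default_peak_tables <- function() {
  list(
    collagen_like = data.frame(
      center = c(855, 938, 1245, 1450, 1660),
      width = c(12, 10, 18, 15, 14),
      height = c(0.8, 0.7, 0.6, 0.5, 1.0)),
    gag_like = data.frame(
      center = c(480, 940, 1060, 1375),
      width = c(14, 12, 10, 16),
      height = c(0.5, 0.6, 1.0, 0.7)),
    cell_like = data.frame(
      center = c(720, 1003, 1300, 1575, 1680),
      width = c(10, 6, 16, 12, 14),
      height = c(0.5, 1.0, 0.6, 0.5, 0.7))
  )
}

.gaussian_bands <- function(axis, pt) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(pt))) {
    y <- y + pt$height[i] * exp(-(axis - pt$center[i])^2 / (2 * pt$width[i]^2))
  }
  y
}

# smooth blob abundance fields: one Gaussian bump per component on a small
# constant floor, centres spread over the grid
.default_abundance_fields <- function(k, nx, ny, rs) {
  gx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  gy <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  centres <- cbind(x = .rng_runif(rs, k, 0.15 * nx, 0.85 * nx),
                   y = .rng_runif(rs, k, 0.15 * ny, 0.85 * ny))
  # push centres apart deterministically: k <= 3 default uses grid thirds
  if (k <= 4L) {
    anchors <- cbind(x = c(0.25, 0.75, 0.25, 0.75) * nx,
                     y = c(0.3, 0.3, 0.75, 0.75) * ny)
    centres <- anchors[seq_len(k), , drop = FALSE]
  }
  sig <- 0.18 * min(nx, ny)
  lapply(seq_len(k), function(c) {
    0.05 + exp(-((gx - centres[c, 1])^2 + (gy - centres[c, 2])^2) / (2 * sig^2))
  })
}

#' Generate a synthetic Raman hyperspectral cube with known ground truth
#'
#' Builds `cube = sum_c abundance_c (x) spectrum_c + baseline + noise +
#' spikes` on the spec's grid and returns the noiseless latent factors (as a
#' [component_set()]) plus the exact spike locations. Deterministic for a
#' fixed spec and seed.
#'
#' @param spec A [raman_phantom_spec()].
#' @return List: `map` (`hyperspectral_map`), `truth` (`component_set` of
#'   the noiseless factors), `spike_mask` (logical channels x pixels),
#'   `abundance_fields` (list of `ny x nx` ground-truth fields, ordered as
#'   the truth components), `pure_spectra` (channels x k matrix, same
#'   order).
#' @export
gen_raman_cube <- function(spec) {
  stopifnot(inherits(spec, "raman_phantom_spec"))
  rs <- .seeded_rng(spec$seed)
  axis <- spec$wavenumber_axis
  n <- length(axis)
  m <- spec$nx * spec$ny
  k <- spec$n_components
  W <- vapply(spec$peak_tables, function(pt) .gaussian_bands(axis, pt),
              numeric(n))
  fields <- spec$abundance_fields
  if (is.null(fields)) fields <- .default_abundance_fields(k, spec$nx, spec$ny, rs)
  # flatten fields in the package's pixel order (y outer, x inner):
  # t(field) stacked column-wise walks x fastest
  S <- do.call(rbind, lapply(fields, function(f) as.numeric(t(f))))
  signal <- W %*% S
  ref <- max(signal)
  noise_sd <- spec$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.01 * ref
  spike_mag <- spec$spike_magnitude
  if (is.null(spike_mag)) spike_mag <- 25 * noise_sd
  A <- signal
  if (spec$baseline_scale > 0) {
    u <- (axis - axis[1]) / (axis[n] - axis[1])
    # fluorescence background varies smoothly across the tissue, so the
    # per-pixel polynomial coefficients are smooth spatial fields
    sm_field <- function(lo, hi) {
      f <- .gauss_smooth(matrix(.rng_rnorm(rs, m), spec$ny, spec$nx),
                         0.15 * min(spec$nx, spec$ny))
      rng <- range(f)
      scale <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
      as.numeric(t(lo + (hi - lo) * scale)) * spec$baseline_scale * ref
    }
    c0 <- sm_field(0.2, 0.5)
    c1 <- sm_field(-0.2, 0.2)
    c2 <- sm_field(0, 0.3)
    # baseline_p(u) = c0 + c1 u + c2 u^2 per pixel, vectorized over channels
    A <- signal + outer(rep(1, n), c0) + outer(u, c1) + outer(u^2, c2)
  }
  if (noise_sd > 0) {
    A <- A + matrix(.rng_rnorm(rs, n * m, 0, noise_sd), n, m)
  }
  spike_mask <- matrix(FALSE, n, m)
  if (spec$spike_rate > 0) {
    spike_mask <- matrix(.rng_runif(rs, n * m) < spec$spike_rate, n, m)
    if (any(spike_mask)) {
      A[spike_mask] <- A[spike_mask] +
        spike_mag * .rng_runif(rs, sum(spike_mask), 1, 2)
    }
  }
  map <- hyperspectral_map(axis, A, spec$nx, spec$ny, spec$x_step, spec$y_step)
  truth <- component_set(W, S, axis, objective_trace = numeric(),
                         restarts_used = 0L, seed = spec$seed)
  # keep the field/spectrum lists aligned with the truth's abundance ordering
  # (component_set absorbs the W-column areas into S before sorting)
  areas <- as.numeric(crossprod(trapz_weights(axis), W))
  ord <- order(rowSums(S) * areas, decreasing = TRUE)
  list(map = map, truth = truth, spike_mask = spike_mask,
       abundance_fields = fields[ord],
       pure_spectra = W[, ord, drop = FALSE])
}

#' Specification for a synthetic AFM surface
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @param pixel_spacing Grid spacing in micrometres.
#' @param target_sa Desired Sa (rms variant) of the generated surface, >= 0.
#' @param correlation_length Lateral correlation length in micrometres.
#' @param seed Integer seed.
#' @return List of class `surface_phantom_spec`.
#' @export
surface_phantom_spec <- function(grid_shape = c(100L, 100L), pixel_spacing = 5,
                                 target_sa = 10, correlation_length = 10,
                                 seed = 1L) {
  .check_finite(list(grid_shape, pixel_spacing, target_sa, correlation_length, seed),
                "surface_phantom_spec")
  if (target_sa < 0) stop("surface_phantom_spec: target_sa must be >= 0", call. = FALSE)
  if (any(grid_shape < 1)) stop("surface_phantom_spec: grid_shape must be positive", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 pixel_spacing = pixel_spacing, target_sa = target_sa,
                 correlation_length = correlation_length, seed = as.integer(seed)),
            class = "surface_phantom_spec")
}

# Gaussian smoothing of a matrix by separable kernel multiplication
.gauss_smooth <- function(X, sigma) {
  if (sigma <= 0) return(X)
  kern <- function(n) {
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    sweep(K, 1L, rowSums(K), "/")
  }
  kern(nrow(X)) %*% X %*% t(kern(ncol(X)))
}

#' Generate a height map with an exact target roughness
#'
#' A Gaussian random field (white noise smoothed to the requested
#' correlation length) is centred and rescaled so that its rms Sa equals
#' `target_sa` exactly (up to floating-point rounding). `target_sa = 0`
#' yields a constant surface.
#'
#' @param spec A [surface_phantom_spec()].
#' @return A [height_map()].
#' @export
gen_height_map <- function(spec) {
  stopifnot(inherits(spec, "surface_phantom_spec"))
  rs <- .seeded_rng(spec$seed)
  r <- spec$grid_shape[1]; cc <- spec$grid_shape[2]
  if (spec$target_sa == 0) {
    return(height_map(matrix(0, r, cc), spec$pixel_spacing))
  }
  Z <- matrix(.rng_rnorm(rs, r * cc), r, cc)
  Z <- .gauss_smooth(Z, spec$correlation_length / spec$pixel_spacing)
  Z <- Z - mean(Z)
  s <- sqrt(mean(Z^2))
  if (s == 0) stop("gen_height_map: degenerate field (zero variance)", call. = FALSE)
  height_map(Z * (spec$target_sa / s), spec$pixel_spacing)
}

#' Specification for a synthetic follicle cohort
#'
#' Default stage mix and follicle-diameter distributions describe a
#' peripubertal mouse ovary: a large primordial reserve with progressively
#' fewer growing stages, and stage diameters of roughly 17, 45, 120 and
#' 320 micrometres for primordial, primary, secondary and antral follicles.
#'
#' @param stage_proportions Named fractions over
#'   primordial/primary/secondary/antral, summing to 1.
#' @param diameter_distributions Named list of `c(mean, sd)` in micrometres
#'   per stage.
#' @param n_follicles Cohort size.
#' @param atresia_rate Fraction of unhealthy (atretic) follicles.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(stage_proportions = c(primordial = 0.55, primary = 0.20,
                                              secondary = 0.15, antral = 0.10),
                        diameter_distributions = list(
                          primordial = c(17, 2), primary = c(45, 10),
                          secondary = c(120, 25), antral = c(320, 60)),
                        n_follicles = 100L, atresia_rate = 0.1, seed = 1L) {
  .check_finite(list(stage_proportions, unlist(diameter_distributions),
                     n_follicles, atresia_rate, seed), "cohort_spec")
  if (abs(sum(stage_proportions) - 1) > 1e-9) {
    stop("cohort_spec: stage proportions must sum to 1", call. = FALSE)
  }
  if (any(stage_proportions < 0)) stop("cohort_spec: proportions must be >= 0", call. = FALSE)
  if (atresia_rate < 0 || atresia_rate > 1) {
    stop("cohort_spec: atresia_rate must lie in [0, 1]", call. = FALSE)
  }
  miss <- setdiff(names(stage_proportions), names(diameter_distributions))
  if (length(miss)) stop("cohort_spec: missing diameter distribution for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(stage_proportions = stage_proportions,
                 diameter_distributions = diameter_distributions,
                 n_follicles = as.integer(n_follicles),
                 atresia_rate = atresia_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

.stage_morphology <- function(stage, rs) {
  switch(stage,
         primordial = list(shape = "flattened", layers = 1L, antrum = FALSE),
         primary = list(shape = "mixed_cuboidal_squamous", layers = 1L, antrum = FALSE),
         secondary = list(shape = "cuboidal",
                          layers = 2L + as.integer(.rng_sample(rs, 0:4, 1L)),
                          antrum = FALSE),
         antral = list(shape = "cuboidal",
                       layers = 4L + as.integer(.rng_sample(rs, 0:6, 1L)),
                       antrum = TRUE),
         stop("unknown stage: ", stage, call. = FALSE))
}

#' Generate a follicle cohort with known stage labels
#'
#' Each record carries the generating stage in column `stage` (the ground
#' truth) alongside morphology fields consistent with that stage, so the
#' rule-based classifier can be tested for exact label recovery. Diameters
#' are drawn from per-stage normal distributions truncated at zero.
#'
#' @param spec A [cohort_spec()].
#' @return `data.frame` of follicle records plus `stage`.
#' @export
gen_follicle_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- .seeded_rng(spec$seed)
  stages <- names(spec$stage_proportions)
  n <- spec$n_follicles
  lab <- .rng_sample(rs, stages, n, replace = TRUE, prob = spec$stage_proportions)
  healthy <- .rng_runif(rs, n) >= spec$atresia_rate
  rows <- lapply(seq_len(n), function(i) {
    st <- lab[i]
    mo <- .stage_morphology(st, rs)
    dd <- spec$diameter_distributions[[st]]
    d <- .rng_rnorm(rs, 1L, dd[1], dd[2])
    while (d <= 0) d <- .rng_rnorm(rs, 1L, dd[1], dd[2])
    rec <- follicle_record(
      id = sprintf("f%04d", i),
      follicle_diameter = d,
      oocyte_diameter = max(d * 0.6, 5),
      nucleus_visible = TRUE,
      granulosa_layers = mo$layers,
      granulosa_shape = mo$shape,
      antrum_present = mo$antrum,
      healthy = healthy[i])
    rec$stage <- st
    rec
  })
  do.call(rbind, rows)
}

#' Specification for a paired mRNA-protein fold-change table
#'
#' @param n_genes Number of genes.
#' @param log2fc_correlation Latent correlation rho of the two log2
#'   fold-change vectors, in `[-1, 1]`.
#' @param fraction_significant Fraction of genes given p < 0.05 on both
#'   axes (the rest get p in `[0.05, 1)`).
#' @param matrisome_fraction Fraction flagged as matrisome genes.
#' @param log2fc_sd Marginal standard deviation of the fold changes.
#' @param seed Integer seed.
#' @return List of class `omics_table_spec`.
#' @export
omics_table_spec <- function(n_genes = 1000L, log2fc_correlation = 0.5,
                             fraction_significant = 0.3,
                             matrisome_fraction = 0.2, log2fc_sd = 1.5,
                             seed = 1L) {
  .check_finite(list(n_genes, log2fc_correlation, fraction_significant,
                     matrisome_fraction, log2fc_sd, seed), "omics_table_spec")
  if (abs(log2fc_correlation) > 1) {
    stop("omics_table_spec: |log2fc_correlation| must be <= 1", call. = FALSE)
  }
  for (f in c(fraction_significant, matrisome_fraction)) {
    if (f < 0 || f > 1) stop("omics_table_spec: fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 log2fc_correlation = log2fc_correlation,
                 fraction_significant = fraction_significant,
                 matrisome_fraction = matrisome_fraction,
                 log2fc_sd = log2fc_sd, seed = as.integer(seed)),
            class = "omics_table_spec")
}

#' Generate a paired mRNA-protein omics table
#'
#' Log2 fold changes are bivariate normal with the requested correlation;
#' significance is generated through the p-values (a `fraction_significant`
#' subset receives p < 0.05 on both axes, all other genes p >= 0.05),
#' independently of the fold changes, so `fraction_significant = 0`
#' guarantees an empty differential set without distorting the fold-change
#' correlation.
#'
#' @param spec An [omics_table_spec()].
#' @return `data.frame` with columns `identifier`, `log2fc_mrna`, `p_mrna`,
#'   `log2fc_protein`, `p_protein`, `matrisome`.
#' @export
gen_omics_table <- function(spec) {
  stopifnot(inherits(spec, "omics_table_spec"))
  rs <- .seeded_rng(spec$seed)
  n <- spec$n_genes
  rho <- spec$log2fc_correlation
  z1 <- .rng_rnorm(rs, n)
  z2 <- .rng_rnorm(rs, n)
  fc_m <- spec$log2fc_sd * z1
  fc_p <- spec$log2fc_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  n_sig <- round(spec$fraction_significant * n)
  sig <- rep(FALSE, n)
  if (n_sig > 0) sig[.rng_sample(rs, seq_len(n), n_sig)] <- TRUE
  p_m <- ifelse(sig, .rng_runif(rs, n, 0, 0.05), .rng_runif(rs, n, 0.05, 1))
  p_p <- ifelse(sig, .rng_runif(rs, n, 0, 0.05), .rng_runif(rs, n, 0.05, 1))
  matrisome <- .rng_runif(rs, n) < spec$matrisome_fraction
  data.frame(identifier = sprintf("gene_%05d", seq_len(n)),
             log2fc_mrna = fc_m, p_mrna = p_m,
             log2fc_protein = fc_p, p_protein = p_p,
             matrisome = matrisome, stringsAsFactors = FALSE)
}
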