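test_that("noiseless single-component phantom is an exact rank-1 construction", {
  spec <- raman_phantom_spec(n_components = 1, nx = 6, ny = 5,
                             baseline_scale = 0, noise_sd = 0, spike_rate = 0,
                             seed = 1)
  g <- gen_raman_cube(spec)
  # every pixel spectrum proportional to the single pure spectrum
  s1 <- g$map$A[, 1]
  for (j in 2:ncol(g$map$A)) {
    ratio <- g$map$A[, j] / s1
    ratio <- ratio[is.finite(ratio)]
    expect_lt(diff(range(ratio)) / stats::median(ratio), 1e-10)
  }
  expect_equal(sum(g$spike_mask), 0)
})

test_that("per-pixel NNLS projection onto the true spectra recovers abundances", {
  skip_if_not_installed("pracma")
  spec <- raman_phantom_spec(nx = 12, ny = 10, baseline_scale = 0,
                             spike_rate = 0, seed = 7)
  g <- gen_raman_cube(spec)
  noise_sd <- 0.01 * max(g$pure_spectra %*%
                           do.call(rbind, lapply(g$abundance_fields,
                                                 function(f) as.numeric(t(f)))))
  est <- nnls_abundance_oracle(g$map$A, g$pure_spectra)
  truth <- do.call(rbind, lapply(g$abundance_fields, function(f) as.numeric(t(f))))
  expect_lt(max(abs(est - truth)), 3 * noise_sd)
})

test_that("generators are bit-identical for a fixed spec and seed", {
  spec <- raman_phantom_spec(nx = 8, ny = 6, seed = 7)
  g1 <- gen_raman_cube(spec); g2 <- gen_raman_cube(spec)
  expect_identical(g1$map$A, g2$map$A)
  expect_identical(g1$spike_mask, g2$spike_mask)
  h1 <- gen_height_map(surface_phantom_spec(seed = 3))
  h2 <- gen_height_map(surface_phantom_spec(seed = 3))
  expect_identical(h1$Z, h2$Z)
  c1 <- gen_follicle_cohort(cohort_spec(n_follicles = 40, seed = 5))
  c2 <- gen_follicle_cohort(cohort_spec(n_follicles = 40, seed = 5))
  expect_identical(c1, c2)
  o1 <- gen_omics_table(omics_table_spec(n_genes = 100, seed = 9))
  o2 <- gen_omics_table(omics_table_spec(n_genes = 100, seed = 9))
  expect_identical(o1, o2)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_raman_cube(raman_phantom_spec(nx = 4, ny = 4, seed = 2)))
  invisible(gen_height_map(surface_phantom_spec(grid_shape = c(10, 10), seed = 2)))
  invisible(gen_follicle_cohort(cohort_spec(n_follicles = 10, seed = 2)))
  invisible(gen_omics_table(omics_table_spec(n_genes = 10, seed = 2)))
  expect_identical(.Random.seed, before)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(raman_phantom_spec(spike_rate = 1.5), "spike_rate")
  expect_error(raman_phantom_spec(wavenumber_axis = c(400, 400, 500)), "increasing")
  pt <- list(data.frame(center = 800, width = 10, height = NaN))
  expect_error(raman_phantom_spec(n_components = 1, peak_tables = pt), "non-finite")
  expect_error(surface_phantom_spec(target_sa = -1), "target_sa")
  expect_error(cohort_spec(stage_proportions = c(primordial = 0.5, primary = 0.4)),
               "sum to 1")
  expect_error(omics_table_spec(log2fc_correlation = 1.2), "correlation")
})

test_that("height-map generator hits the target roughness and seeds differ", {
  h0 <- gen_height_map(surface_phantom_spec(target_sa = 0, seed = 1))
  expect_true(all(h0$Z == h0$Z[1, 1]))
  h1 <- gen_height_map(surface_phantom_spec(target_sa = 12.5, seed = 1))
  expect_equal(compute_sa(h1, "rms")$sa, 12.5, tolerance = 1e-9)
  h2 <- gen_height_map(surface_phantom_spec(target_sa = 12.5, seed = 2))
  expect_false(identical(h1$Z, h2$Z))
  expect_equal(compute_sa(h2, "rms")$sa, 12.5, tolerance = 1e-9)
})

test_that("follicle cohorts carry classifiable truth labels in spec proportions", {
  # single-stage cohort: every record classifiable as primordial
  c1 <- gen_follicle_cohort(cohort_spec(
    stage_proportions = c(primordial = 1.0),
    diameter_distributions = list(primordial = c(17, 2)),
    n_follicles = 20, seed = 1))
  expect_true(all(classify_follicle(c1) == "primordial"))
  # mixed cohort: classifier reproduces the generating labels exactly
  co <- gen_follicle_cohort(cohort_spec(n_follicles = 300, seed = 3))
  expect_identical(classify_follicle(co), co$stage)
  # empirical fractions within binomial 99% bounds of the spec
  big <- gen_follicle_cohort(cohort_spec(n_follicles = 1000, seed = 3))
  props <- c(primordial = 0.55, primary = 0.20, secondary = 0.15, antral = 0.10)
  for (st in names(props)) {
    k <- sum(big$stage == st)
    bounds <- qbinom(c(0.005, 0.995), 1000, props[[st]])
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
  # atresia_rate = 0 means every record healthy
  c0 <- gen_follicle_cohort(cohort_spec(n_follicles = 50, atresia_rate = 0, seed = 2))
  expect_true(all(c0$healthy))
  expect_true(all(c0$follicle_diameter > 0))
})

test_that("omics generator honours correlation and significance fraction", {
  # rho = 1 is a degenerate exact correlation
  o1 <- gen_omics_table(omics_table_spec(n_genes = 200, log2fc_correlation = 1, seed = 4))
  expect_equal(cor(o1$log2fc_mrna, o1$log2fc_protein), 1, tolerance = 1e-12)
  # rho = 0.5 at n = 5000 lands in the sampling band of r
  o2 <- gen_omics_table(omics_table_spec(n_genes = 5000, log2fc_correlation = 0.5,
                                         seed = 11))
  r <- cor(o2$log2fc_mrna, o2$log2fc_protein)
  expect_gt(r, 0.45); expect_lt(r, 0.55)
  # no significant fraction -> DEG filter is empty on both axes
  o3 <- gen_omics_table(omics_table_spec(n_genes = 500, fraction_significant = 0,
                                         seed = 5))
  expect_equal(deg_filter(data.frame(log2fc = o3$log2fc_mrna, p = o3$p_mrna))$n_total, 0)
  expect_equal(deg_filter(data.frame(log2fc = o3$log2fc_protein, p = o3$p_protein))$n_total, 0)
})
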