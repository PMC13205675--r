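test_that("range truncation keeps exactly the closed-interval channels", {
  sp <- raman_spectrum(100:3000, rep(1, 2901))
  tr <- truncate_range(sp, 400, 2000)
  expect_equal(length(tr$wavenumbers), 1601)  # integers in [400, 2000]
  expect_equal(range(tr$wavenumbers), c(400, 2000))
  # whole-axis bounds are the identity
  expect_equal(truncate_range(sp, 100, 3000)$intensities, sp$intensities)
  expect_error(truncate_range(sp, 500, 500), "lo < hi")
  expect_error(truncate_range(sp, 3500, 4000), "finite lo < hi|fewer than 2")
})

test_that("spike removal flags the generator's spikes and nothing else", {
  spec <- raman_phantom_spec(nx = 20, ny = 16, spike_rate = 0.002, seed = 13)
  g <- gen_raman_cube(spec)
  out <- remove_cosmic_spikes(g$map, z_threshold = 8)
  truth <- g$spike_mask
  expect_gte(sum(out$spike_mask & truth) / sum(truth), 0.99)
  expect_lte(sum(out$spike_mask & !truth) / sum(!truth), 1e-4)
  # unflagged values unchanged
  expect_identical(out$map$A[!out$spike_mask], g$map$A[!out$spike_mask])
  # spike-free phantom: empty mask, map unchanged
  g0 <- gen_raman_cube(raman_phantom_spec(nx = 10, ny = 8, spike_rate = 0, seed = 2))
  out0 <- remove_cosmic_spikes(g0$map)
  expect_equal(sum(out0$spike_mask), 0)
  expect_identical(out0$map$A, g0$map$A)
})

test_that("a spike shared by every pixel at one channel defeats neighbour comparison", {
  g <- gen_raman_cube(raman_phantom_spec(nx = 10, ny = 8, spike_rate = 0, seed = 4))
  A <- g$map$A
  A[300, ] <- A[300, ] + 100 * max(A)  # same artefact everywhere
  m2 <- hyperspectral_map(g$map$wavenumbers, A, g$map$nx, g$map$ny)
  out <- remove_cosmic_spikes(m2)
  # documented limitation: the neighbourhood median is itself contaminated
  expect_equal(sum(out$spike_mask[300, ]), 0)
})

test_that("single-pixel maps fall back to a within-spectrum median filter", {
  set.seed(1)
  y <- abs(rnorm(200)) + 10
  y[50] <- y[50] + 500
  m <- hyperspectral_map(seq(400, 2000, length.out = 200), matrix(y, ncol = 1), 1, 1)
  expect_message(out <- remove_cosmic_spikes(m), "single-pixel")
  expect_true(out$spike_mask[50, 1])
})

test_that("SNIP baseline: fixed points, lower bound, and peak stripping", {
  axis <- seq(400, 2000, length.out = 400)
  # constant spectrum is an exact fixed point
  cst <- raman_spectrum(axis, rep(5, 400))
  expect_equal(snip_baseline(cst, 40)$intensities, rep(5, 400))
  # linear ramp is an exact fixed point of the clipping average
  ramp <- raman_spectrum(axis, seq(2, 30, length.out = 400))
  expect_equal(snip_baseline(ramp, 40)$intensities, ramp$intensities,
               tolerance = 1e-9)
  # ramp + Gaussian peak: baseline tracks the ramp away from the peak
  peak <- 100 * exp(-(seq_len(400) - 200)^2 / (2 * 5^2))
  spc <- raman_spectrum(axis, ramp$intensities + peak)
  bl <- snip_baseline(spc, 40)
  away <- abs(seq_len(400) - 200) >= 15  # >= 3 sigma from the peak centre
  expect_lt(max(abs(bl$intensities[away] - ramp$intensities[away])), 5)
  # matches an independent implementation of the clipping recurrence
  expect_equal(bl$intensities, snip_oracle(spc$intensities, 40), tolerance = 1e-12)
  # baseline <= input pointwise, always (random spectra, LLS on and off)
  set.seed(42)
  for (i in 1:10) {
    y <- abs(rnorm(400)) + 5 * exp(-(seq_len(400) - sample(400, 1))^2 / 50)
    s <- raman_spectrum(axis, y)
    for (lls in c(FALSE, TRUE)) {
      b <- snip_baseline(s, 30, use_lls = lls)
      expect_true(all(b$intensities <= y + 1e-9))
    }
  }
  expect_error(snip_baseline(cst, 200), "max_half_window")
})

test_that("baseline subtraction clips at zero and counts clipped channels", {
  axis <- seq(400, 500, length.out = 50)
  s <- raman_spectrum(axis, rep(1, 50))
  b <- raman_spectrum(axis, c(rep(2, 10), rep(0.5, 40)))
  out <- subtract_baseline(s, b)
  expect_true(all(out$intensities >= 0))
  expect_equal(attr(out, "n_clipped"), 10)
  expect_error(subtract_baseline(s, raman_spectrum(axis + 1, rep(0, 50))),
               "different wavenumber axes")
})

test_that("Savitzky-Golay reproduces cubics exactly and smooths noise", {
  n <- 200
  axis <- seq(400, 2000, length.out = n)
  x <- seq_len(n)
  y <- 2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3
  sm <- savitzky_golay(raman_spectrum(axis, y), window = 9, order = 3)
  expect_equal(sm$intensities, y, tolerance = 1e-9)
  # constant unchanged
  expect_equal(savitzky_golay(raman_spectrum(axis, rep(3, n)))$intensities, rep(3, n))
  # white noise variance shrinks
  set.seed(7)
  z <- rnorm(1601)
  ax2 <- seq(400, 2000, by = 1)
  smz <- savitzky_golay(raman_spectrum(ax2, z))
  expect_lt(var(smz$intensities), var(z))
  # agrees with signal::sgolayfilt on the vectorized matrix path
  Y <- cbind(y, z[seq_len(n)])
  sm_mat <- ovamat:::.sg_matrix(Y, 9, 3)
  expect_equal(sm_mat[, 1], as.numeric(signal::sgolayfilt(y, p = 3, n = 9)),
               tolerance = 1e-9)
  expect_equal(sm_mat[, 2], as.numeric(signal::sgolayfilt(z[seq_len(n)], p = 3, n = 9)),
               tolerance = 1e-9)
  expect_error(savitzky_golay(raman_spectrum(axis[1:5], y[1:5])), "shorter")
})

test_that("area normalization yields unit integrals and is idempotent", {
  axis <- seq(400, 2000, length.out = 300)
  y <- abs(sin(axis / 100)) + 0.1
  s <- area_normalize(raman_spectrum(axis, y))
  expect_equal(sum(trapz_w(axis) * s$intensities), 1, tolerance = 1e-9)
  s2 <- area_normalize(s)
  expect_equal(s2$intensities, s$intensities, tolerance = 1e-12)
  expect_error(area_normalize(raman_spectrum(axis, rep(0, 300))), "non-positive")
})

test_that("the preprocessing chain is a pure function with documented effects", {
  spec <- raman_phantom_spec(nx = 10, ny = 8, seed = 21)
  g <- gen_raman_cube(spec)
  p1 <- preprocess_map(g$map)
  p2 <- preprocess_map(g$map)
  expect_identical(p1$A, p2$A)
  expect_true(all(p1$A >= 0))
  expect_equal(range(p1$wavenumbers), c(400, 2000))
  # every pixel is unit-area after the chain
  areas <- as.numeric(crossprod(trapz_w(p1$wavenumbers), p1$A))
  expect_equal(areas, rep(1, ncol(p1$A)), tolerance = 1e-9)
})
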