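---
title: "Methods: Raman unmixing, AFM roughness, follicle scoring and matrisome statistics"
author: "ovamat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman unmixing, AFM roughness, follicle scoring and matrisome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovamat)
```

`ovamat` packages the computational stages used to study extracellular-matrix
(matrisome) dynamics during early follicular development in the ovary:
hyperspectral Raman unmixing, AFM surface statistics, rule-based follicle
staging with a puberty score, and matrisome categorization with mRNA-protein
concordance. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the procedure
left genuine freedom. Every input can be simulated with known ground truth,
so all claims below are backed by the package's own test suite rather than
by external data.

## Raman preprocessing

A hyperspectral map holds one spectrum per pixel of a spatial grid
(channels x pixels matrix; pixels stored row-major, y outer, x inner). The
chain in `preprocess_map()` applies, in fixed order:

1. **Truncation** to the 400-2000 cm^-1 fingerprint window
   (`truncate_range()`, closed interval).
2. **Cosmic-spike removal** (`remove_cosmic_spikes()`). Cosmic rays hit one
   detector channel of one pixel. Each pixel's spectrum is compared to the
   median spectrum of its 8 spatial neighbours (centre excluded: an included
   centre makes the residual exactly zero whenever the pixel itself is the
   window median, which puts a point mass at zero in the residual
   distribution and deflates its MAD-based scale). A channel is flagged when
   its positive residual exceeds `z_threshold` (default 8) robust standard
   deviations (1.4826 x per-channel MAD across pixels) *and* the residual is
   one channel wide (the mean residual of the two adjacent channels stays
   below half the centre). The width criterion separates spikes from genuine
   tissue contrast, which makes a pixel exceed its neighbours smoothly over
   several channels. Flagged values are replaced by the neighbourhood
   median. Limitations follow directly from the model: an artefact present
   at the same channel in every pixel cancels in the spatial residual and is
   not flagged, and two spikes in adjacent channels defeat the width
   criterion. On a single-pixel map the method falls back to a
   within-spectrum running-median filter.
3. **SNIP baseline estimation and subtraction** (`snip_baseline()`,
   `subtract_baseline()`). Statistics-sensitive non-linear iterative peak
   clipping: for half-windows m = 1..M each intensity is replaced by
   `min(y_i, (y_{i-m} + y_{i+m})/2)`. Clipping is applied only where both
   offset neighbours exist, so constant and linear spectra are exact fixed
   points of the recurrence — the property the tests assert. The default
   M = 40 channels is a conventional choice for fluorescence backgrounds
   under ~100-channel-wide peaks; it is a config parameter, not a measured
   value. The optional log-log-square-root (LLS) compression protects weak
   peaks on intense backgrounds but is nonlinear, so the linear-ramp fixed
   point no longer holds under it; it therefore defaults to off and is
   exposed as `use_lls`. The baseline never exceeds the input, and the
   subtraction clips at zero (the factorization below requires
   non-negativity) while logging how many channels were clipped.
4. **Savitzky-Golay smoothing** (`savitzky_golay()`, 9-point window,
   polynomial order 3 by default). Edge channels use the dedicated
   least-squares edge filters rather than padding, because only those
   reproduce polynomials up to the fit order exactly over the whole
   spectrum — the package's asserted invariant. The implementation wraps
   `signal::sgolayfilt`; the vectorised per-map path is tested against it.
5. **Area normalization** (`area_normalize()`): each pixel spectrum is
   scaled to unit trapezoidal integral, correcting focus-driven intensity
   variation. A non-positive area is a dead pixel and raises an error.

The order (truncate, despike, baseline, smooth, normalize) follows the
order in which the steps are conventionally listed for this workflow; the
chain is a pure function of input and configuration.

## NMF unmixing

The preprocessed matrix `A` (n channels x m pixels, non-negative) is
decomposed as `A ~ W S` with `W` (n x k) the pure-component spectra and `S`
(k x m) the per-pixel concentration profiles, by minimizing the squared
Frobenius reconstruction error with the classical multiplicative updates.
These updates never increase the objective, which the implementation
records per iteration and the tests assert (non-increasing to 1e-10
relative slack). Because the problem is non-convex, `nmf_decompose()` runs
`n_restarts` (default 10) seeded uniform-random initializations in
`(0, max(A)]` and keeps the best final objective; iteration stops when the
relative objective change drops below `tol` (default 1e-6) or at `max_iter`
(default 500). The scale/permutation indeterminacy of NMF is resolved by
rescaling the columns of `W` to unit trapezoidal area (inverse scale
absorbed into `S`) and sorting components by total abundance. The component
count k is a user choice; `scree_over_k()` tabulates the best objective
over a k range (forced monotone by carrying the running minimum, since a
larger k can always represent a smaller k's solution).

Correctness is checked two ways that do not share code with the
implementation: per-pixel non-negative least-squares projections onto the
true spectra (active-set solver) recover phantom abundances, and on small
random matrices the converged multiplicative-update objective agrees within
1% with an independent alternating non-negative-least-squares solver.

## What the Raman phantom emulates — and what it does not

`gen_raman_cube()` builds `sum_c abundance_c (x) spectrum_c + baseline +
noise + spikes` with every latent factor returned. Pure spectra are sums of
Gaussian bands at collagen-, glycosaminoglycan- and cell-like literature
positions (measured tissue spectra are empirical mixtures; Gaussian bands
suffice to test recovery). Abundance fields are smooth Gaussian blobs at
distinct grid positions, mirroring the spatial cell-versus-matrix contrast
of tissue maps. The fluorescence baseline is a per-pixel quadratic whose
coefficients vary smoothly across the grid, as real backgrounds do — this
smoothness is what lets a spatial-median despiker work at all. Noise is
i.i.d. Gaussian at 1% of the maximum noiseless signal by default; cosmic
spikes are additive single-channel positive outliers at rate 0.1% per
channel-pixel with magnitude 25x the noise standard deviation, as genuine
cosmic-ray events are large. Not emulated: detector response and
wavelength-dependent noise, focus drift, saturations, or spatially
correlated (striping) noise. Passing recovery tests on the phantom
therefore demonstrate the pipeline's algebra and robustness to the modelled
artefacts, not performance on any particular instrument's data.

Recovery is asserted on a 50 x 40-pixel, 801-channel phantom: after
permutation matching, each recovered spectrum has cosine similarity >= 0.95
with its true counterpart and each concentration profile has Pearson
r >= 0.9 with the ground-truth field. One subtlety: per-pixel area
normalization makes concentrations *relative* (each pixel's abundances are
effectively divided by the pixel's total spectral area), so the recoverable
ground truth for the correlation test is each component's share of the
pixel's spectral area, which is what the acceptance test compares against.

## AFM maps

`compute_sa()` quantifies the dispersion of surface heights about the mean
height `Z_avg` over the N unmasked grid points. Two renderings are
provided because the printed formula for Sa is ambiguous about a square
root: the default `rms` variant `sqrt(mean((Z - Z_avg)^2))` (a plain mean
of squared deviations would carry squared length units, so the
root-mean-square reading is adopted) and the ISO arithmetic-mean deviation
`mean_abs`. Sa is translation-invariant and absolutely homogeneous, and
the mean-absolute variant never exceeds the rms one (Jensen); all three
properties are asserted on random maps. NaN entries are treated as masked
points, excluded from N and reported as a fraction. Young's-modulus maps
are consumed as data (force-curve fitting is out of scope) and summarized
by masked-aware location/spread statistics and a histogram. The standard
force-mapping geometry — a 50 um square grid sampled every 5 um with
inclusive endpoints, hence 11 points per axis — is exposed by
`grid_from_spec()`.

`gen_height_map()` produces a Gaussian random field smoothed to a requested
correlation length, centred, and rescaled so its rms Sa equals the target
exactly; the round trip through `compute_sa()` is exact by construction and
verified over many seeds.

## Follicle staging and the puberty score

`classify_follicle()` encodes the standard morphological criteria with a
fixed precedence, because the criteria themselves carry none: records
without a visible oocyte nucleus are excluded (the inclusion criterion);
an antrum makes the follicle antral; otherwise flattened (pre-)granulosa
means primordial, a single mixed cuboidal/squamous layer primary, and two
or more cuboidal layers secondary. A single fully cuboidal layer is
transitional and scored with the primary follicles. Contradictory
morphology (an antrum over a single flattened layer) classifies antral
with a warning rather than failing. The classifier is total: every valid
record receives exactly one label.

For MVH/ZP3 immunofluorescence, MVH (DDX4) marks every oocyte and proxies
the total follicle count, while ZP3 marks the zona pellucida of growing
(non-primordial) follicles. The MVH − ZP3 difference is therefore
semantically a primordial count, yet in neonatal culture, where growing
follicles are essentially all primary, it is conventionally read as the
primary count. Both labelling policies are implemented
(`derive_if_counts()`, default `"paper_literal"` = primary); a negative
difference is flagged and reported as zero.

The puberty score (`puberty_score()`) takes the six largest healthy antral
follicle diameters and classifies the single largest: SF < 250 um (score
−5), F1 250-300 (−4), F2 300-350 (−3), F3 350-400 (−2), F4 > 400 um (−1).
The printed classes are integer-labelled with 1-um gaps (300 vs 301); to
make the classifier total over real-valued diameters the classes are
half-open with inclusive upper bounds, which preserves every printed
integer boundary assignment. Fewer than six healthy antral follicles is
allowed with a warning; none at all scores −5 with flag `no_antral`. The
score is monotone in the largest diameter and always in [−5, −1].

The cohort generator defaults describe a peripubertal mouse ovary: stage
mix 55/20/15/10% (primordial/primary/secondary/antral), follicle diameters
of roughly 17 ± 2, 45 ± 10, 120 ± 25 and 320 ± 60 um respectively, and 10%
atresia. These are typical literature magnitudes chosen once for realism;
all are spec fields.

## Matrisome statistics

`annotate_list()` categorizes identifiers by case-folded exact match
against a MatrisomeDB-style reference (six categories: collagens,
proteoglycans, glycoproteins in the core matrisome; ECM regulators,
ECM-affiliated, secreted factors in the matrisome-associated division;
unmatched entries are non-matrisome). No alias or ortholog resolution is
attempted — identifier standardization pipelines are tool-specific and out
of scope. Duplicates are collapsed before counting and reported. The
bundled reference is a small synthetic fixture for tests; users supply
their own atlas CSV. `overlap_sets()` computes all `2^s − 1` Venn region
counts by exact set algebra and is property-tested against a per-element
membership-pattern oracle.

`deg_filter()` applies the differential-expression criterion
`|log2FC| > 1 and p < 0.05` with strict inequalities at both boundaries,
exactly as printed. `nine_quadrant()` classifies each gene by its joint
axis states (down / unchanged / up per axis, using the same strict
thresholds) into quadrants numbered `3*mRNA + protein + 1` (1 = both down,
5 = both unchanged, 9 = both up), and reports the Pearson correlation of
the two fold-change vectors computed over *all* supplied pairs with n —
restricting to significant genes is left as an explicit user choice, since
the convention varies.

The omics generator draws fold changes from a bivariate normal with the
requested correlation and generates significance through the p-values
(a chosen fraction receives p < 0.05 on both axes), independently of the
fold changes; this keeps the fold-change correlation undistorted and makes
`fraction_significant = 0` yield an empty differential set.

## Numerical choices and degenerate inputs

- Trapezoidal quadrature is used for all spectral areas (axes may be
  non-uniform).
- NMF updates guard divisions with the machine epsilon; an identically
  zero map or negative entries are errors naming the offending pixel and
  channel.
- `area_normalize()` and `preprocess_map()` treat non-positive spectral
  areas as dead pixels and fail loudly rather than producing NaNs.
- Annotation ties between reference labels are reported as unassigned with
  a tie flag rather than broken arbitrarily.
- `pearson_r()` refuses fewer than 3 pairs or zero variance.
- All generators take explicit integer seeds, are bit-reproducible, and
  never touch the caller's RNG state.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen so the full suite
completes in about a minute while still exercising every code path at the
study's stated measurement geometry: the recovery phantom is 50 x 40
pixels x 801 channels (one map of the order an instrument produces), NMF
oracle comparisons use 20 x 12 matrices, roughness checks 100 x 100 grids,
cohorts of 500-1000 follicles, and omics tables of 5000 genes.

## Known limitations

- The despiker cannot flag artefacts shared by all pixels at one channel,
  nor two-channel spikes (by design of the width criterion).
- SNIP with large M flattens genuinely broad bands; M trades baseline
  fidelity against band distortion and should be tuned to the widest band
  of interest.
- NMF solutions are local optima; restarts mitigate but do not guarantee
  the global optimum, and k must be chosen by the user (scree diagnostic
  provided).
- The matrisome reference shipped with the package is synthetic; category
  percentages computed against it say nothing about any real atlas.
- Raman component annotation uses literature-typical band positions; they
  are editable data, not measured truth.
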