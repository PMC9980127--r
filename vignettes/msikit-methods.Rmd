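---
title: "msikit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msikit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msikit)
```

This vignette is the package's own account of what its methods compute,
which knobs matter, and where genuinely open design choices were resolved.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The data model

An `msi_dataset` couples a feature-by-pixel intensity store with a pixel
table (`run`, 0-based integer `x`/`y` grid coordinates, arbitrary
annotation columns), a feature table (one m/z per row, ascending), and a
provenance list to which every processing operation appends exactly one
record. Pixel order is row-major within a run, runs concatenated in input
order; the imzML standard does not fix an order, so we fix one and keep it
stable through every operation. Missing annotations are `NA`, never a
sentinel number.

Intensities may live in memory (matrix, or a list of ragged vectors for
processed-mode data) or stay on disk in the `.ibd` file opened by
`read_imzml()`, in which case `msi_intensities(x, pixels)` materializes
only the requested pixel columns. Every whole-dataset statistic is routed
through `process_in_chunks()`, which materializes at most `chunk_size`
pixels at a time and combines per-chunk results along a fixed pairwise
(cascade) tree. Cascade reduction is why the answer does not depend on the
chunking: reassociating IEEE sums changes results, but a balanced fixed
tree keeps the discrepancy at the ~1e-12 relative level for any chunk size
or worker count, which is what the tests assert (bit-exactness across
worker counts is deliberately *not* promised).

# imzML I/O

The writer emits imzML 1.1 with the minimal controlled-vocabulary set:
mode (continuous/processed), "no compression", 32/64-bit float binary
types, external offsets/lengths, scan positions (written 1-based per the
imzML convention, converted to 0-based on read), a fresh type-4 UUID
duplicated in the `.ibd` head, and an MD5 of the `.ibd`. The reader
resolves `referenceableParamGroup` references as well as inline cvParams,
verifies the UUID and that every offset+length lies inside the file, and
returns a lazily backed dataset. `validate_imzml()` reports violations
(UUID mismatch, out-of-range or overlapping binary regions, missing mode,
continuous files whose spectra do not share one m/z record) instead of
raising. Integer binary types are read and upcast to double; only float
types are written.

# Preprocessing

* **Gaussian smoothing** (`smooth_gaussian`): discrete convolution with a
  truncated Gaussian kernel, renormalized over the available samples at
  the spectrum edges so no padding values are invented and constants are
  preserved. `window` is a sample count and must be odd for a centered
  kernel; an even request (MALDI protocols often quote one) is rounded up
  and the adjustment recorded in provenance. Defaults `window = 9`,
  `sd = 2` samples.
* **Baseline removal** (`remove_baseline_median`): the baseline is the
  per-block median over `blocks` equal-width index blocks, linearly
  interpolated at block centers with constant extrapolation at the ends.
  The residual is clamped at zero: profile intensities are nonnegative and
  negative residuals would corrupt TIC normalization downstream. A typical
  TOF profile uses several hundred blocks (default 750).
* **TIC normalization** (`normalize_tic`): each spectrum is scaled so its
  intensity sum equals the mean TIC of the non-empty spectra, computed
  before scaling. All-zero spectra are unscalable; they are left unchanged
  and flagged (`tic_zero`). Excluding them from the target mean is what
  makes the operation idempotent — including them would shrink the target
  on every reapplication.
* **ppm binning** (`resample_ppm_bins`): the shared axis is geometric,
  `m_{i+1} = m_i (1 + ppm·1e-6)` from the global minimum to the global
  maximum, so adjacent axis points differ by exactly `ppm`. Bin values are
  the mean of the samples falling in `[m_i, m_{i+1})` (sum is available
  for centroided input); empty bins are zero. This is also the route from
  ragged processed-mode files to a matrix-shaped dataset.

# Mass-axis correction

Alignment and re-calibration split the problem the way multi-sample TOF
studies do: first remove spectrum-to-spectrum jitter against the dataset's
own mean spectrum, then move the now-consistent axis onto true positions
using analytes of known mass.

**Alignment** (`mz_align_to_mean`) takes the `anchors` (default 20) most
intense mean-spectrum maxima as references, matches each to the nearest
local maximum of every spectrum within `tol_ppm`, and warps the spectrum's
sampling positions through the matched pairs by a piecewise-linear map,
re-interpolating intensities onto the shared axis. Three numerical
safeguards matter:

* anchor and per-spectrum maxima are SNR-filtered (MAD noise, threshold
  6), so matching can never latch onto noise spikes;
* matched pairs that would make the corrected positions non-monotone are
  dropped, largest correction first, and duplicate matches collapse to the
  nearest pair — the warp is strictly monotone by construction;
* the correction tapers linearly to zero over a margin of eight times the
  tolerance beyond the outermost matches. A hard return to identity at the
  match hull would create a non-monotone jump (and visible interpolation
  artifacts); with |correction| ≤ tol and an 8×tol margin the taper slope
  deviates from 1 by at most 1/8, which keeps peak areas near the taper
  essentially undistorted.

Spectra with fewer than two matches are left unwarped and flagged.
Alignment removes *relative* jitter only: a shift common to all spectra is
inherited by the mean spectrum and survives alignment by design — that is
what re-calibration is for.

**Re-calibration** (`recalibrate_internal`) locates each calibrant as the
nearest SNR-filtered mean-spectrum maximum within `tol_ppm` (default 200),
fits a linear model of the mass error against m/z to the matched pairs
(at least two required; fewer is an error naming the misses), and corrects
the shared axis globally. The report carries per-calibrant residuals
before and after. The model is global and linear; physics-based TOF
square-root laws and per-scan lock-mass correction are out of scope.

# Peaks

Noise (`estimate_noise`) is estimated per block — `mad` (1.4826 × median
absolute deviation, consistent for Gaussian noise) or `simple` (block mean
absolute deviation; the name follows common MSI usage, the definition is
ours and recorded here) — then linearly interpolated at block centers and
floored at machine epsilon. A sample is a peak (`detect_peaks`) when it is
a strict local maximum over ±`window` samples *with at least one strictly
lower neighbor in the window* (so plateaus count once, at their leftmost
index, and constant spectra yield nothing) and clears `snr` × noise.

`build_reference` detects peaks on the mean spectrum and attaches, per
reference m/z, the detection frequency (fraction of spectra with a local
maximum within `tol_ppm` — presence of a maximum, not nonzero area, which
is robust to baseline residue) and the mean of the per-spectrum maximum
intensity in the window. `filter_reference` keeps references by minimum
frequency and mean intensity. `integrate_peak_areas` integrates each
spectrum trapezoidally over ±`tol_ppm` windows; windows of adjacent
references are truncated at the midpoint between their m/z values so no
signal is counted twice (recorded in provenance). Integration against a
fixed ±ppm window (rather than out to local minima) is the documented
choice; it makes the operation linear in the spectrum, which the tests
exploit.

# Spatial weights and ion images

Neighborhoods are square (Chebyshev radius r, same run, self included)
with Euclidean distances inside — the square-window convention of
spatially aware MSI clustering. Gaussian weights use
`sigma = (2r + 1)/4`; the protocols that motivated the defaults quote only
r, so the kernel scale had to be fixed somewhere and this constant is
recorded here and in the configuration defaults. Adaptive weights multiply
by a bilateral term `exp(-delta^2 / (2 lambda^2))` where `delta` is the
spectral distance to the neighbor and `lambda` the maximum such distance
in the neighborhood (floored at machine epsilon); identical spectra make
the adaptive weights collapse to the Gaussian ones. Weights are
renormalized to sum to one per pixel.

`render_ion_image` places a resolved feature on each run's grid and
offers Gaussian or bilateral smoothing, contrast enhancement by
suppression (clip above the 0.99 quantile — configurable — then min-max)
or histogram equalization (normalized ranks), and linear min-max
normalization. "Linear normalization" is implemented as min-max; an
alternative reading (TIC-relative scaling) exists and is intentionally not
what this function does. A constant image has no range: it renders as
zeros with a `degenerate` attribute rather than dividing by zero.

# Spatial shrunken centroids

The model equations are the nearest-shrunken-centroids family (see the
README for the formulas): pooled within-class dispersions `s_j` offset by
`s0 = median(s_j)`, size factors `m_k = sqrt(1/n_k - 1/n)`, t-statistics
`d_kj`, soft threshold at `s`, reconstruction
`x̄'_kj = x̄_j + m_k (s_j + s0) d'_kj`. The `-1/n` convention matches the
variance of (class mean − overall mean); the `+1/n` variant is available
as `size_convention = "plus"` internally. Feature standardization is
realized by the `(s_j + s0)` scaling inside the scoring metric rather than
by pre-z-scoring the matrix; at `r = 0, s = 0` this makes predictions
coincide exactly with a diagonal-covariance nearest-centroid rule, which
the tests verify against an independently coded oracle.

Spatial information enters through exactly one mechanism: pixel spectra
are smoothed with the neighborhood weights before scoring, identically in
segmentation and prediction. (Smoothing class probabilities instead is a
defensible alternative; one mechanism applied uniformly is easier to
reason about, and at r = 0 the two coincide with the oracle either way.)

Segmentation initializes labels by seeded k-means on a pixel subsample
(10% of pixels, at least 2k; a degenerate k-means falls back to sampled
centers), then alternates model computation and reassignment
(`argmin_k Σ_j (x̃_ij − x̄'_kj)^2/(s_j+s0)^2 − 2 log π_k`, ties to the
lowest class index), drops emptied classes, floors priors at `1/(10n)`,
and stops when fewer than `tol = 1e-3` of labels change or at
`max_iter = 100`. Only the reassignment step has a guaranteed direction —
under the then-current model it cannot increase the assignment objective —
so that is what the fit records (`assignment_decrease`) and the tests
assert; the objective across iterations is also reported but model
re-estimation (s0, priors) may move it either way. Class probabilities are
`exp(-score/2)`, normalized.

A vector of `s` values is fitted as a regularization path in ascending
order, each fit warm-started from the previous labels (the same
continuation logic penalized-regression packages use). Warm starting keeps
the segmentations comparable along the path, and with stable labels the
count of surviving features is monotone non-increasing in `s` — the
property by which the shrinkage grid is read.

Classification (`ssc_fit_classifier`) is a single pass of the model
equations on given labels (≥ 2 classes, ≥ 2 pixels each — a singleton
class has no dispersion); smoothing applies at prediction time.
`cross_validate` partitions the *levels* of a grouping unit (e.g. tissue
cores of a microarray), never pixels, so spatially autocorrelated pixels
of one unit cannot sit on both sides of a fold; with a `rebin_hook`,
reference peaks are rebuilt from each fold's training spectra only and
both halves re-integrated, keeping peak selection inside the fold.
Accuracy ties resolve to the smaller model (larger `s`, fewer PLS
components).

# DGMM single-ion segmentation

EM on one feature's pixel intensities with per-pixel mixing proportions
`π_ik = (Σ w_ii′ γ_i′k + a)/(1 + k a)`: the spatial smoothing of
responsibilities plays the role of a soft spatial prior and the Dirichlet
pseudo-count `a` (default 1e-2) keeps proportions off the boundary. (The
exact prior update of the method this emulates is not published in a form
we could transcribe; this responsibility-smoothing variant is the
implemented definition.) Means initialize at the `(2q−1)/(2k)` intensity
quantiles with pooled-sd spread and a small seeded jitter; `σ_k` is
floored at 1e-6 of the intensity range (flagged when hit); optional
deterministic annealing raises responsibilities to `1/T` with `T` falling
geometrically 2 → 1 at ratio 0.9. Convergence is by relative
log-likelihood change. With `r = 0` and `a → 0` the fit coincides with a
plain Gaussian mixture on well-separated components, which the tests check
against a textbook EM oracle; the log-likelihood trace is asserted
non-decreasing (annealing iterations exempt).

# Class comparison, PLS, PCA, co-localization

`means_test` is deliberately group-then-test: pixel intensities are
averaged within each biological unit (sample, ROI, core) and a Welch
two-sample t-test compares group means between the two condition levels,
with Benjamini-Hochberg adjustment across features. Testing pixels
directly would treat thousands of autocorrelated pixels as independent
replicates; the function refuses to run with fewer than two groups per
level. The null calibration of this scheme (type-I error within
[0.03, 0.07] at α = 0.05 over 1000 simulated null datasets of 20 groups ×
200 features) is recomputed by the acceptance script.

`pls_fit` is NIPALS PLS2 on the mean-centered intensity matrix against the
centered one-hot class matrix; scores are mutually orthogonal by
construction, and with as many components as the matrix rank the
regression coefficients coincide with ordinary least squares (tested
against the normal equations at 1e-8). Prediction is the argmax of the
regressed class scores, ties to the first training class. `pca` wraps
`prcomp` (centered, unscaled). `colocalize` ranks features by Pearson
correlation with the query's ion image; the query lists first with
correlation exactly 1 (self-correlation is 1 by definition — computed
values are clamped to [−1, 1] to keep floating-point round-off out of the
ranking), and zero-variance decoys rank last with correlation 0 while a
zero-variance query is an error.

# The phantom generator

`generate_phantom` renders a declarative recipe: rectangular labeled
segments (plus a background) on per-run grids, per-segment Gaussian peaks
(m/z, amplitude, sd in Da), an exponentially decaying baseline,
multiplicative per-pixel TIC variation (default uniform 0.8–1.2), additive
Gaussian noise truncated at zero (intensities are nonnegative), and mass
drift applied to the *sampling positions* (instrument-like), either
constant per spectrum or growing linearly along the axis. The default
recipe — a 20 × 20 grid, m/z 500–2500 at 100 ppm sampling, three tissue
rectangles over a background sharing one common peak, 20% TIC spread,
noise at a few percent of peak amplitude — was chosen once as a plausible
small MALDI-TOF acquisition and is not adjusted per test; tests that need
a different axis or geometry declare their own recipe explicitly. The
generator returns the planted truth (segment map, peak table, per-spectrum
drift, TIC factors) alongside the dataset, and `write_fixture` emits the
imzML pair plus truth CSVs.

What the phantom does *not* emulate: isotope envelopes, matrix clusters,
detector saturation, correlated (pink) noise, and irregular tissue
boundaries. Tests passing on phantoms therefore demonstrate algorithmic
correctness against known truth — recovery of planted structure, exact
oracle agreement, calibrated error rates — not robustness to every
artifact of real acquisitions.

# Problem sizes and budgets

The test suite and acceptance script run on deliberately small instances —
grids between 4×4 and 50×40 pixels (up to 2,000 spectra), axes up to
~20,000 samples, 1,000 replicate null simulations for the type-I error
check — chosen so the whole suite completes in well under a minute while
still exercising chunked paths with several chunks and multiple workers.
The chunked contract, not the absolute size, is what makes the same code
paths scale to larger-than-memory data.

# Known limitations

* Processed-mode datasets must be resampled onto a shared axis before any
  matrix-shaped operation; there is no on-the-fly union axis.
* Re-calibration is global and linear in m/z; strong local distortions
  need more anchors at alignment time, not a higher-order model.
* The DGMM prior update is the responsibility-smoothing variant described
  above, not a full Markov-random-field posterior.
* `run_pipeline` validates step names and parameter keys, not parameter
  *values*; a type error inside a step still surfaces at execution.
* One run per imzML file pair: multi-run datasets round-trip through
  separate file pairs.
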