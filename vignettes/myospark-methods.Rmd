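---
title: "Methods: spark detection, T50 mapping and the phantom model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spark detection, T50 mapping and the phantom model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `myospark` — the things a maintainer or reviewer needs that the
function reference does not spell out.

## Conventions

All images are `rows x cols` matrices indexed 1-based with pixel centres at
integer coordinates, the R convention (`x` in tables means column, `y`
row). Intensities are processed as floating point regardless of input bit
depth; integer digital numbers are only re-imposed when writing 16-bit
TIFFs. Pacing-edge times stay in milliseconds at the trace's native
sampling — the 2 ms stimulus pulse is shorter than one frame period
(1000/395 ≈ 2.53 ms), so snapping edges to frames would lose real
information; frame indices are derived with a floor convention only where
an operation needs one.

## Pre-processing

The two spectral channels land on different halves of the camera with a
fixed relative magnification (0.9 on the reference instrument) and a small
unknown translation. Registration therefore has exactly two steps: a
deterministic rescale of the membrane channel by the known ratio (bilinear,
about the frame centre), then an exhaustive integer-translation search
(default ±10 px) maximizing the normalized cross-correlation of the two
temporal-mean images. The calcium channel — the quantitative one — is never
resampled, so ΔF/F₀ is never diluted by interpolation. A correlation peak
below `registration_min_corr` falls back to the identity with a warning.
Integer translation plus bilinear rescale means masks derived from the
registered membrane channel carry up to ~1 px of boundary blur; on a
striped phantom the recovered tubule mask overlaps the true lattice with a
Dice coefficient of roughly 0.92–0.95, which is the practical ceiling of
this registration class and the reason the test suite asserts 0.92.

Background is a per-frame scalar: the median intensity outside a dilated
provisional cell mask (Otsu on the temporal mean), subtracted and clipped
at zero. A scalar per frame tracks slow ambient/baseline drift but not
flat-field structure — flat-field correction is deliberately out of scope.
Cell segmentation is Otsu on the temporal-mean calcium image, closing with
a ~0.5 µm disc, hole filling, largest connected component. All three steps
are plain functions that can be swapped without touching later stages.

## Structure and the DNT map

Tubules are extracted directly in image space with no orientation prior: a
white top-hat (disc radius `tubule_filter_um`, default 0.7 µm ≈ the width
of a stained tubule in the image — the structuring element must be wider
than the ridges it should pass) followed by Otsu computed over cell pixels
only. Fourier-domain lattice methods are out of scope by design.

The DNT map is the exact Euclidean distance transform of the tubule mask
(computed over the full frame after discarding tubule pixels outside the
cell, then masked to the cell). The implementation delegates to
`EBImage::distmap`, which the test suite holds to *exact* equality against
a brute-force nearest-tubule-pixel oracle on random 64×64 instances. The
paratubular bound is stored in pixels (5) with the µm equivalent (0.74 µm)
derived from the pixel size. An empty tubule mask yields infinite
distances and a fully detubulated cell rather than an error.

## Spark detection

Detection runs on the last `n_blocks × block_len_frames` frames (the
unpaced tail of a recording; 5 × 1000 frames ≈ 12.7 s at instrument
defaults). The stack is smoothed with a normalized 5 × 5 × 3 box kernel —
the simplest kernel family consistent with fixed-size spatio-temporal
smoothing; edges are renormalized rather than padded. Each block is
normalized by its per-pixel temporal mean, making detection invariant to
gain and to slow drifts between blocks, and per-pixel thresholds are
`T_L = µ + 2.9σ`, `T_H = µ + 5.4σ` from the block's ΔF/F₀ moments.
Candidate events are connected components above `T_L` containing at least
one seed voxel above `T_H`. Connectivity is face-adjacent (6-neighbour) in
x-y-t; a second reading of a "minimum 6-pixel connectivity" rule —
26-neighbour components of at least 6 voxels — is selectable via
`connectivity = "min_size6"`, and the ≥50 px / ≥4 frame acceptance filters
subsume any small-size reading in practice.

The pass-2 refinement masks out pass-1 event voxels, re-estimates F₀ as the
per-pixel mean over the first 100 frames of each block (block mean over
unmasked frames as a fallback where the baseline window is entirely
masked), recomputes µ and σ with event voxels excluded, and re-detects.
Pixels with σ = 0 (possible in noiseless synthetic data) get a machine-eps
floor and cannot seed events. Blocks are hard boundaries: events touching a
block's first or last frame are flagged `boundary_truncated` and excluded,
consistent with the exclusion of "unfinished" events whose profile never
falls back below F50.

Characterization follows the area-averaged convention: the x-y-t component
is collapsed in time to a 2D footprint; the temporal profile is the mean
normalized intensity over that footprint; amplitude is (peak −
baseline)/baseline of that profile with the baseline taken over the block
frames outside the event. One consequence deserves emphasis: **the
area-averaged amplitude of a Gaussian-shaped spark is substantially below
its apex ΔF/F₀** (the mean of a Gaussian over its above-threshold footprint
is ~0.4–0.75 of the apex, depending on where the threshold sits), and the
F50 level derived from it widens the measured FWHM relative to the apex
half-maximum. These are properties of the estimator's definition, not
bugs; the test suite therefore checks amplitude against the closed-form
footprint-mean expectation, and FDHM and COM — which are insensitive to the
area averaging for separable events — against the generator truth
directly. FWHM counts the contiguous run of pixels at or above F50 along
the row/column lines through the COM at the peak frame (the contiguous rule
avoids inflation by distant super-threshold pixels), and FDHM uses the
smoothed profile (the same domain the detector operates in). Spark mass is
the exact identity `amplitude × mean(FWHM_x, FWHM_y) × FDHM` on every
emitted event.

Acceptance filters: area ≥ 50 px (strictly-below-50 rejected, i.e. 50 is
retained), on-time ≥ 4 frames, no unfinished/truncated flag. The 50 px
bound is taken as authoritative in pixels (it corresponds to 1.09 µm² at
the 0.1477 µm pixel, not exactly 1 µm²).

## Transient T50 mapping

The paced analysis segment is an 8 s window (four pacing periods at
0.5 Hz), by protocol starting two pacing periods into the recording
(`start_periods = 2`; phantoms that *are* the segment use 0). Smoothing is
a 5 × 5 median filter per frame plus a centred 3-frame moving average.
Global transient peaks come from the cell-average trace with a minimum
separation of 95% of a pacing period; three consecutive transients are
cropped to 525-frame windows centred on their peaks, each paired with the
pacing edge immediately preceding the peak.

Per pixel, baseline = mean of the 50 frames up to the edge, peak = mean of
the 20 frames from the *cell-average* peak frame, and
F50 = (baseline + peak)/2. The first upward crossing of F50 on the rising
limb — searched from the stimulus edge to the cell-average peak frame, the
first crossing winning if noise produces several — is refined by linear
interpolation between the bracketing frames; T50 is that time minus the
edge time. Pixels with peak ≤ baseline, no crossing, or already above F50
at the stimulus are undefined (`NA`), and aggregation over the three
transients (pixel-wise mean and SD) is defined only where all three maps
are. Because the peak estimate is a 20-frame average over the early decay,
it slightly underestimates the true maximum and shifts F50 down; with
transient kinetics in the physiological range this biases T50 by only a few
tenths of a millisecond, and the noiseless-phantom acceptance test bounds
the total pixel-level error by half a frame period (1.27 ms).

Regional summaries assume the cell is roughly horizontal in the FOV: cell
length is the span of columns with defined T50, the central ROI is the
middle half, the grouped outer ROIs the two end quarters, with nuclear
pixels excluded from the regional medians. The dyssynchrony index is the
IQR of T50 over all defined cell pixels. T50-vs-DNT slopes are ordinary
least squares per pixel population, with "tubulated" = DNT ≤ 5 px
(epitubular + paratubular) and "detubulated" = DNT > 5 px, and 95% CIs from
the slope's t-based standard error.

## Statistical routing

`choose_and_run_test()` routes: both samples pass the D'Agostino–Pearson
test (implemented here as the standard K² with the 1970 skewness and
Anscombe–Glynn kurtosis transforms, since no installed package provides
it; it matches an independent reference implementation to 10 decimals in
the tests) → t-test on raw values, with the F-test of variance equality
(at the same α = 0.05, which the source of the scheme leaves unstated)
deciding Welch's correction for unpaired comparisons; otherwise, if both
samples are strictly positive and their logs pass → t-test on logs;
otherwise Mann–Whitney or Wilcoxon signed rank. Zero paired differences
are dropped (the standard convention), and fully degenerate inputs return
an undefined p rather than an error. Samples below n = 8 cannot be
normality-tested and take the nonparametric route. Per-heart aggregation
averages cell-level values within heart, excludes hearts with fewer than
two cells (a singleton isolation carries no within-heart information), and
applies a one-sample t-test to the heart means. The imaging-time-window
filter scans every observed time as a candidate window start and keeps the
subset maximizing retained cells with both groups represented (ties: more
balanced groups, then earlier start) — one admissible reading of
"maximize overlap", and config-overridable.

## The phantom model

The generator emulates: an ellipsoidal cell (default 34 × 14 µm in a
256 × 128 px FOV — a deliberately short cell so that default phantoms
render at desk scale; all lengths scale through `pixel_size_um`); a
transverse stripe lattice at a whole-pixel period (2 µm → 14 px) with
0.7 µm stripes — the width of *stained, masked* tubules, chosen so the
lattice reproduces the ~35% masked-tubule coverage and ~1.5 px mean
random DNT characteristic of real recordings, not the ~250 nm anatomical
tubule — plus optional longitudinal elements, detubulated patches and up
to two tubule-free nuclei; a baseline map with mild edge falloff; paced
transients with the product kinetics
`A (1 − e^{−t/τ_rise}) e^{−t/τ_decay}` (defaults τ_rise = 10 ms,
τ_decay = 500 ms, A = 1.5, base latency 20 ms) and a per-pixel onset-delay
field (nuclear extra delay +3.5 ms, end-vs-centre offset −2 ms, optional
DNT-proportional term); sparks as separable spatial Gaussians times a
rise-decay exponential whose decay constant is solved numerically so the
rendered FDHM matches the drawn value; Gaussian read noise (default SD
20 DN on a 100 DN baseline) with optional Poisson shot noise; and a 1 kHz
top-hat pacing trace. Default spark rates (0.5 / 0.2 / 0.08 events per
100 µm² s⁻¹ for epitubular/paratubular/detubulated) reproduce the
spontaneous-rate regime of healthy rat ventricular myocytes, including the
~60%-lower paratubular rate and the predominance of tubule-centred events.

What it does **not** emulate: optical PSF and light-sheet physics,
photobleaching, motion (cells are modeled as pharmacologically
immobilized), flat-field structure, and spatially correlated noise.
Passing phantom tests therefore demonstrates the correctness of the
*algorithms* under known ground truth — not robustness to every optical
artefact of real data.

Determinism: `seed` fixes masks, spark draws and delay fields
(`generate_phantom`) and, offset by a constant, the rendered noise
(`render_recording`), so equal seeds give bit-identical movies and truth
tables. The delay field is quantized to 0.05 ms so the truth T50 field
(delay + analytic half-rise) is exact for the rendered movie. The analytic
half-rise oracle solves `F(t) = (F_peak + F_0)/2` on the rising limb by
bisection to 10⁻⁶ ms (closed form for the ramp shape), and is validated
against a dense-grid search.

Spark placement is `"poisson"` by default — independent draws, the
physiological process. The `"spaced"` mode greedily thins
spatio-temporally overlapping draws and exists for detector benchmarking:
overlapping events merge into one connected component and have no uniquely
attributable per-event truth, so recall/precision are scored on isolated
events. For the same reason the benchmark scores recall over truth events
whose COM lies at least 1.5 µm inside the cell border (an event centred on
the border has most of its footprint masked away, so its in-cell COM is
displaced by construction), while precision associates detections against
all truth events with a relaxed window.

## Problem sizes

The test-suite and acceptance-script phantoms are sized for a single-CPU
desk run: spark-recovery recordings are 112 × 112 px × 1000 frames
(two 500-frame blocks), transient phantoms 80 × 160 px × 3160 frames
(three analysed transients of four pacing periods), structural phantoms
96 × 160 px × 60 frames, and the DNT oracle sweep uses 64 × 64 masks. At
these sizes the whole suite runs in roughly ten minutes and the acceptance
script in under five.

## Known limitations

* Registration is integer-pixel; sub-pixel residuals (up to ~0.5 px plus
  rescale blur) propagate into masks derived from the membrane channel.
* The area-averaged amplitude convention under-reports apex ΔF/F₀
  (documented above); comparisons between spark populations are unaffected
  since the same estimator is applied everywhere.
* Regional ROIs assume an approximately horizontal cell; an off-axis cell
  should be rotated upstream (the generator can produce one via
  `orientation_deg`, and the summary's column-span convention will then
  mix regions).
* The spark-rate denominator uses the DNT-category areas of the analysed
  cell only; rates are undefined (NA), not zero, for absent categories.
* No multiple-testing correction and no multilevel models in the
  statistics module; those are explicitly outside its scope.
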