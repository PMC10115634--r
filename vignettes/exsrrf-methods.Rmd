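---
title: "ExSRRF methods: registration, radiality and nanoscale morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ExSRRF methods: registration, radiality and nanoscale morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exsrrf)
```

## Scope

Expansion microscopy physically enlarges a specimen (~3.7–3.8×) so that a
widefield microscope can see structures below its native diffraction limit;
super-resolution radial fluctuations (SRRF) then sharpens a short time stack
of the expanded sample computationally. This package implements the
computational half of that workflow: reading time stacks, correcting lateral
drift, computing the SRRF image, scoring the drift correction, and
quantifying the resulting ridge-like biology (slit diaphragms between
podocyte foot processes, ER networks) with reproducible "nanometrics":
ridge density, local spacing, width and peak-distance profiles, nanoruler
resolution calls and expansion-factor estimates. Seeded generators supply
every input class with known ground truth, so the whole pipeline runs and is
validated without microscope data.

## Drift registration

Every frame is aligned to the first frame of a reference channel. Each
reference frame is smoothed with a Gaussian of sigma 1 px, everything at or
below the 90th percentile of the smoothed values is set to zero (only the
brightest structures should drive the estimate), and the frame's histogram
is matched to the preprocessed first frame. The shift is then the maximiser
of the Fourier-domain cross-correlation, refined to 1/100 px by
matrix-multiply DFT upsampling (the Guizar-Sicairos algorithm). The negated
shift is removed from *all* channels: the integer part by crop-and-pad, the
fractional part by first-order interpolation, with a configurable fill
value; a flag (`subpixel = FALSE`) rounds shifts to whole pixels instead.

Numerical notes:

* The estimator uses the plain (unnormalised) cross-power spectrum.
  Phase-normalised correlation was evaluated and discarded: on
  percentile-clipped sparse frames it is substantially less accurate, as is
  windowing.
* Frames whose preprocessed reference is entirely zero fall back to
  raw-intensity correlation with a warning, rather than failing the stack.
* Shift-recovery accuracy is bounded by content crossing the frame border
  under drift (the cross-correlation sees a changing scene). The registration
  benchmark (`make_texture_stack`) therefore keeps its structures inside a
  margin at least as large as the maximal drift, which is also the generator
  contract for emitter stacks.

`make_texture_stack` emulates what the registration stage actually sees in
tissue work: a persistent, aperiodic, high-contrast texture (smoothed
uniform noise, contrast-squared, so bright structures sit on a dark
background), a global log-normal intensity fluctuation per frame (sd 0.3),
shot noise, and read noise set by `snr` = peak intensity over read-noise sd.
Point-emitter stacks with heavy blinking are deliberately *not* used here —
frames that share no persistent structure cannot be registered — and
periodic lattices are excluded because translation is only identifiable
modulo the period. At the benchmark conditions (64×64 px, 50 frames,
SNR 5, drifts up to ~10 px in subpixel steps) the pooled shift-recovery
RMSE is below 0.2 px.

## Drift-quality metrics

For each frame the offset is the 2-norm of its estimated shift; stacks are
summarised by the mean offset over frames 2..T and the final frame's offset.
MSSIM and MSE against frame 1 are computed before and after registration,
restricted to the overlap region that survives shift removal. Because rigid
translations make that region a rectangle, the metrics are computed on the
cropped rectangle; the padded-region fill value therefore cannot influence
them, not even through the SSIM window. Deltas are before − after, so
`delta_mssim < 0` and `delta_mse > 0` both indicate improvement. SSIM uses a
7×7 Gaussian-weighted window (sigma 1.5) with the standard stabilising
constants on a common [0, 1] rescaling of each compared pair.

Cohorts are stratified by "mean offset above the cohort mean + 0.5 sd" into
low and high drift; the phrase "0.5 sd from the mean" anchors the threshold
at the mean, and the alternative absolute reading (0.5 sd alone) is
available via `threshold_mode = "half_sd"`. The mean offset (rather than
the last offset) is the stratification statistic because it is less
sensitive to a single noisy frame; both are reported.

## The SRRF radiality transform

For each position $c$ of the $M\times$-magnified grid, $K = 2A$ points are
sampled on a ring of radius $r$ (source pixels). The image gradient at each
ring point (bilinear interpolation of centred differences; optional Gaussian
pre-smoothing of sigma 1 when `gradient_smoothing` is on) defines a line
through that point. With $d_k$ the perpendicular distance from $c$ to that
line, the sample contributes

$$s_k = \pm \max\!\left(0,\, 1 - d_k / r\right)^{6},$$

positive when the gradient points toward $c$ (convergent — the centre of a
bright structure), negative otherwise; flat samples contribute 0. Radiality
is the mean over the ring, clamped at zero under the positivity constraint
and multiplied by the Catmull-Rom-interpolated frame intensity under
intensity weighting. The temporal radiality average (TRA) is the pixel-wise
mean over frames.

Design choices worth stating:

* **Kernel sharpness.** The convergence ramp is raised to the sixth power.
  With a linear ramp the radiality of an isolated emitter keeps a halo of
  ~18% of its peak at 0.8 px distance, which fills the gap between emitter
  pairs below one PSF FWHM and makes sub-diffraction separation impossible
  under the "no signal between the maxima" rule; nanoruler experiments
  resolve such pairs in practice, so the kernel must decay faster than its
  own support. The exponent is fixed, not exposed, and the kernel is
  isolated in one compiled function so alternatives can be swapped.
* **Anti-patterning.** Interpolation biases give the $M\times M$
  subpixel-offset classes of the magnified grid systematically different
  mean levels, visible as an $M$-periodic lattice. The correction shifts
  each class by a constant so all class means equal their grand mean. An
  additive correction is used deliberately: a multiplicative rescaling (the
  other obvious choice) distorts sparse signals, because the classes
  containing an emitter's peak then get scaled by background-driven
  factors — in testing this displaced localized peaks by more than a
  magnified pixel at moderate noise. The additive form preserves the image
  mean exactly and suppresses the lattice frequency.
* **Unimplemented flags.** `renormalize` and `gradient_weighting` are
  accepted (the reference settings run both disabled) but raise a
  documented error when enabled.
* Temporal aggregation is restricted to the average (TRA);
  autocorrelation modes are out of scope.

Peak readout on SRRF maps (`peak_position`) refines the argmax by an
intensity-weighted centroid, optionally after smoothing the map with a
Gaussian at the scale of the radiality peak (the localization benchmark
uses 5 magnified px against a peak of comparable half-width) — a
matched-filter reading that suppresses pixel noise without displacing a
symmetric peak.

### Resolution benchmark

The nanoruler generator places two point marks at
`distance_nm * expansion_factor / pixel_size_nm` px and blinks them
independently. Two-mark separation on a TRA image is carried by frames in
which only one mark is lit: when both are on, a pair below ~2σ separation
merges into a single blob whose gradients converge on the midpoint. The
resolution benchmark therefore runs at duty cycle 0.1 (sparse blinking, the
regime SRRF is designed for), 50 frames, bright marks (1000 photons/frame)
and low read noise (sd 2, an exposure-optimised acquisition), probing
distances of {0.5, 0.8, 1.2, 2.0} PSF FWHM. The separation call
(`psf_separation`) mimics the visual criterion: normalise the crop, apply a
10% signal floor, and require exactly two dominant blobs (peak ≥ 15% of the
maximum, area ≥ 4 px, peak at least 5 robust sd above the image median)
with at least one below-floor pixel on the segment between their maxima.
Under these conditions SRRF separation is monotone in distance, the
widefield frame average separates essentially nothing up to 2 FWHM
(its valley at 2 FWHM is ~12.5% of peak, above the floor), and SRRF is
never worse and strictly better overall. At 0.5 FWHM both methods sit near
zero — separations there occur only for fortuitously asymmetric blinking —
consistent with the smallest rulers being at the edge of what temporal
radiality averaging can resolve.

## Ridge nanometrics

The region of interest is extracted at 25% scale (block-mean downsampling,
mass-preserving): optional low-level noise cut at 5% of the maximum (sd
preset), Gaussian smoothing (sigma 8; the er preset applies sigma 8 then
sigma 10 and skips the noise cut and the closing), Otsu threshold, binary
hole filling (+ closing with a disc of radius 5 for the sd preset), then
removal of components of at most 5000 downsampled pixels; the mask is
upsampled back by nearest neighbour (label-preserving).

Ridges are segmented with the Meijering neuriteness filter — modified
Hessian eigenvalues with $\alpha = 1/3$, Gaussian-derivative Hessian
computed as a cascade of two first-derivative passes at $\sigma/\sqrt 2$
(wide truncation), per-scale max-normalisation and the pixel-wise maximum
over scales. The port agrees with the scikit-image reference implementation
to machine precision, which one test asserts through the system Python. The
normalised response is thresholded at 0.2 (sd) or 0.25 (er, with objects
under 125 px removed first), opened with a disc, and restricted to the ROI.
Density is the ratio of ridge pixels to ROI pixels.

Local spacing is the local-thickness transform: with $d(c)$ the exact
Euclidean distance from a free pixel $c$ (inside the ROI, outside the
ridges, with the frame border counting as boundary) to the nearest non-free
pixel, the spacing at $p$ is $\max\, 2d(c)$ over centres $c$ with
$\lVert p - c\rVert < d(c)$ — the diameter of the greatest open disk that
fits in the free space and covers $p$. The implementation (Felzenszwalb
exact EDT + descending-radius disk painting, all comparisons in the exact
squared-integer domain) is tested for *bit-exact* equality against a literal
$O(N^2)$ double loop over pixel pairs. Statistics (mean, median, sd) are
taken over the free pixels; the "area fraction" is the fraction of free
pixels with a defined (positive) spacing, which is an interpretation — under
the open-disk definition every free pixel covers itself, so it equals 1
whenever the free set is non-empty. The 8-bit display map rescales the
defined spacings to 0..255.

Width profiling thresholds the image with the iterative intermeans
(isodata) algorithm — the fixed point of
$t \leftarrow (\mu_{\le t} + \mu_{> t})/2$ on a 256-bin histogram, iterated
from the mid-range — and measures the contiguous above-threshold run of a
bilinear line profile containing its brightest sample, with subpixel edges
by linear interpolation of the threshold crossing. An oblique line measures
the geometrically foreshortened width. Profiles with two maxima also report
the peak distance (parabolic subpixel refinement), which feeds the
expansion factor: post- over pre-expansion peak distance of the same
structure, referenced at micrometre scale where single-pixel localization
noise is negligible relative to the distance.

Foot-process segmentation thresholds the separator (isodata), inverts, and
applies watershed on the distance transform; only the automatic stages are
implemented (the published workflow adds a supervised curation step).

### Detector scale for the density benchmark

The ridge-detector scale set is configurable (`ridge_sigmas`, default
1, 2, 3 for tissue work, where structure widths vary). The lattice density
benchmark measures 3–4 px wide lines and uses a single matched scale of
1.3 px with the opening disabled: the multiscale union inflates a 3-px line
to a ~5-px mask (a 20–60% density error), and an opening of radius 2
deletes 3-px ridges entirely. Axis-aligned lattices quantise any measured
width to whole pixels, so benchmark densities are averaged over 16 sub-pixel
lattice phases, and the lattices carry a 0.9 px optical blur; with those
choices measured densities sit within 10% of width/period and within ~1%
between 0° and 37° orientations, deterministically.

## Synthetic data: what it does and does not emulate

The generators cover point emitters with Bernoulli blinking and optional
log-normal brightness fluctuation, Gaussian PSFs (flux-normalised so
noise-free frames conserve total emitter flux to <0.1% truncation), linear /
random-walk / explicit drift, Poisson shot noise and Gaussian read noise,
nanoruler pairs, anti-aliased ridge lattices, interdigitating foot-process
phantoms (comb-like teeth separated by a thin bright separator curve, with
an "effaced" variant that widens the teeth and deletes a fraction of the
separator segments) and the registration texture described above. They do
not emulate triplet-state photophysics, bleaching kinetics, 3-D PSFs, gel
distortion or autofluorescence backgrounds; a pass on synthetic data shows
the algorithms are implemented and calibrated as described, not that real
tissue will reach the same numbers.

Problem sizes used by the test-suite benchmarks: 20 registration stacks of
64×64×50; 10 localization and 40 nanoruler stacks of 32×32×50 at
magnification 10; 10 spacing-oracle masks of 48×48; 64 lattice segmentations
at 256×256; 20 interdigitation phantoms at 160×160; 20 expansion pairs;
100 threshold histograms. All seeds are fixed in the tests and derived from
`--seed` in `scripts/acceptance.R`.

## Known limitations

* Registration is rigid translation only; rotation and non-rigid distortion
  are out of scope, as is correlative pre/post-expansion alignment.
* The radiality kernel is one concrete realisation of the published
  idea; its sixth-power sharpness was chosen so that isolated-emitter halos
  do not preclude sub-FWHM separation, and other choices would shift the
  absolute separation rates (not the orderings the tests assert).
* The anti-patterning correction is a stated stand-in for an undocumented
  reference behaviour.
* `measure_sd_width` reports the run containing the profile's brightest
  sample; profiles crossing several structures should be drawn per
  structure.
* Isodata thresholds are not unique fixed points on every histogram; the
  implementation returns the one reached from the mid-range start, and the
  oracle test asserts membership in the exhaustively enumerated fixed-point
  set.
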