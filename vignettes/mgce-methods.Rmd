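---
title: "Methods: digitizing the MG core examination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digitizing the MG core examination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgcekit)
```

This vignette is the package's own account of its methods: the models and
conventions behind each exercise metric, the parameters that matter and why
their defaults were chosen, what the synthetic generators do and do not
emulate, and the known limitations. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## Coordinate and schema conventions

All pixel coordinates use the native image convention: origin top-left,
y increasing downward, so *elevation* of a landmark means *decreasing* y.
This is deliberate — converting to a y-up convention invites silent sign
errors at every image interface. The face schema uses 1-based indices
(eye hexagons 37–42 / 43–48, mouth 49–68, nose base 34), the body schema
0-based indices (shoulders 11/12, elbows 13/14, hips 23/24), each matching
the convention of the detector family that produces it; `mgce_landmarks`
is the single constants table and `face_point()` / `body_point()` do the
conversion. Detector adapters are a plug-in boundary: the package consumes
landmark streams (CSV/JSONL) and never imports a detector.

Frames with detector confidence below 0.5 are flagged, not dropped: series
keep their full time base, and fits and event detectors exclude masked
points. The floor is configurable; 0.5 is the conventional midpoint and the
choice only matters for marginal detections.

## Eye segmentation at telehealth resolution

A webcam eye region is roughly 40×20 px. Circle-based iris detectors
(Hough-transform or integro-differential) need more pixels and stabler
illumination than that regime provides, so the segmenter is a hybrid local
search inside the detector's ROI:

1. grayscale (Rec.601 luma) and a 1st–99th percentile contrast stretch;
2. 2-class intensity clustering — Otsu threshold by default, 1-D k-means as
   a config switch; the two agree on bimodal patches and Otsu is
   deterministic — isolating dark pixels;
3. the largest dark connected component of ≥ 6 px² is the iris+pupil blob
   (ties broken toward the patch centre; smaller components are lashes or
   shadow). If none exists, the eye is reported `closed` rather than
   guessed — a quality flag is a result, a guess is a defect;
4. the pupil centre is the blob's darkness-weighted centroid. At this
   resolution iris and pupil are not separable, so the blob centroid *is*
   the operational pupil centre; the bias this introduces is part of what
   the accuracy batch measures;
5. lids: per column, the strongest bright→dark downward gradient just above
   the blob (upper lid) and dark→bright below it (lower lid), refined to
   sub-pixel by parabolic interpolation of the gradient peak, then fitted
   by a quadratic with one round of 2·MAD outlier rejection. A quadratic
   matches lid curvature over a 40 px span; higher orders chase noise.

The minimum dark-component area (6 px²), stretch percentiles and gradient
search margin (2 rows) are exposed in `eye_seg_params()`. The three
per-frame measures (`eye_measures()`) are evaluated on the fitted curves at
the pupil column: lid-to-lid distance, lid-to-pupil distance, and the
opening area integrated in closed form over the iris span.

`segmentation_accuracy_batch()` is the standing benchmark: 40×20 patches
with pupil centre drawn in x ∈ [16, 24], y ∈ [8, 12], iris radius
[4, 6] px, initial lid-to-pupil distance [3, 6] px and pixel noise sd 0.05
— a regime in which the upper lid partially occludes the iris, as during
sustained upgaze. The acceptance thresholds for this batch (mean pupil
error ≤ 3 px, mean lid-to-pupil error ≤ 2 px) are deliberately loose
relative to typical performance on clean renders; they are the regime's
requirement, not the method's ceiling.

## Ptosis and alignment

The ptosis exercise is summarized by ordinary least squares of the
lid-to-pupil distance over the exercise window. Percent decay is computed
from the *fitted* endpoints, making it robust to endpoint noise, and
"significant decay" means the standard two-sided slope t-test at α = 0.05
(no test is canonical for this exam; OLS + t-test is the minimal defensible
choice). Series require ≥ 10 usable frames spanning ≥ 30 s by default —
half the nominal 60 s exercise — below which a fit would be dominated by
frame-level jitter. An exponential relaxation-time fit is provided but
marked exploratory: it is not an exam metric.

Alignment uses the barycentric coordinate of each eye's inner iris border
between the eye corners (hexagon extremes 37/40 and 43/46, configurable).
The misalignment baseline is the median of the first 2 s: the patient
fixates before the lateral hold begins, and a median over ~2 s of frames is
insensitive to startup artifacts. The steadiness threshold (0.1 barycentric
units ≈ 10% of the corner span) flags gross divergence, not microsaccades.

## Motor kinematics

The arm angle is measured against the *image* horizontal through the
shoulder midpoint, not the shoulder-to-shoulder axis: the exam instructs a
horizontal arm hold, and a tilted torso should register as a tilted arm.
Smoothing is Savitzky–Golay (order 4, 1 s window): it preserves
polynomials up to its order exactly, so the linear decay the fit targets
passes through untouched while frame-level jitter is attenuated; any filter
with that property is conformant. Drift is declared when the smoothed angle
stays below −5° for ≥ 1 s. The exam's grading rows never define "drift"
numerically; −5° is small enough to catch early drift yet ~5 smoothed
standard deviations above 1°-level landmark jitter, and the 1 s hold
rejects transients. Both are configurable, and the drift-recovery test
(onsets uniform in [5, 115] s, jitter sd 1°, fall rate 10°/s) checks the
detector, with these defaults, recovers onsets within ±1 s.

Sit-to-stand: hip elevation is smoothed with a 0.3 s window (a ~1 s rise
must not be flattened), plateaus are medians of the first and last 15% of
frames, and the rise is the crossing from within 10% of the seated plateau
to within 10% of the standing one. Speeds are central differences over
~0.2 s — wide enough to suppress the smoother's overshoot at plateau
corners, short against the rise. Lateral sway is the RMS of hip x about its
mean during the rise. Pixel-to-cm calibration comes from a known reference
(the seat) via `calibrate_pixels()`.

## Facial features

The cheek exercises are read through mouth geometry, which survives
lighting changes that defeat appearance signals. The headline feature is
the upper-lip-to-nose-base distance (landmarks 52 and 34 by default; the
schema has no unique "nose bottom", so both indices are config) normalized
twice: by the inter-ocular distance (zoom invariance) and by its
baseline-window mean (rest value ≡ 1). A cheek puff then reads as a step
from 1. Events are spans where the feature deviates from the baseline mean
by > 4 baseline-MAD sigmas for ≥ 0.5 s, with sub-0.3 s gaps merged; the
MAD makes the threshold immune to baseline outliers, and a constant
baseline with zero deviation yields no events rather than an error. The
signed mouth angle (segment 49→55 vs. horizontal) captures the one-sided
tongue push; the switch detector centres the series on its midrange — with
two sustained plateaus the midrange sits between them regardless of their
relative durations, where a median collapses onto the longer plateau — and
requires ≥ 1 s and ≥ 1° mean amplitude on each side.

The blue-channel cheek illumination series is retained as a secondary
signal with an explicit caveat: it is sensitive to lighting and may depend
on skin tone, so it supplements the geometric features, never replaces
them. Detector-confidence masks propagate; events are suppressed on masked
spans (beards, occluding fingers and similar failure modes arrive as
low-confidence landmarks).

## Voice features

Speech segmentation runs on a twice-reduced signal: RMS magnitude over
sample blocks to ~1000 Hz, then block means of 60 to a ~16.7 Hz envelope.
The intermediate 1000 Hz series is explicit config rather than an
assumption about the recording: breathing-band analysis (5–25 Hz) needs a
series whose Nyquist exceeds 25 Hz, which the envelope cannot provide, and
the block-of-60 averaging is only coherent on such a series. The envelope
threshold is 3 × median (the median is the noise floor whenever speech
occupies under half the exercise), capped at the median–maximum midpoint so
continuous voicing still segments; gaps < 0.15 s are bridged and segments
< 0.05 s dropped — values chosen to absorb intra-word dips without
fusing adjacent counted numbers at a ~1/s counting rhythm. Counting-to-50
keeps the 50 longest segments, ties to the earlier start.

Loudness implements the BS.1770-4 / R128 measurement model (K-weighting
designed parametrically so any fs ≥ 8 kHz is supported; 400 ms blocks, 75%
overlap, −70 LUFS absolute then −10 LU relative gating, mono weight 1.0)
and is checked against the standard's calibration point (a full-scale
997 Hz sine reads −3.01 LKFS) and its gain law. Pitch is per-segment
normalized autocorrelation searched over 50–400 Hz — spanning the typical
adult male (85–155 Hz) and female (165–255 Hz) ranges with margin — with a
0.5 peak-correlation voicing gate. Spectral entropy normalizes each
frame's power spectrum (DC excluded) to a probability distribution;
division by log(bins) bounds it in [0, 1]. Entropy peaks use a prominence
threshold of 0.1: "singular peaks" have no canonical definition, and 0.1
on a unit-bounded series ignores ripple while counting genuine prosody
excursions. Single-breath features are the segment-span duration, the
energy integral Σx²Δt over speech (airflow proxy, uncalibrated), and the
voiced fraction.

## Grading

Printed grade boundaries are applied verbatim with inclusive interval
semantics. Two seams exist in the printed rows and both resolve to the
milder grade: an arm-drift onset of exactly 120 s (between "no drift
> 120 s" and "90–119 s") grades 0, and a dysarthria onset at exactly 50
grades 0. A dysarthria onset below every printed interval (count 0) grades
3 — that is beyond the severe end, not a between-grade seam. The
lid-at-pupil band for ptosis is |d| ≤ 1 px by default (configurable): at
telehealth resolution, sub-pixel distinctions between "at" and "above" are
not meaningful. Visual categories the vision modules cannot certify —
cheek "transverse pucker", "need to use hands" — are manual annotations;
automated features ride along as supporting evidence.

## Synthetic generators: what they emulate, and what they do not

The generators reproduce the *acquisition regime*, not appearance: eye
patches are anti-aliased discs under parabolic lid occluders with Gaussian
pixel noise; landmark streams are kinematically consistent trajectories
(linear arm-angle decay after onset, cosine-ramp stand-up with sinusoidal
sway, linear ptosis decay with multiplicative measurement noise) with
Gaussian jitter; counting audio is raised-cosine sine bursts over Gaussian
noise at a stated SNR. Defaults encode the exam's nominal conditions: 60 s
ptosis hold with a 15% decay option, 120 s arm hold, 50 bursts at roughly
one per second, SNR 20 dB, 8 kHz audio. All generators are bit-deterministic
under a fixed seed, and their ground truth is internally consistent with
the package's own measures to 10⁻⁹.

Passing on these fixtures therefore demonstrates correctness of the
*algorithms* under controlled degradation. It does not demonstrate
robustness to specular corneal reflections, eyelash texture, makeup,
glasses, compression artifacts, rolling-shutter distortion, reverberant or
non-stationary room noise, or detector failure modes (beards, high BMI,
occluding fingers) — on real footage those arrive, at best, as low
detector confidence and quality flags.

## Problem sizes and numerical choices

The test suite works at the scale the methods target: 50–60 eye patches
per accuracy batch, 60 s series at 10–15 fps, 50-replicate recovery suites,
20–50-burst audio at 8 kHz. The acceptance script renders its batch and
ptosis sequence fresh at every invocation from the supplied seed.
Degenerate inputs have defined behaviour rather than errors where a result
is still meaningful (constant series → zero slope with p = 1; zero-variance
baseline with zero deviation → no events; silence → gated/undefined
loudness flags) and classed errors where it is not (insufficient frames,
degenerate geometry, windows longer than the series).

## Known limitations

* The pupil centre is the iris+pupil blob centroid; under heavy lid
  occlusion it biases toward the visible portion. The accuracy batch
  includes moderate occlusion; extreme ptosis (blob < 6 px²) reports
  `closed` instead.
* Eye-corner positions for alignment come from the caller (landmark
  hexagon extremes); corner localization error propagates directly into
  the barycentric coordinate.
* The illumination cheek signal is not lighting-robust by construction.
* Dysarthria itself is not detected; the count at which it appears is an
  annotation, as are the exam's visual categories.
* Voice features assume a single speaker on a mono track; overlapping
  examiner speech contaminates segments.
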