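# mgcekit

Quantitative analysis toolbox for the telehealth **Myasthenia Gravis Core
Examination (MG-CE)** — the standardized 8-item physical exam (ptosis,
diplopia, cheek puff, tongue-to-cheek, counting to 50, arm strength,
single-breath count, sit-to-stand) administered over a video call.

Clinicians grade these exercises by eye, on ordinary webcam footage where an
eye region may be only ~40×20 pixels. `mgcekit` replaces that subjective read
with reproducible measurements computed from the session's media and
landmark streams, and maps them onto the exam's ordinal 0–3 severity grades.
It is written for clinical researchers digitizing neuromuscular telehealth
exams and for engineers building the analysis backend of such platforms.

## What it computes

**Ocular.** A hybrid segmenter refines each eye region (detector landmarks
give the ROI; re-implementing detectors is out of scope): 2-class intensity
clustering isolates the dark iris+pupil blob, whose darkness-weighted
centroid serves as pupil centre; per-column vertical-gradient extrema,
robust-fitted by quadratics, give the lid curves. Per frame this yields the
three ptosis measures — lid-to-lid distance *d*<sub>ll</sub>, opening area,
and lid-to-pupil distance *d*<sub>lp</sub> — and the ptosis exercise is
summarized by the OLS fit *d*<sub>lp</sub>(*t*) = *a* + *b t* with its
percent decay 100·(*d̂*(t₀) − *d̂*(t₁))/*d̂*(t₀) and slope t-test. For
diplopia, each eye's inner iris border becomes a barycentric coordinate
*b* = (x<sub>iris</sub> − x<sub>inner corner</sub>)/(x<sub>outer</sub> −
x<sub>inner</sub>) ∈ [0,1]; misalignment is the drift of *b*<sub>L</sub> −
*b*<sub>R</sub> from baseline.

**Motor.** From 33-point body-pose streams: arm angle
θ = −atan2(Δy, |Δx|) of the shoulder→elbow segment against the image
horizontal (0° = horizontal, negative = fallen arm), Savitzky–Golay
smoothed; drift onset is the first sustained excursion below −5°. The
sit-to-stand maneuver is tracked through hip elevation: rise interval,
peak upward speed and acceleration (cm/s with seat-based pixel
calibration), and lateral sway RMS.

**Facial.** Mouth geometry from 68-point face streams: corner distance
(landmarks 49–55), signed mouth angle, inner-lip opening/seal flag, lip
curvatures, and the upper-lip-to-nose distance normalized by inter-ocular
distance and its rest baseline — a near-step curve during a cheek puff,
detected as events against the baseline MAD. The tongue-to-cheek switch is
the sign reversal of the mouth angle. A cheek-polygon blue-channel
illumination series is provided as a secondary, lighting-sensitive signal.

**Voice.** Counting audio is reduced to a ~1000 Hz magnitude series and a
~17 Hz block-averaged envelope; a noise threshold on the envelope yields
speech segments (the 50 longest for counting-to-50). Features: integrated
loudness per ITU-R BS.1770-4 / EBU R128 (K-weighted, gated), per-segment
autocorrelation pitch, L2 spectral energy in the 5–25 Hz breathing band,
Teager–Kaiser energy ψ(n) = x(n)² − x(n−1)x(n+1), normalized spectral
entropy with prominence-counted peaks, and single-breath duration/energy
integral.

**Grading.** The exam's printed 0–3 boundaries applied verbatim (e.g.
single-breath count ≥30 → 0, 25–29 → 1, 20–24 → 2, <20 → 3), with
inclusive intervals and milder-grade resolution at printed seams; visual
categories (cheek seal, use of hands) are taken as annotations.

Everything is testable without patient data: seeded generators render eye
patches with known geometry, landmark streams with injected ptosis decay /
arm drift / stand-up trajectories, and counting audio as tone bursts over
noise, all with analytic ground truth.

## Worked example

Generate a complete synthetic examination session and analyze it:

```r
library(mgcekit)

dir <- tempfile("session-")
cfg <- write_session_fixtures(dir, seed = 1)  # media + landmarks + config
report <- run_session(cfg)
report
#> <session_report> v0.1.0 seed=1 config=61afd71f
#>   ptosis           ok grade=1
#>   diplopia         ok grade=0
#>   cheek_puff       ok grade=0
#>   tongue_to_cheek  ok grade=0
#>   count50          ok grade=0
#>   arm_strength     ok grade=1
#>   single_breath    ok grade=0
#>   sit_to_stand     ok grade=0
```

The fixture injects a 15% linear ptosis decay and an arm drift at 95 s; the
report grades them mild (lid still above the pupil; drift in the 90–119 s
band) and everything else normal. The underlying numbers are in
`report$exercises`, e.g. the ptosis fit:

```r
fit_linear_decay(series, "d_lid_pupil")
#> <decay_fit> d_lid_pupil: slope -0.0127 px/s, decay 15.22% over [0.0, 60.0] s (p = 9.96e-232)
```

and a single segmented eye patch:

```r
p <- eye_scene_params(pupil_center = c(20, 10), noise_sigma = 0.05, seed = 2)
g <- segment_eye(render_eye_sequence(p, 1)$frames[[1]])
g
#> <eye_geometry> quality=ok pupil=(20.06, 10.02) iris x=[15.50, 24.50]
```

A thin CLI wraps the same functions (`inst/cli/mgce`): `mgce run --config
session.yaml`, `mgce fixtures --dir out/`, `mgce grade --report report.json`,
`mgce report-validate --report report.json`.

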