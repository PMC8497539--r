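---
title: "Measuring cervical skin motion during swallowing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cervical skin motion during swallowing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowtrack)
```

## The measurement problem

After low-neck surgery such as thyroidectomy, fibrous adhesions can tether
the skin and strap muscles to the airway. When the patient swallows, the
larynx rises and normally drags the overlying skin with it; adhesions
restrict that motion. Questionnaires capture this only subjectively.
`swallowtrack` implements an objective alternative: nine small colored
stickers (5 mm diameter) are attached in a 3×3 grid around the incision
line — rows labeled H (1 cm above the wound), M (on the wound) and L (1 cm
below), columns 1–3 left to right — and the neck is filmed from the front
while a recorded voice cues three water swallows over about 36 s at 30 fps.

The quantity of interest per recording session is the **session distance**:
the vertical excursion (max − min of the mean marker trajectory, in mm)
during a swallow, summarized over the three swallows by the **median**, so
that one aberrant swallow cannot distort the value. For a trial, each
subject is recorded before surgery and at 2 weeks, 3 and 9 months after;
subtracting the subject's own pre-operative distance removes
inter-individual differences in swallowing vigor, and the
baseline-subtracted changes are compared between arms.

## Pipeline

1. **ROI** — the marker region is designated on the first frame, or
   recovered automatically as the dilated bounding box of all color blobs.
2. **Segmentation** — each frame is converted from RGB to HSV; the four
   sticker colors (blue, orange, green, yellow) are thresholded in
   disjoint hue bands and connected components of at least `min_area_px`
   (default 20 px) are kept, with unweighted centroids and
   equivalent-circle diameters.
3. **Grid labeling** — with nine blobs, labels follow geometry alone: a
   3-way partition of y gives the rows (smallest y = H), ascending x gives
   the columns (ties broken by x then blob area). With fewer blobs, labels
   are recovered by minimum-total-distance assignment (Hungarian algorithm)
   against the previous frame's positions. Color identity is deliberately
   not used for labeling, since the color-to-position assignment is not
   fixed by the protocol.
4. **Jump gating** — a label whose centroid would move more than
   `max_jump_px` (default 3× the first-frame marker diameter) from its last
   recognized position in one frame is marked unrecognized for that frame;
   this suppresses momentary swaps and illumination flicker.
5. **Calibration** — mm-per-pixel is the known sticker diameter (5 mm)
   divided by the mean first-frame diameter in pixels over recognized
   markers.
6. **Kinematics** — the dropout-robust mean trajectory is segmented into
   three swallow windows, each window's excursion is converted to mm, and
   the session distance is their median.

## Design choices in the open

**Averaging under dropout.** Frames in which a marker is washed out or
occluded are excluded from that frame's average. Because the nine markers
sit at different heights (rows are ~10 mm apart), a plain mean of raw y
coordinates would jump by a large fraction of the row spacing whenever the
recognized subset changes — an artifact easily exceeding the few-mm signal.
The trajectory therefore averages each marker's *displacement from its own
reference level* (its median recognized y) and adds back the common mean
reference. With full visibility this is exactly the plain mean; under
dropout it is invariant to which markers are present (when all markers
share the swallow displacement). Frames with no recognized marker at all
become gaps, bridged by linear interpolation and reported as a gap
fraction.

**Average-then-excursion.** The excursion is taken on the mean trajectory
(average first). The alternative — each marker's own excursion, averaged —
is available via `excursion_method = "per_marker_then_mean"`; on clean
synchronized motion the two agree, but the default order is the one
consistent with the dropout rule above.

**Swallow segmentation.** Because swallows follow the recorded voice cue,
the default segmentation is the fixed guide schedule (cues at 8, 18, 28 s;
6 s analysis windows), shared between the simulator and the analysis
through one `guide_schedule` object so the two can never drift apart. An
`auto` mode instead locates the three largest-amplitude pulses of the mean
trajectory (peak finding with a prominence floor) and is appropriate when
cue times are unknown; it refuses flat trajectories rather than guessing.

**Color thresholds.** Hue bands: orange 15–40°, yellow 45–70°, green
90–150°, blue 200–260°, value ≥ 0.3. Saturation floors are per color
(blue/yellow 0.40, green 0.45, orange 0.60): skin tones fall inside the
*orange* hue band at saturation around 0.3, so a uniform 0.4 floor lets
orange-sticker edge pixels that are mostly skin pass, inflating measured
blob diameters by ~3% and biasing the pixel-to-mm calibration — and with it
every distance — low by ~1%. Each floor is set so the faintest accepted
edge pixel is roughly half sticker, half background, which keeps measured
diameters within ~0.5% of the physical sticker size. All thresholds are
configurable.

**Statistics.** Main endpoints (actual and baseline-subtracted distances
per timepoint) are compared by independent two-sample t-tests; the variant
is configurable and defaults to Welch, with the pooled (Student) variant
available — the summary-statistic form `ttest_from_summary()` reproduces
either exactly from published mean/SD/n. Subgroup comparisons (sex, age
dichotomized at 50 years, height at 160 cm) use Mann–Whitney U tests: the
U statistic uses mid-ranks; p is exact for combined n ≤ 20 without ties,
otherwise a normal approximation with tie and continuity corrections.
Outlier screening is applied per arm before testing. The
statistically-extreme criterion is implemented two ways, since "extreme by
p-value" admits several readings: an iterative Grubbs test at α = 0.05
(default), and a fixed-count mode removing exactly k most-extreme subjects
per arm (k = 5 mirrors the reference trial's 49 → 44 analyzed per arm).
The default screening value is each subject's mean baseline-subtracted
change across follow-ups; a single endpoint can be screened instead.
P-values are reported unadjusted per endpoint (as is conventional for this
design), with an optional Holm correction flag.

## The synthetic session generator

No patient videos are distributable, so the package ships a generator that
emulates the recording protocol and provides exact ground truth; every
downstream stage is validated against it.

* **Swallow waveforms** — each swallow is a single displacement pulse
  (raised cosine by default, triangular available) with configurable peak
  (mm), onset and duration; the three pulses must not overlap. The default
  schedule places 4 s swallows at 8, 18 and 28 s of a 36 s, 30 fps
  recording.
* **Geometry** — 3×3 sticker grid, rows 10 mm apart, columns 15 mm apart
  (lateral spacing is not prescribed by the protocol), rendered as
  anti-aliased disks at 0.25 mm/px in a 480×360 frame by default. Each
  sticker gets a time-constant placement offset (SD 1 mm) from its nominal
  grid position: stickers are attached by hand, and a perfectly regular
  grid would also be numerically unkind in an artificial way — all nine
  centroids would share one fractional pixel phase, so centroid
  quantization bias would add coherently instead of averaging out.
* **Adhesion phenotype** — a per-row gain in [0,1] multiplies the swallow
  displacement, so tethered skin (reduced excursion near the wound) can be
  simulated and detection of reduced motion tested.
* **Nuisance processes** — additive Gaussian luminance noise (SD 0.01 by
  default), slow sinusoidal illumination drift, and per-marker per-frame
  dropout in which the sticker is simply absent from the frame.
* **Determinism** — all randomness derives from one seed; frames are
  rendered lazily from per-frame sub-seeds fixed at generation time, so
  sessions of any length cost one frame of memory and repeated rendering
  is bit-identical.

Ground truth records per-frame centroids, the visibility mask, each
window's true mean-trajectory excursion and the true session distance
(their median).

What the generator does **not** model: real anatomy and texture of the
neck, specular highlights, motion blur, perspective change, camera shake,
or learning-based detection scenarios. Passing the recovery study
therefore demonstrates correctness of the measurement chain under the
protocol's nominal conditions, not robustness to everything a clinic can
produce.

The trial generator `generate_trial()` draws per-subject baselines and
changes from per-arm normal distributions; its defaults are the published
per-arm summaries of the reference trial (44 analyzed subjects per arm),
so a default synthetic trial reproduces that trial's effect sizes in
distribution. Covariates: sex 36% male, age ~ N(48, 9.5²) truncated to the
20–65 eligibility window, height ~ N(160, 7²) cm truncated to 140–185 —
values chosen to resemble the reported cohort, with follow-up distances
floored at zero (hit in well under 1% of draws).

## Numerical notes

* Pixel centers sit at integer coordinates, origin top-left, y downward;
  excursions use max − min, so the y direction never changes a result.
* Calibration uses the *mean* of available first-frame diameters (the
  protocol measures "the" diameter without naming a sticker).
* Degenerate inputs have defined behavior: zero-area ROI, no first-frame
  diameter, all-gap trajectories, empty samples and single-arm tables are
  errors; zero variance in both t-test arms yields p = 1 (equal means) or
  p = 0 (different means) with a warning; empty subgroup strata are
  reported "not testable" rather than aborting.
* More than nine candidate blobs keeps the nine largest with a warning;
  row partition ties break by ascending x, then blob area.

## Validation studies shipped with the package

`recovery_study()` generates seeded sessions with swallow peaks drawn from
2–10 mm, dropout up to 10%, illumination drift 0.1 and default pixel
noise, runs the full chain, and reports the error against ground truth;
the package's acceptance suite requires a mean absolute session-distance
error of at most 0.2 mm over 50 sessions. Sessions for this study are
rendered at 480×360 px, 10 fps × 12 s with cues at 2, 5.5 and 9 s — the
protocol geometry at reduced sampling, chosen so a 50-session study runs
comfortably on one CPU; the accuracy being measured does not depend on the
recording being long, only on the swallow pulses being resolved.
`noiseless_accuracy()` checks the clean-image limits (centroid RMS error
≤ 0.5 px, excursion error ≤ 0.5 px × scale), and `null_trial_pvalues()`
confirms the endpoint analysis holds its nominal type-I error on null
trials.

## Known limitations

* Labeling relies on geometry, not color identity; a frame in which two
  markers truly swap vertical order would be mislabeled (the jump gate
  only suppresses momentary swaps).
* The auto segmentation assumes three clear pulses; weak swallows
  (row gains near zero) require the schedule mode.
* The Grubbs screen assumes approximately normal endpoint values within
  each arm.
* Side-view recordings and x-axis kinematics are out of scope (front-view
  swallowing moves markers along y).
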