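# swallowtrack

Objective, vision-based quantification of cervical skin motion during
swallowing.

After low-neck surgery (thyroidectomy in particular), fibrous adhesions can
tether the skin to the airway and restrict its movement when the patient
swallows. `swallowtrack` measures that movement from front-view video of
nine colored stickers (5 mm, four colors) attached in a 3×3 grid around the
incision — rows H/M/L (1 cm above / on / 1 cm below the wound), columns
1–3 — while a voice cue prompts three water swallows.

For each recording session the package computes the **session distance**

&nbsp;&nbsp;&nbsp;&nbsp;*d* = median over the three swallows of
( max − min of the mean marker y-trajectory during the swallow ) × *s*,

where the scale *s* (mm/px) comes from the known sticker diameter observed
on the first frame. Detection is HSV color thresholding plus connected
components; grid labels are assigned geometrically (rows by y, columns by
x, Hungarian matching against the previous frame when markers drop out).
For a longitudinal trial, each subject's pre-operative distance is
subtracted from the follow-up distances, arms are screened for
statistically extreme subjects per arm, and endpoints are compared with
independent t-tests (Welch or pooled; also directly from published
mean/SD/n summaries) and Mann–Whitney U tests for subgroups.

Because patient videos cannot be shipped, the package includes a fully
seeded synthetic session generator (anti-aliased markers on a textured
skin-tone background, pixel noise, illumination drift, marker dropout, and
a per-row "adhesion" gain) with exact ground truth, plus a trial generator
parameterized by the published per-arm endpoint summaries.

## Worked example

```r
library(swallowtrack)

# a synthetic session: three 6 mm swallows, 10 fps x 12 s, with dropout
sch  <- guide_schedule(c(2, 5.5, 9), swallow_s = 2, window_s = 3)
spec <- session_spec(schedule = sch, fps = 10, duration_s = 12,
                     waveforms = schedule_waveforms(sch, c(6, 6, 6)),
                     dropout_prob = 0.05, illumination_drift = 0.1, seed = 7)
ses <- generate_session(spec)
ses
#> synthetic swallow session: 120 frames @ 10 fps (12 s)
#>   true excursions: 6.000, 6.000, 6.000 mm; session distance 6.000 mm
#>   marker visibility: 95.5% of frame-markers

tracks <- track_markers(ses)
result <- analyze_session(tracks, schedule = sch)
result
#> session distance: 5.961 mm (subject NA, timepoint NA)
#>   swallow excursions: 5.961, 5.962, 5.959 mm; scale 0.2497 mm/px; gaps 0.0%
```

The three excursions are the per-swallow ranges of the dropout-robust mean
trajectory in mm; the session distance is their median — here within
0.04 mm of the generator's ground truth. On a real recording, replace the
session object with a frame directory (`track_markers("frames/")`).

Trial-level analysis from per-subject distances:

```r
tt  <- generate_trial(n_per_arm = 49, seed = 11)   # defaults: published summaries
rep <- run_trial_analysis(tt, outlier_mode = "fixed", outlier_k = 5,
                          ttest_variant = "pooled")
rep$endpoints[rep$endpoints$type == "baseline-subtracted",
              c("endpoint", "mean_1", "mean_2", "p")]
#>     endpoint   mean_1    mean_2            p
#> 5 change_2wk 3.069329 2.1430349 0.0319389540
#> 6 change_3mo 1.840122 1.1036990 0.0212964796
#> 7 change_9mo 1.859890 0.8018562 0.0005842541
```

Column `mean_1` is the anti-adhesion arm, `mean_2` the control arm (mm);
`p` is the two-sided t-test p-value after the 49 → 44 per-arm outlier
screen.

A thin command-line wrapper over these functions is installed at
`inst/cli/swallowtrack.R` (subcommands `simulate`, `track`, `distance`,
`trial`, configured by one YAML file so simulation and analysis share the
same guide schedule).

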