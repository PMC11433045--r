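---
title: "Locating regions of use of a progressive power lens from wearable eye tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating regions of use of a progressive power lens from wearable eye tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensuse)
```

## The problem

A progressive power lens (PPL) varies its spherical power smoothly from a
distance zone down a corridor to a near zone, at the cost of lateral regions
of unwanted astigmatism. Lens designs assume the wearer looks through
particular regions for particular tasks, but wearers often do not. This
package implements an experimental method for finding the regions of a PPL
that are *actually* used: a head-mounted eye tracker records, per sample,
the 3-D pupil position and gaze direction of each eye; each fixation's mean
sight line is intersected with the back surface of the lens; and the
resulting cloud of viewing-through points — the region of use — is
summarized and compared with the region a purely geometric model of the
task predicts.

## Geometry and coordinate convention

One right-handed headset frame is used everywhere: origin at the eye-tracker
reference point, `+Z` forward along primary gaze, `+Y` up, `+X` toward the
wearer's left. The right-eye center of rotation (CRE) sits at `x = -ipd/2`,
the left-eye CRE at `x = +ipd/2`, both `cre_to_lens_mm` behind the lens
vertex. The default CRE-to-lens distance is 25.5 mm: 13.5 mm from cornea to
CRE plus a 12 mm back vertex distance.

Given a pupil position $P$ and unit gaze direction $\vec v$, the
viewing-through point is the smallest-$t$ solution of

$$P' = P + t\,\vec v, \qquad t > 0,$$

on the lens back surface — a plane perpendicular to primary gaze by default
(that is how the published computation is done), or optionally a sphere
concave toward the eye for sensitivity analysis. $P'$ is then re-expressed
relative to the engraved fitting cross of that eye's lens, with `y` up and a
nasal-positive horizontal coordinate derived per eye (`+x` is nasal for the
right eye, `-x` for the left). Reporting in nasal/temporal terms makes
results immune to the viewed-from-front versus viewed-from-behind plotting
ambiguity; the raw signed `x` is always retained alongside.

Pantoscopic tilt and frame wrap are read from frame files but deliberately
*not* applied: the clip-on measurement setup this method models keeps the
lens out of the camera path and the published computation ignores both
angles. The package warns whenever they are present and non-zero.

## From raw samples to a region of use

1. **Reading and QC** (`read_recording`, `qc_filter`). Native TSV and a
   JSON-lines dialect are supported; malformed rows are flagged invalid,
   never dropped. Data loss for an eye is
   `(expected - valid) / expected` against the nominal 50 Hz grid — the most
   conservative reading, counting both invalid and missing samples — and a
   recording is kept only if loss is *strictly* below 10 % (the threshold
   wording is "lower than", so exactly 10 % is excluded). Loss is assessed
   per eye; a subject is excluded if any analyzed eye fails. Both the
   threshold and the eye set are configurable.
2. **Fixation classification** (`classify_fixations`). The source method
   consumes device-classified fixations; to be self-contained the package
   ships a standard I-VT classifier with a 30 °/s velocity threshold and
   60 ms minimum duration, both exposed as parameters. Angular velocity is
   the angle between consecutive valid gaze directions over their time
   step; invalid samples terminate runs. Each sample covers one frame
   period, so a steady 2 s recording yields one fixation of duration
   2.00 s, not 1.98 s. Device fixation tables can also be imported directly
   as CSV, bypassing this module.
3. **Projection** (`project_fixations`). Each fixation's *mean* pupil
   position and renormalized mean direction are intersected with the
   surface ("mean-first"; projecting per sample and averaging afterwards is
   possible by classifying with a high threshold but mean-first is the
   default, matching the per-fixation description of the method).
4. **Summary** (`region_of_use`, `condition_summary`). The region of use is
   summarized by the center of mass $(C_x, C_y)$ of the fixation points
   relative to the fitting cross, unweighted across fixations by default
   (the method description is silent on duration weighting; a `weights`
   argument gives the dwell-time-weighted version).

## Theoretical zones

For a task whose target rectangle sits at horizontal distance $d$,
head-relative azimuth $\alpha$ (positive toward the wearer's right) and
elevation $\varepsilon$, with angular extent $w \times h$, the expected zone
on each lens is computed by casting sight lines from that eye's CRE to the
four corner directions $(\alpha_e \pm w/2,\ \varepsilon_e \pm h/2)$, where
$(\alpha_e, \varepsilon_e)$ are the *per-eye* angles to the target center —
the eye's lateral `ipd/2` offset makes near targets demand convergence and
shifts both zones nasally. The corner hits' bounding rectangle is expanded
on every edge by half the cohort-average pupil diameter: the finite pupil
aperture widens the bundle of viewing-through points symmetrically, and no
more specific tolerance rule is published. On a plane at lever arm $L$ the
corner coordinates have the closed form $x = -L\tan\alpha$,
$y = L\tan\varepsilon / \cos\alpha$, which the tests use as an independent
oracle.

The built-in `task_presets()` encode the reading protocol this method was
demonstrated on: a distance screen 5.25 m away and 31.7 cm above primary
gaze subtending 4.2° × 2.3°, viewed on-axis and at 10° / 15° counterclockwise
subject rotation; and a near display at 0.37 m with three 3°-wide,
3.6°-tall text columns at azimuths −12.5°, 0°, +12.5°. Cohort pupil
diameters default to 3.73 mm (distance) and 2.88 mm (near).

Two genuinely open choices are resolved as follows and surfaced in output
rather than hidden. First, the near display's height relative to primary
gaze is not published; the default elevation is −20°, a typical reading
posture, exposed as `near_elevation_deg` and echoed in `zones.csv`. Second,
whether distance-task zones used per-eye convergence (≈0.34° at 5.25 m) or
optical infinity is not derivable; both modes exist
(`convergent = TRUE/FALSE`) and the difference is far below the pupil
tolerance at 5.25 m.

A related numerical note: the published error budget converts 0.6° accuracy
and 0.03° precision to 0.34 mm and 0.02 mm on the lens. Those figures imply
a ≈32.5 mm lever arm, which exceeds the 25.5 mm CRE-to-lens default;
`angular_to_lens_mm` therefore takes the lever arm explicitly and reports
state which arm they used instead of silently reconciling the discrepancy.

## Concordance

`point_in_zone` uses closed boundaries (an on-edge point counts as inside —
a documented tie-break). Three estimators are always reported together,
because a printed "percentage of fixations for all subjects" can mean
either of the first two:

* `pooled_concordance` — total fixations inside / total fixations × 100,
  pooled across subjects (the reading the wording favors);
* `subject_mean_concordance` — mean of per-subject fractions × 100;
* `strict_subject_percentage` — percentage of subjects with *every*
  fixation inside.

`strict <= pooled` is not mathematically guaranteed and is not asserted;
what is asserted (and tested) is the equivalence strict = 100 ⇔ pooled =
100, the bracketing of the pooled estimate by the per-subject extremes, and
monotone containment under zone shrinkage.

## The synthetic generator: what it does and does not establish

`simulate_recording` produces seeded, bit-reproducible 50 Hz binocular
streams: fixation targets sweep left-to-right over the task rectangle along
5 text lines (or hold the center, for exact-recovery tests), with
exponential fixation durations of mean 250 ms clipped to [0.08, 1] s; true
per-eye directions from each CRE to each target; a systematic accuracy
rotation of fixed magnitude (default 0.6°, direction random per scenario
unless pinned); per-sample angular jitter with RMS `precision_sd_deg`
(default 0.03°, the device-class precision); independent per-sample data
loss; and a pupil placed 11 mm from the CRE along the current gaze
direction (an approximate CRE-to-entrance-pupil distance — the real device
measures the pupil, so this constant only needs to be plausible and is
configurable). `simulate_pinhole_check` reproduces the pinhole validity
experiment: every true right-eye sight line passes through one known lens
point, the left eye is emitted occluded, and the per-fixation estimates
plus ground truth support the measurement-error metric.

The generator emulates geometry and tracker noise, not oculomotor
behaviour: no saccade dynamics, no head motion (chinrest assumed), no
smooth pursuit, no per-subject posture idiosyncrasies. A green end-to-end
test therefore establishes that the projection, zone and concordance
machinery is correct and noise-calibrated — it does not reproduce, and
cannot be compared against, the human cohort percentages, which is also why
the acceptance report contains no numeric targets.

One tested property needs a caveat: concordance degradation under growing
jitter is exercised through the schedule-based per-fixation estimator of
`simulate_pinhole_check`, because the I-VT classifier at its 30 °/s default
rejects streams whose jitter exceeds roughly 0.2° (sample-to-sample noise
velocity crosses the threshold) — far above the 0.03° device class, so the
limitation is irrelevant in the regime the pipeline targets, but it would
make classifier-mediated concordance undefined at large simulated σ.
Similarly, the expectation that distance-task vertical zone bounds do not
move across azimuth conditions holds only to first order: exact 3-D
geometry inflates `y` by sec(azimuth) off-axis (≈0.05 mm at 15°), so the
test asserts the difference stays an order of magnitude below the pupil
margin rather than exact equality.

## Numerical choices

* Plane intersections are closed-form (residual < 1e-9 mm); sphere
  intersections take the smallest positive quadratic root and are verified
  against a bisection oracle to 1e-6 mm, with the plane recovered in the
  radius → ∞ limit.
* Gaze directions are renormalized on read (tolerance 1e-6) and after
  averaging; zero-length directions invalidate the sample.
* Duplicate samples beyond the nominal grid clip data loss at 0 with a
  warning rather than going negative.
* All randomness flows through one scenario seed; simulation restores the
  caller's RNG state.

## Limitations

Ray tracing through the lens (prismatic deviation, magnification) is out of
scope — the modeled setup clips the lens in front of the tracker precisely
to avoid it. Toric/free-form surface sag, pantoscopic tilt and wrap
compensation, vertical heterophoria, and inferential statistics across
conditions are likewise out of scope. Zones are axis-aligned rectangles on
the lens plane, matching the rectangular reading targets.
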