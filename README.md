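# lensuse

Locating the actually-used regions of a progressive power lens (PPL) from
wearable eye-tracker data.

PPL designs assume wearers look through particular lens regions for
particular tasks; in practice they often do not. `lensuse` implements the
experimental method for finding the regions really used: each fixation's
sight line — pupil position $P$ and gaze direction $\vec v$ recorded by a
head-mounted tracker at 50 Hz — is intersected with the lens back surface,

$$P' = P + t\,\vec v \quad (\text{smallest } t > 0),$$

and expressed in millimetres relative to the lens fitting cross, with a
nasal-positive horizontal convention per eye. The *region of use* of a task
is the cloud of these viewing-through points over its fixations,
summarized by the center of mass $(C_x, C_y)$. The package also computes
the *theoretical* zone a task should occupy — sight lines from each eye's
center of rotation to the target rectangle's corners, per-eye convergence
included, expanded by half the cohort-average pupil diameter — and
quantifies concordance as the percentage of fixations falling inside the
zone. A seeded synthetic gaze simulator (configurable accuracy bias,
precision jitter, data loss, reading-like scanpaths, plus the
pinhole validity-check scenario) makes the whole pipeline testable without
human recordings.

Intended users: visual-optics and oculomotor researchers evaluating lens
designs or wearable-tracker analysis pipelines.

## Worked example

Simulate a near-reading recording (0.37 m display, one 3° × 3.6° text
column on the midline, device-class noise: 0.6° accuracy, 0.03° precision,
2 % data loss), then run QC → fixations → projection → zone → concordance:

```r
library(lensuse)

frame <- frame_geometry(ipd_mm = 62)           # CRE-to-lens 25.5 mm default
task  <- task_presets()$near_on
sc <- simulation_scenario(task, frame, duration_s = 30,
                          accuracy_bias_deg = 0.6, precision_sd_deg = 0.03,
                          data_loss_p = 0.02, seed = 7)
rec <- simulate_recording(sc)
rec
#> <gaze_recording> SIM / near_on: 30.0 s at 50 Hz, 3000 samples (2954 valid)

data_loss_fraction(rec, "right")               # QC keeps it: 0.017 < 0.10
#> [1] 0.017

fx  <- classify_fixations(rec, "right")        # I-VT, 30 deg/s, 60 ms
pts <- project_fixations(fx, frame, sc$surface)
region_of_use(pts, subject = "S01", condition = task$name)
#> <region_of_use> S01 / near_on / right: C = (1.88, -9.37) mm, n = 28

zone <- theoretical_zone(task, frame, "right")
zone
#> <theoretical_zone> near_on / right eye: x [0.03, 4.25] mm, y [-11.67, -6.93] mm (margin 1.44 mm)

res <- concordance_result(pts, zone, "S01")
pooled_concordance(res)
#> [1] 100
```

Reading the numbers: the region center sits ~1.9 mm nasal of the fitting
cross (convergence at 0.37 m pulls both eyes nasally) and ~9.4 mm below it
(the −20° default reading elevation), inside the theoretical zone whose
1.44 mm margin is half the 2.88 mm near-task pupil diameter; all 28
fixations land inside, so pooled concordance is 100 %. The device error
budget is available directly:

```r
angular_to_lens_mm(0.6, 32.5)   # 0.34 mm on the lens at a 32.5 mm lever arm
```

A command-line pipeline (`simulate`, `project`, `zones`, `concordance`)
wraps the same functions:

```sh
Rscript inst/cli/lensuse.R simulate --config cfg.json --out out/ --seed 1
```

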