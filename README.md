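# scapsta

Quantifying the **soft-tissue artifact (STA)** of scapular skin markers from
two-pose 3-D landmark data.

Optical motion capture tracks the scapula with markers glued to the skin over
three bony landmarks — the acromial angle (AA), the root of the scapular spine
(TS) and the inferior angle (AI). The scapula glides far beneath the skin
during arm elevation, so these markers drift away from the bone; the drift
(the soft-tissue artifact) corrupts marker-based estimates of scapular
orientation. `scapsta` measures that drift and its kinematic consequences from
bony-landmark and marker-center coordinates acquired in two static arm
postures (`reference`: arm at the side; `elevated`: maximal elevation), the
setting of upright-CT validation studies.

## What it computes

* **ISB anatomical frames.** Thorax (origin IJ; Y along the spine line from
  mid(PX, T8) to mid(IJ, C7); Z perpendicular to the IJ–C7–mid(PX, T8) plane,
  pointing right; X = Y × Z), scapula (origin AA; Z along TS→AA; X normal to
  the AA–TS–AI plane; Y = Z × X) and humerus (origin at the humeral-head
  center from a least-squares sphere fit; Y from the epicondyle midpoint to
  the head center; Z = X × Y). Left shoulders are mirrored through the
  sagittal plane to the right-side convention first.
* **Marker displacement in the bone-fixed scapular frame.** Each marker center
  is expressed in the scapular frame of its own pose; the displacement is

  `d = (Xe − Xr, Ye − Yr, Ze − Zr)`, `total = ‖d‖₂`,

  with anterior = +X, superior = +Y, lateral = +Z. Differencing bone-frame
  coordinates is exactly equivalent to superimposing the rigid scapula of the
  two poses.
* **Bone-based vs marker-based angles.** Scapulothoracic rotation by the ISB
  Y-X-Z sequence (internal rotation = +y, upward rotation = −x, posterior
  tilt = +z) computed from both the bone landmarks and the marker centers;
  humerothoracic elevation as the middle angle of the Y-X-Y sequence.
* **Cohort statistics.** Shapiro–Wilk-gated descriptives (median/IQR vs
  mean/SD); Friedman omnibus plus exact Wilcoxon signed-rank pairwise tests
  with Bonferroni (m = 3) across the three landmarks; paired t-tests of bone
  vs marker angles; Spearman correlations of displacement against angle error
  and BMI; Shrout–Fleiss ICC(1,1) and ICC(2,1) with 95% CIs for reliability
  sub-studies.
* **Synthetic cohorts.** `pose_cohort()` generates two-pose cohorts with
  planted scapulothoracic/humerothoracic kinematics and planted per-landmark
  STA vectors (plus Gaussian landmark noise), so every stage is testable
  without access to imaging data; `default_study_spec()` encodes a published
  upright-CT cohort's directional medians, IQR-derived dispersions and BMI
  link as the default world.

## Worked example

```r
library(scapsta)
coh <- pose_cohort(default_study_spec(seed = 7))   # 20 synthetic shoulders
res <- analyze_cohort(coh)
print(res)
#> <sta_analysis> 20 shoulders, 60 complete marker rows
#>   AA total movement: median 30.5 (IQR 27.2-34.4) mm, mean 31.6 +/- 6.5
#>   TS total movement: median 49.6 (IQR 39.2-56.6) mm, mean 48.4 +/- 9.9
#>   AI total movement: median 63.9 (IQR 53.1-68.3) mm, mean 62.2 +/- 14.8
#>   Friedman (totals): chi2 = 30.10, p = 2.91e-07

el <- res$angle_tests$elevated$upward_rotation_deg
sprintf("upward rotation, elevated: bone - marker = %.1f +/- %.1f deg (p = %.2g)",
        el$mean_diff, el$sd_diff, el$p)
#> "upward rotation, elevated: bone - marker = 8.7 +/- 6.4 deg (p = 6.9e-06)"

res$bmi_correlations$AA$rho      # acromial drift grows with BMI
#> 0.7579395
```

Reading: the AA marker moved least (median 30.5 mm) and AI most (63.9 mm);
the landmarks differ strongly (Friedman p ≈ 3e−7); in the elevated pose the
marker-based frame underestimates upward rotation by ≈ 9°; AA displacement
correlates with BMI (ρ ≈ 0.76). Those are the planted properties of the
synthetic world being recovered through the full measurement chain.

File-based workflows use the same path as real data:

```r
write_landmarks(coh, "cohort.csv")                 # + cohort_subjects.csv (BMI)
shoulders <- read_landmarks("cohort.csv", "cohort_subjects.csv")
run_pipeline(run_config(input = "cohort.csv", subjects = "cohort_subjects.csv",
                        out_dir = "results", seed = 7))
# results/: displacements.csv, angles.csv, stats.json, landmarks.csv, run.log
```

or on the command line:

```sh
inst/cli/scapsta simulate --n 20 --seed 7 --out cohort.csv
inst/cli/scapsta analyze --input cohort.csv --subjects cohort_subjects.csv --out-dir results
```

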