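# arnav

Accuracy evaluation of augmented-reality (AR) surgical navigation for
laparoscopic liver surgery, by simulation.

## What this is for

In image-guided laparoscopic liver resection, a CT-derived 3D model is
overlaid on the live laparoscope video.  The overlay chains several
estimated transforms — hand-eye calibration `T_C^M`, image-to-patient
registration `T_I^P`, tracked poses `T_M^O` and `T_P^O`, and the camera
intrinsics `M_I`:

    T_I^C = M_I · (T_C^M)⁻¹ · (T_M^O)⁻¹ · T_P^O · (T_P^I)⁻¹

Overlay accuracy is degraded by pneumoperitoneum (insufflation deforms
the liver, so preoperative CT no longer matches the intraoperative
shape) and by clinician annotation error in the registration landmarks.
`arnav` implements the full estimation pipeline and its evaluation:

- **geometry** — frame-checked rigid transforms, pinhole projection, the
  AR chain, pixel↔mm error conversion at depth;
- **hand-eye calibration** — the stacked Kronecker-product linear system
  solved by QR with SVD projection back to SO(3);
- **registration** — rigid point registration by cross-covariance SVD
  (with determinant correction), FRE, and a small rigid ICP for
  fiducial-model compensation;
- **evaluation** — FLE, TRE with the registration-mark exclusion rule,
  the 3–10 marker-subset resampling experiment, summary tables and a
  descriptive condition comparison;
- **synthetic data** — a liver-scale phantom with 15 labeled
  cauterization marks, pneumoperitoneum-like deformation, per-clinician
  annotation noise, tracked-tool sampling with breathing motion, and
  laparoscope camera trajectories, all pure functions of (config, seed);
- **study driver** — `run_study()` composes everything into a
  multi-trial experiment and writes CSV/JSON/PNG reports.

It is aimed at image-guided-surgery researchers who want a tested,
reproducible reference implementation of the TRE/FLE evaluation
methodology without access to in-vivo data.

## Worked example

```r
library(arnav)

study <- run_study(study_config(seed = 20, output_dir = "study_out"),
                   quiet = TRUE)
summarize_tre(study$results, "condition")
```

```
     condition    mean_mm      sd_mm      n sd_defined
1 intraop-user 10.7865111 14.0597716 136000       TRUE
2   preop-user 19.7823890 18.0989605 136000       TRUE
3     fiducial  0.9480031  0.5153675  27200       TRUE
```

Reading this: across 4 synthetic trials, 5 clinicians and registration
subsets of 3–10 marks, AR driven by clinician annotations on the
*preoperative* (deformed) model is roughly twice as inaccurate as on the
*intraoperative* model (19.8 vs 10.8 mm mean TRE), and removing the
human annotation error entirely (registering on fiducial ground truth)
leaves only the ~1 mm floor set by tool-sampling and centroid noise.
The per-N summary shows TRE falling as markers are added, with strongly
diminishing returns past ~5 markers:

```r
study$tre_deltas[study$tre_deltas$condition == "intraop-user", ]
```

The packaged reference FLE table (three subjects annotating 15 marks)
reproduces its printed subject means exactly:

```r
s <- summarize_fle(fle_reference(), group_by = "subject")
round_half_up(s$mean_mm, 1)
#> [1] 29.4 31.6 28.5
```

See the vignette (`vignettes/ar-navigation-accuracy.Rmd`) for the models,
their defaults, and what the synthetic world does and does not emulate.

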