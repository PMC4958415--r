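# cupmig

Three-dimensional migration of marker-equipped acetabular cups from
low-dose CT, measured the way radiostereometric analysis (RSA) defines it
— for researchers validating CT as an alternative to stereo radiographs in
total hip arthroplasty follow-up.

After hip replacement, 1.0 mm tantalum beads implanted in the
periacetabular bone and in the periphery of the cup liner define two rigid
bodies, **p** (pelvis) and **c** (cup). Given two examinations A and B,
`cupmig` detects the beads in each CT volume with subvoxel precision,
aligns B to A on the pelvic beads by the closed-form least-squares rigid
fit (SVD/Kabsch)

&nbsp;&nbsp;&nbsp;&nbsp;T&#770; = argmin<sub>T rigid</sub> Σᵢ ‖T(pᵢᴮ) − pᵢᴬ‖²,

and reports the cup motion M = fit(cᴬ → T&#770;(cᴮ)) as three translations
(mm) of the cup-bead centroid and three Cardan rotations (degrees,
intrinsic x–y–z), expressed in anatomical axes (x transverse, y
longitudinal, z sagittal). Precision is summarised from double
examinations as 2.45 × SD (95% t-limit, 6 d.o.f.) of the
series-1 − series-2 differences; accuracy against a gold standard as
2.57 × RMS (5 d.o.f.) of the gold-minus-method differences. The RSA
quality metrics — marker-scatter condition number (reliable below ~100)
and rigid-body mean error (acceptable below 0.35 mm) — annotate every
result.

The package also ships the simulation apparatus to characterise the
method end to end with no external data: a pelvic-phantom CT renderer
(blurred-sphere beads with partial volume and noise on a
0.6 × 0.6 × 0.3 mm grid, jig-controlled cup motions in 1.0 mm / 1.0°
increments, six positions × two series with whole-phantom repositioning)
and a simplified stereo X-ray simulator (two foci at 40°, projection,
ray-intersection reconstruction, marker occlusion) serving as the RSA
gold standard.

## Worked example

Simulate one complete validation study — six cup positions, each imaged
twice by CT and by the stereo simulator — and summarise it:

```r
library(cupmig)
study <- run_phantom_study(phantom_config(seed = 7))
print(study)
```

```
<phantom_study> cemented cup, seed 7

3D CT Precision (2.45 x SD of double-examination differences, 6 d.o.f.)
 component precision   mean    min    max
   dx (mm)     0.010  0.000 -0.005  0.006
   dy (mm)     0.010  0.001 -0.003  0.008
   dz (mm)     0.006  0.001 -0.001  0.005
  rx (deg)     0.011 -0.000 -0.008  0.006
  ry (deg)     0.020 -0.001 -0.014  0.009
  rz (deg)     0.015  0.003 -0.004  0.013

RSA Precision (2.45 x SD of double-examination differences, 6 d.o.f.)
 component precision   mean    min    max
   dx (mm)     0.014 -0.002 -0.010  0.007
   dy (mm)     0.039  0.006 -0.012  0.025
   dz (mm)     0.081  0.021 -0.009  0.059
  rx (deg)     0.112 -0.008 -0.046  0.089
  ry (deg)     0.127 -0.013 -0.078  0.070
  rz (deg)     0.076 -0.007 -0.040  0.048

3D CT vs RSA Accuracy (2.57 x RMS of gold-minus-method differences, 5 d.o.f.)
 component accuracy   mean    min    max
   dx (mm)    0.017 -0.001 -0.009  0.008
   dy (mm)    0.044 -0.009 -0.023  0.013
   dz (mm)    0.078  0.003 -0.035  0.046
  rx (deg)    0.163  0.040 -0.002  0.144
  ry (deg)    0.258 -0.093 -0.133 -0.029
  rz (deg)    0.087  0.019 -0.029  0.054

QC: max mean error 0.0517 mm, max condition number 8.3
```

Reading the output: each CT precision entry is the 95% repeatability limit
of that migration component under unchanged cup position — here ≤ 0.010 mm
/ 0.020°, with the stereo arm a few times wider because occlusion leaves
it only 6 cup and 7 pelvic beads. Each accuracy entry bounds the
disagreement between CT and the stereo gold standard on the three
independent 1.0 mm + 1.0° jig moves (pairs 1–2, 3–4, 5–6), both
modalities restricted to the beads visible in both. All registrations in
the run stayed far inside the QC bounds (mean error 0.052 mm vs the
0.35 mm limit; condition number 8.3 vs 100).

The building blocks are exported individually — `read_volume()`,
`detect_beads()`, `refine_centroid()`, `label_markers()`, `fit_rigid()`,
`decompose_cardan()`, `cup_migration()`, `precision_summary()`,
`accuracy_summary()`, `effective_dose()` — and a thin command-line
interface (`inst/cli/cupmig.R`, subcommands `simulate`, `detect`,
`migrate`, `rsa-sim`, `precision`, `accuracy`, `dose`) wraps the same
functions for shell pipelines. See the methods vignette
(`vignettes/ct-migration-methods.Rmd`) for the full model description and
design rationale.

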