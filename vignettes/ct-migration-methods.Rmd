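---
title: "Measuring acetabular cup migration from low-dose 3D CT: models and methods"
author: "cupmig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup migration from low-dose 3D CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupmig)
```

## The measurement problem

Early migration of a total-hip-arthroplasty cup relative to the pelvis — a
few tenths of a millimetre over months — predicts later loosening and
revision. The reference technique, radiostereometric analysis (RSA), tracks
1.0 mm tantalum beads implanted in the periacetabular bone and in the
periphery of the polyethylene liner using calibrated stereo radiographs.
RSA needs dedicated stereo equipment; modern CT scanners, by contrast, are
ubiquitous and resolve the same beads in three dimensions at submillimetre
voxel sizes. `cupmig` implements the CT alternative end to end and the
simulation apparatus needed to characterise its precision and accuracy
without access to a physical phantom or X-ray hardware.

Both rigid bodies are defined by their beads: the pelvis (typically nine
beads) and the cup (nine on a cemented design, twelve on an uncemented
one, placed in a circle at the liner opening). Migration between two
examinations is the rigid motion of the cup after the two examinations
have been aligned on the pelvic beads.

## The measurement chain

1. **Bead detection** (`detect_beads()`): the CT volume is thresholded
   (default 1500 HU), 26-connected components are extracted, and
   components outside a size window are discarded. Each surviving
   component yields a candidate center.
2. **Subvoxel refinement** (`refine_centroid()`): the
   background-subtracted intensity-weighted centroid over a spherical
   window (radius = bead radius + 3 PSF sigma), iterated until the window
   recenters on the estimate. At 2–4 voxels per bead the weighted centroid
   of the blurred intensity profile is a stable subvoxel estimator; sphere
   fitting has no advantage at this sampling and is noisier.
3. **Labelling** (`label_markers()`): candidates are matched to the study's
   marker table by a deterministic alignment search — three well-separated
   template anchors are matched against candidate triplets with compatible
   pairwise distances (rigid invariants, so a few missing beads just
   eliminate some triplets), each compatible triplet proposes a transform,
   and the proposal matching the most template markers wins — followed by
   a rigid refit and a nearest-neighbour assignment under the refined
   transform. Conflicting assignments raise errors rather than guesses.
4. **Registration** (`register_exams()`): the moving examination's pelvic
   beads are fitted to the reference examination's by closed-form
   least-squares (SVD/Kabsch with reflection correction). The RMS post-fit
   residual is the classical RSA *mean error* (instability QC, bound
   0.35 mm); the singular-value ratio of the centered marker matrix is the
   *condition number* (scatter QC, bound 100). QC failures annotate the
   result, they do not abort it.
5. **Migration** (`cup_migration()`): the registered cup-to-cup rigid fit,
   reported as three translations of the cup-bead centroid (mm) and three
   Cardan rotations (degrees) in the intrinsic x–y–z sequence
   (x = transverse, y = longitudinal, z = sagittal). The Cardan sequence is
   part of the definition of the reported angles and is fixed throughout.

### Reporting frame

Components are reported in *anatomical* axes: the reference examination's
pelvis is registered to the pelvis marker table (`frame` argument) and the
cup motion is conjugated into that frame. Without this step the components
would be expressed in whichever way the subject happened to lie in the
scanner, and repositioning the subject would change them. With it, the
whole pipeline is provably invariant to rigid repositioning — the property
that makes scanner positioning non-critical — and the tests verify this
invariance both on exact marker sets (to 1e-9) and through the full
rendered pipeline.

A related subtlety: translations are reported at the centroid of the cup
beads *used*. When occlusion restricts the usable beads (see below), the
centroid moves, and under nonzero rotation the reported translation changes
by (R − I)(c′ − c). Accuracy comparisons therefore restrict both
modalities to the same bead subset — the same rigid-body model — before
differencing.

## The synthetic phantom

`phantom_config()` fixes the study conditions; `build_study()` realises
them:

* 9 pelvic beads scattered uniformly (seeded) in a 60 × 60 × 40 mm
  periacetabular box, subject to ≥ 12 mm mutual and ≥ 10 mm bead-to-cup
  separation — surgical marker spacing, and a guarantee that blurred beads
  never merge in the image. The resulting scatter has condition numbers of
  2–10, far inside the 100 QC bound.
* Cup beads equally spaced on a circle of radius 25 mm in the
  liner-opening plane, with a seeded ±0.5 mm axial stagger emulating
  seating depth (and keeping the cup body non-coplanar).
* A jig moves the cup in 1.0 mm translation and 1.0° (about x) rotation
  increments. Six positions are visited; the default schedule alternates
  x/y translation steps with a 1.0° rotation each, so the independent
  pairs 1–2, 3–4, 5–6 each carry a true migration of 1.0 mm + 1.0°.
  The jig pivot is the cup-bead centroid, which makes each pair's
  ground-truth components exactly the incremental setting.
* Each position is imaged twice (a double examination); between the two
  series the whole phantom is repositioned by a seeded random rigid pose
  (up to ±10° per axis, ±20 mm per axis) without touching the
  cup-to-pelvis relation — the patient moving between scans. Bounded
  poses keep all beads inside the field of view.

### CT rendering model

Volumes are rendered on the clinical acquisition grid — 0.6 × 0.6 mm
in-plane, 0.3 mm increments — over a 120 × 120 × 90 mm field of view
cropped around the acetabulum. Each bead is a uniform sphere convolved
with an isotropic Gaussian point-spread function (sigma 0.4 mm ≈ 0.94 mm
FWHM, a typical soft reconstruction kernel), evaluated by the closed-form
radial profile of a ball–Gaussian convolution and averaged over each voxel
by 3× supersampling per axis (partial volume). Gaussian noise (SD 20 HU)
is added voxelwise.

The bead amplitude deserves a note. Tantalum's attenuation at 120 kVp is
enormous — the *pre-blur* contrast of a pure-Ta bead corresponds to tens
of thousands of HU, far beyond the display clip of a clinical scanner.
Because a 1.0 mm bead is comparable in size to the PSF, the rendered peak
is strongly diluted: with the default pre-blur contrast of 10 000 HU above
a 100 HU background, the peak *observed* voxel lands near 3000 HU — the
familiar saturated-tantalum value — and the default 1500 HU threshold sits
midway between background and peak. (Modelling the bead at an
"observed-looking" 3000 HU pre-blur would be physically inconsistent: the
blurred peak would fall near 1000 HU and no threshold above soft tissue
would detect it.) Detection size bounds are derived from the blurred
profile: the predicted above-threshold blob (~9 voxels at the defaults)
scaled by 0.25× and 4×.

The renderer is exactly translation-equivariant over whole-voxel shifts,
and conserves integrated bead contrast to better than 2% — both checked
against analytic values in the tests.

### What the simulator does not model

Bone texture, beam hardening, metal/blooming artefacts near the shell,
scanner-specific reconstruction kernels, and gantry geometry are all
absent. Passing the simulation bounds therefore demonstrates the
correctness and noise behaviour of the *measurement chain*, not robustness
to clinical artefacts; beads adjacent to metal in real scans will behave
worse than anything simulated here.

## The stereo (RSA) gold standard

The accuracy arm needs a reference measurement. `stereo_geometry()` models
a uniplanar RSA setup: two tube foci 1000 mm above a single detector
plane, central rays crossing at the examination volume (200 mm above the
detector) at 40° to each other. Calibration is assumed perfect — the cage
fiducials are carried for workflow realism only — and detector coordinates
are continuous with seeded Gaussian measurement noise (SD 0.02 mm,
film/digitisation error). Reconstruction takes the midpoint of the common
perpendicular of the two back-projected rays, recording the ray-skew
distance as a per-marker quality value; rays subtending under 5° are
rejected as ill-conditioned.

Occlusion, the practical weakness of stereo radiographs around metal cups,
is modelled by deterministic masks reproducing the reported visible
counts: 7 of 9 pelvic beads for both cups, 6 of 9 cup beads (cemented) or
4 of 12 (uncemented). Which ids are hidden is a fixed, documented choice
(`default_occlusion()`); a silhouette ray-caster would add realism but the
statistics depend only on the visible counts and scatter.

## Precision and accuracy statistics

*Precision* comes from the double examinations: per component, the
difference between the two series of one position estimates zero, and over
the six positions the summary is `2.45 × SD` — the central 95% Student-t
limit with 6 d.o.f. The SD is taken about zero (`sqrt(sum(d²)/n)`): the
true difference is zero by construction, so no degree of freedom is spent
on a mean, which is exactly what makes six differences carry six d.o.f.
and the 2.45 multiplier apply. A mean-subtracted variant
(`about_zero = FALSE`, n−1 d.o.f., multiplier 2.57 at n = 6) is available
for sensitivity analysis.

*Accuracy* compares the CT pipeline with the stereo gold standard on the
independent pairs 1–2, 3–4, 5–6, series-matched (series 1 with 1, 2
with 2), giving n = 6 differences per component per study. The summary is
`2.57 × RMS` (central 95% t limit, n − 1 = 5 d.o.f.); RMS rather than SD
because the gold-minus-method differences carry both systematic and random
error and may be of either sign.

`t_quantile(p, dof)` returns the symmetric coverage multiplier
`qt((1+p)/2, dof)` — the quantity the RSA literature calls "the 95%
quantile of the t-distribution" (2.45 at 6 d.o.f., 2.57 at 5 d.o.f.); the
tests pin it against a numeric integration of the hand-written t density.

`normality_check()` provides the advisory Gaussianity diagnostics
(histogram, Q–Q data, Shapiro–Wilk, a robust tail-ratio heuristic) that
justify summarising by standard deviations; it never gates a computation.

Effective dose is the scanner dose–length product times the pelvis
conversion factor, `effective_dose(dlp, k)`; with DLP ≈ 22 mGy·cm and
k = 0.015 mSv/(mGy·cm) this gives the ~0.33 mSv of a low-dose protocol.

## Numerical choices and degenerate inputs

* Rigid fits are closed-form (SVD of the 3×3 cross-covariance, smallest
  singular direction sign-corrected), so there is no iteration or
  initialisation to tune; collinear configurations and fewer than three
  shared markers are errors.
* Cardan decomposition refuses rotations within 1° of gimbal lock
  (|ry| ≥ 89°) — six orders of magnitude beyond any plausible migration —
  advising a quaternion representation instead.
* Condition numbers of rank-deficient scatters return `Inf` with the QC
  flag set, not an error: the fit itself may still be computable.
* Centroid refinement estimates the local background as the median of
  below-threshold voxels in the window and clips negative weights;
  iteration stops when the estimate moves < 1e-5 mm.
* Tie-breaking in labelling is by ascending match distance with
  uniqueness; a template bead whose nearest candidate is already claimed
  within tolerance is reported as a conflict, never silently reassigned.
* Volume geometry: world coordinates in mm; voxel indices are 0-based and
  continuous with index (0,0,0) at the corner voxel's *center*; NIfTI
  sform is preferred over qform when both are present.

## Validation problem sizes

The test suite validates the chain at two scales, chosen as a deliberate
compromise between statistical resolution and a desk-scale run: unit tests
use a compact phantom (96 × 96 × 72 mm field of view), while the
validation suite and `scripts/acceptance.R` run 20 replicate full-size
studies (12 volumes of 200 × 200 × 300 voxels each, both modalities,
~15 s per study) and check the worst case over axes and replicates against
the reported performance envelope: translation precision ≤ 0.09 mm,
rotation precision ≤ 0.29°, translation accuracy ≤ 0.32 mm, rotation
accuracy ≤ 0.82°, every rigid-body mean error < 0.30 mm. Exactness
properties (noiseless end-to-end recovery to < 0.01 mm / 0.02° across the
±3 mm / ±3° jig range, repositioning invariance, stereo round-trips,
Cardan round-trips, equivalence of the SVD fit with a brute-force
optimizer) are tested at tolerances of 1e-9 where the computation is
exact.

## Known limitations

* The simulator's noise is stationary Gaussian; real CT noise is
  correlated by the reconstruction kernel and spatially varying.
* Labelling assumes the cup has moved at most a few millimetres relative
  to the marker table between examinations (matching tolerance 6 mm);
  gross early failure would need a re-baselined template.
* The stereo simulator idealises calibration; real cage calibration error
  would add a systematic floor to the gold standard.
* Only bead-based (marker) analysis is implemented — no model-based
  (CAD-silhouette) variant, no wear or osteolysis measures.
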