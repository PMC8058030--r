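---
title: "Methods: evaluating synthetic CT for head-and-neck radiotherapy"
author: "sctqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating synthetic CT for head-and-neck radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctqa)
```

## Problem

MRI-only radiotherapy planning replaces the planning CT with a synthetic CT
(sCT) derived from MR images. Before an sCT can be trusted for dose
calculation it must be shown that (i) its geometry and Hounsfield-unit (HU)
content agree with a reference CT, and (ii) dose distributions computed on
it are clinically equivalent to CT-based ones. `sctqa` implements that
evaluation battery for the head-and-neck region: tissue-class HU errors,
overlap metrics, radial water-equivalent depth (WED) profiles, DVH-parameter
dose comparison with clinical gating rules, local-normalisation 3D gamma
analysis, and a paired TOST equivalence test — together with a seeded
digital phantom and a toy dose engine so the whole chain can be exercised
and regression-tested without patient data.

Inputs are assumed co-registered; registration itself is out of scope. The
canonical on-disk format is NIfTI-1 (spacing in `pixdim`, origin in the
sform); calibration curves are two-column CSV (HU, RED).

## Image evaluation

**Tissue classes.** Within the body contour, bone is HU > 250, air is
HU < −200, and soft tissue is the closed interval between them. The two
boundary values are assigned to soft tissue so the three classes partition
the body exactly; the open/closed choice at exactly 250 and −200 HU is a
convention the thresholds' source leaves ambiguous, and assigning both to
soft keeps the partition clean.

**Body contour.** Thresholding at −300 HU (configurable; auto-segmentation
tools do not publish their exact rule), keeping the largest 26-connected
component and filling internal cavities slice-wise in 2D. Hole filling is
2D because the trachea and sinuses must remain part of the body even where
they span many slices, and a 3D fill would leak through the caudal face of
a clipped field of view.

**ME, MAE, DSC, HD.** Mean signed and mean absolute HU error are computed
over segments taken from the *reference* segmentation, inside an evaluation
ROI: the craniocaudal slice range of the PTV plus a 15 mm margin (converted
to slices with a ceiling so the margin is never under-covered), minus any
explicitly listed artefact slices. Artefact slices are user-supplied
indices; streak artefacts are identified visually in practice and no
automatic detector is claimed. Overlap metrics compare the reference and
candidate segmentations of each class: Dice on voxel sets, and the classic
symmetric (maximum) Hausdorff distance between surface voxel sets, with
Euclidean distances in mm so anisotropic grids are handled in physical
space. A percentile option (e.g. HD95) exists for robustness studies, as
the maximum is notoriously sensitive to single stray voxels — visibly so on
noisy synthetic bone segments. Hausdorff distances are evaluated through an
exact Euclidean distance transform; the test suite cross-checks them
against brute-force max–min over all surface point pairs on small masks.

## Water-equivalent depth

For a chosen slice (the package follows the convention of one slice each at
vertebra Th1–C7, mid mandible and mid nose), rays are cast from the body
centroid in 2639 uniformly spaced directions over 360°, angle 0 anterior,
increasing clockwise viewed from cranial. 2639 is kept as the default
direction count for continuity with published profiles; any positive count
is accepted. Along each ray, HU is sampled by bilinear interpolation at
midpoints of steps of `stepMm` (default: half the minimum in-plane
spacing), converted to relative electron density (RED) via the calibration
curve, and accumulated as RED × step until the ray exits the body.

The exit test deserves a note. The ray terminates at the first sample where
the *bilinearly interpolated* body mask reaches zero, so the boundary
voxel's partial contribution enters proportionally through the
interpolation ramp. With a nearest-neighbour membership test the
worst-direction error of a voxelized circle is about 0.6 × the voxel size —
independent of the marching step, so refining the step cannot converge past
it. With the ramp rule the discretisation floor drops to about
0.45 × voxel size, below the default step, and the analytic-cylinder
checks (error within one step; halving the step halving the bound) hold at
the tolerances the tests state. The remaining floor is a property of
voxelizing a smooth contour, not of the quadrature.

The per-slice centroid is used as "patient centre" (with a manual override
for concave slices such as shoulders, where the centroid can fall outside
the body); for paired volumes the centre computed from the reference body
is reused for the candidate so both profiles share their ray geometry.

## Dose evaluation

**Contour harmonization.** To compare dose on a common geometry, candidate
tissue outside the reference body contour is set to air (−1000 HU) and air
inside the reference body that is face-connected (6-connectivity) to the
contour — e.g. a gap between a shifted skin surface and the reference
contour — is set to water (0 HU). Fully enclosed air (trachea, sinuses) is
preserved. Face-adjacency to an *outside-body voxel* defines
"connected to the contour"; the image boundary itself does not count, so an
air tube leaving the field of view caudally is still interior air.

**DVH parameters.** D~mean~, and the near-max/near-min points D~2%~ and
D~98%~ defined as the dose received by the hottest x% of the structure
volume, computed by linear interpolation of the inverse cumulative volume
curve over sorted voxel doses (a nearest-rank option is available for
cross-checks). With discrete mass-point dose distributions the interpolated
D~98%~ can marginally exceed the mean; on continuous dose fields the
ordering D~98%~ ≤ D~mean~ ≤ D~2%~ holds, and is verified on 1000 random
grids in the tests rather than enforced as a hard class invariant.

**Evaluation rules.** PTVs are cropped 4 mm away from the skin surface via
an exact distance transform of the body surface voxels (field-of-view clip
faces are not skin). Parameters per structure role: primary PTV
D~mean~/D~98%~/D~2%~, nodal PTV D~98%~, serial OARs (PRV spinal cord)
D~2%~, parallel OARs D~mean~, body D~mean~ and D~2%~. An OAR is evaluated
only if its reference mean dose reaches 10% of the prescription (6.8 Gy at
68 Gy); with dual prescription levels the highest defines the gate. The
relative difference is local: 100 × (candidate − reference) / reference.

**3D gamma.** Local normalisation with a 2% / 1 mm criterion and a 10%
dose cutoff: for each reference voxel above cutoff,
γ = min over candidate positions within the search radius of
√(|Δr|²/DTA² + ΔD²/(f·D~ref~)²), with the candidate dose trilinearly
interpolated on a lattice of DTA/3 within a radius of 3 × DTA (beyond which
the distance term alone exceeds 3). γ ≤ 1 passes, inclusively — the
exact-criterion case passes, with a 10⁻⁹ guard for floating-point
round-off. The optimized search visits lattice offsets in order of
increasing distance and stops when the distance term alone exceeds every
voxel's running minimum; this is exact, and the suite verifies bit-level
agreement (≤ 10⁻⁶) with an exhaustive brute-force implementation on seeded
random dose pairs. Voxels whose search sphere is truncated by the grid edge
are scored from available samples and counted in `nIncomplete`.

**Equivalence.** Per-patient relative DVH differences (in percent — the
"normalized" paired variable) are tested with two one-sided t-tests against
a (−1%, 1%) interval: t~L~ = (m̄ + 1)/(s/√n) against H₀: μ ≤ −1 and
t~U~ = (m̄ − 1)/(s/√n) against H₀: μ ≥ +1, n − 1 degrees of freedom,
equivalence iff both p < 0.05. The conventional TOST interval at α = 0.05
is the 90% CI; both the 90% and 95% CIs are reported since equivalence
studies often quote the latter. Zero-variance samples with the mean exactly
on a margin are reported as degenerate rather than tested. Because the
parameter-pooling question (one TOST over all parameters vs one per
parameter) is genuinely open, `runEvaluation()` reports both. Outliers are
flagged by the 1.5 × IQR box-plot rule with type-7 (linear interpolation)
quartiles.

## The synthetic phantom and toy dose engine

`generatePhantom()` builds a stylized head-and-neck patient: per-zone
elliptical body (shoulders 230 × 144 mm, neck 110 × 124 mm, head
150 × 176 mm in-plane), a vertebral column with spinal canal and cord, a
mandible arc, an interior air trachea, oral and nasal cavities, paired
parotid-like OARs, a larynx, a dental "filling" at metal HU, and primary /
nodal PTV ellipsoids. Default grid 96 × 96 × 48 at 2.5 × 2.5 × 3 mm
(240 × 240 × 144 mm FOV) — large enough for realistic path lengths, small
enough that the full battery runs in seconds per phantom. Tissue HU are
Gaussian: background −1000 ± 10, soft 40 ± 30, bone 700 ± 100, air
−950 ± 30; with these widths the threshold segmentation recovers the truth
masks essentially exactly, so segmentation error does not confound
downstream tests. All randomness flows from one explicit seed, and the
global RNG state is saved and restored.

`perturbToSct()` degrades the reference into an sCT-like candidate with
per-tissue biases (defaults bone −62, air +107, soft −1 HU — the systematic
under-/over-estimation direction reported for CNN-generated head-and-neck
sCT) plus per-tissue Gaussian noise (defaults 230/230/50 HU, chosen once so
the per-class mean absolute errors land near reported clinical magnitudes:
soft ≈ 40, bone ≈ 190, air ≈ 200 HU), optional body-contour
dilation/erosion via the distance transform, and an optional signal-void
patch at the dental filling (sCT metal voids are millimetres where CT
streaks span centimetres; the streak generator itself is a plausible
stand-in, not a physical artefact model). The noise is voxel-wise
independent — real sCT error fields are spatially correlated and
anatomy-dependent, so passing tests demonstrate the *metrics*, not
generative realism.

`toyDose()` is deliberately not a clinical dose algorithm. Each of 8
equispaced coplanar parallel beams deposits
D ∝ RED(r) · exp(−μ · WED(r)) along its rays (μ = 0.005 per mm of unit-RED
path, a plausible MV falloff), is smeared laterally with a 5 mm Gaussian,
and the summed dose is scaled so the target point (typically the PTV
centroid) receives the prescription. For paired comparison the scale is
calibrated on the reference and reused for the candidate — the "identical
beam parameters" convention. The engine makes HU differences propagate to
dose differences with the right sign and rough magnitude, which is all the
evaluation chain needs; it has no build-up, scatter kernels or beam
modifiers.

## Numerical choices and degenerate inputs

* Voxel centres sit at `origin + (index − 1) × spacing`; resampling
  interpolates at target voxel centres, filling out-of-field voxels with
  −1000 HU / 0 Gy / FALSE (radiologically and dosimetrically inert).
* Calibration curves are piecewise linear, clamped outside their range, and
  must contain the water anchor (0 HU → RED 1).
* Connected components use 26-connectivity for the body and 6-connectivity
  for air-reachability; both are implemented in compiled code, as is the
  exact anisotropic Euclidean distance transform (Felzenszwalb–Huttenlocher
  separable squared-distance algorithm).
* Empty masks, empty ROIs, non-overlapping extents, non-monotone curves and
  missing structures raise errors naming the offending object; per-patient
  failures in `runEvaluation()` are logged and skipped, and the run fails
  only if every patient fails.

## Problem sizes used in the checks

The test suite exercises identity behaviour and the full pipeline at the
default 96 × 96 × 48 phantom resolution; gamma oracle equivalence uses 20
seeded 16³ dose pairs; DVH oracle checks use 1000 random masked grids; TOST
operating characteristics use 1000 replicates at n = 44 (10,000 for the
size-at-the-margin check); the end-to-end cohort check uses 5 phantoms with
small perturbations (|bias| ≤ 10 HU, noise sd 20 HU, no contour change),
under which the cohort mean relative DVH differences fall inside (−1%, 1%)
and TOST declares equivalence — the qualitative behaviour expected of a
faithful sCT. These sizes were chosen as the smallest that make each
property sharp.

## Known limitations

* The phantom is stylized: no couch, no immobilisation mask, no partial
  volume at tissue interfaces, voxel-independent noise.
* The toy engine's dose is only qualitatively related to a clinical
  VMAT/AAA calculation; absolute dose differences it produces should not be
  read as clinical predictions.
* Maximum Hausdorff distance on noisy segmentations is dominated by stray
  voxels; prefer the percentile variant when comparing noisy masks.
* DICOM (RTSTRUCT/RTDOSE/RTPLAN) is not parsed; convert to NIfTI upstream.
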