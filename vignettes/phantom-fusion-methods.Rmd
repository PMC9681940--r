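---
title: "Methods: SPECT/CT to intraoperative CT fusion and AR overlay accuracy on a digital pelvic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom fusion and AR overlay accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfusion)
```

## The problem

Sentinel-lymph-node (SLN) surgery in endometrial cancer relies on
preoperative SPECT/CT lymphoscintigraphy to locate the first draining
nodes, but that functional information must somehow reach the surgeon
intraoperatively. One route is to fuse the preoperative SPECT/CT with
an intraoperative CT and project the fused SLN segmentations into the
laparoscopic view as an augmented-reality (AR) overlay. `arfusion`
implements that pipeline end to end on a *digital twin* of a pelvic
phantom, so every stage — simulation, segmentation, registration,
projection, scoring — is reproducible and can be validated against
known ground truth.

The phantom emulated here is a pelvis-like radiopaque arch, an
iliac-like vessel tree of tubes, two fillable spheres acting as SLNs
(8 mm on the left, 15 mm on the right), and a calibration board of
spherical fiducials, embedded in a gelatin-like background.

## Coordinate conventions

One convention is fixed and used everywhere:

* World frame: right-handed, axes aligned with the phantom board,
  units mm, origin at the corner of the field of view.
* Voxel indices are 0-based and address voxel centres; the world
  position of index $i$ is $\mathrm{origin} + O\,(s \circ i)$ with
  spacing $s$ and orientation matrix $O$ (orthonormal, $\det O = +1$).
* A registration transform is a 4x4 homogeneous matrix mapping
  *moving-session* world coordinates to *fixed-session* (intraoperative
  CT) world coordinates. Exported matrices are row-major plain text.

## Phantom generator and acquisition models

`buildPhantomLabelMap()` voxelizes the parametric phantom with a fixed
label precedence (fiducial > SLN > vessel > bone > background); a voxel
belongs to a structure if its centre does. At 1 mm spacing the 15 mm
sphere's voxel count is within 2% of its analytic volume.

The CT arm (`renderCT()`) assigns each label its mean intensity in
HU-like units (gelatin 40, vessel contrast 300, contrast-filled SLNs
600, bone 1200, fiducials 1500 — chosen for clear separation, as the
study gives no HU values) and adds seeded Gaussian noise
(default sigma 10). The acquisition grid is centred on the posed
phantom, as a scanner operator would centre the object.

The SPECT arm (`renderSPECT()`) carries activity only in the SLN
spheres (a nominal 12 activity units standing for the 12 MBq/mL
filling), integrates each 4.4 mm voxel by sub-voxel supersampling
(partial-volume behaviour), convolves with an isotropic Gaussian PSF of
10 mm FWHM, and applies scaled-Poisson counting noise (default 40
expected counts per activity unit, giving a realistic ~5% coefficient
of variation in the hot voxels). Tomographic acquisition and OSEM
reconstruction are *not* simulated — they would add cost but no
information to the registration and metric contracts — and the emulated
protocol (60 projections of 30 s, 128 matrix, OSEM 8x8, photopeak and
scatter windows) is recorded as metadata only.

The unknown physical repositioning between the two imaging sessions is
modelled by `sampleRigidMisalignment()`: a rotation of uniform angle up
to 10 degrees about a uniformly random axis through the phantom centre,
plus a translation of uniform norm up to 20 mm in a uniform random
direction. The bounds are deliberately larger than careful phantom
handling would produce, to stress the registration.

## Segmentation

CT structures are segmented by per-structure intensity intervals plus
26-connectivity connected components (`segmentCT()`), discarding
components below a minimum size; this replaces the study's manual
corrections with a parameterized, reproducible rule. CT centroids are
geometric; SPECT hotspot centroids are intensity-weighted, which under
PSF blur is the better estimator of the sphere centre.

SPECT hotspots are isocontoured at a fraction of the global maximum
(`segmentSpectHotspots()`). The default fraction is 0.15, not the more
conventional 0.4: partial-volume dilution under a 10 mm FWHM PSF leaves
the 8 mm node peaking at only ~27% of the 15 mm node's peak, so any
global isocontour above ~0.25 sees one hotspot, never two. With zero
background activity a low isocontour is safe. Left and right are
assigned by the first world coordinate of the centroids; an exact tie
falls back to volume (larger node to the right) and is logged.

Fiducials are detected by thresholding and matched to their expected
ordering by exhaustive assignment minimizing the discrepancy of the
inter-point distance matrices — invariant to rigid motion of the whole
board, so the expected positions may be given in any session frame.
The board layout is irregular by design: a symmetric layout would make
this matching ambiguous.

## Registration

Two registrations are composed:

* **Fiducial (closed form).** `registerPoints()` solves the
  least-squares rigid alignment by centroid alignment plus orthogonal
  Procrustes (SVD) with $\det = +1$ enforced; the fiducial registration
  error (FRE) is the RMS residual. On noiseless detections this is
  exact to numerical precision; on the rendered phantom the FRE is at
  the voxelization noise floor (~0.1-0.2 mm at 1 mm CT voxels).
* **Mutual information (iterative).** `mutualInformation()` uses a
  dense joint histogram (32 bins per axis, min-max normalization,
  out-of-field voxels excluded), and `registerRigidMI()` maximizes it
  over 6 DOF with coarse-to-fine Nelder-Mead (default pyramid 4x, 2x,
  1x block-mean downsampling). The initialization is always a vertex of
  the first simplex, and the finest level re-evaluates the plain
  initialization, so refinement can never end below the
  initialization's metric.

In the default pipeline, mutual information refines the alignment
between the *preoperative CT of the SPECT/CT session* and the
intraoperative CT; the SPECT volume rides along through hybrid
co-registration. Same-modality bone-driven MI is far better conditioned
than aligning a two-blob activity map directly, and mirrors the role of
bone structures in the study's validation and planned clinical
workflow; `registerRigidMI()` accepts the SPECT volume directly for the
ablation case. Because the fiducial initialization is already within a
fraction of a voxel, the default refinement uses a single 2x level with
small initial steps (0.5 mm / 0.5 degrees): adding the 1x level was
measured to triple the cost without changing the SLN target
registration error (~0.01-0.06 mm either way). The full pyramid
remains the default for `registerRigidMI()` itself, whose centred
initialization must capture misalignments up to 10 degrees / 20 mm.

Registration quality is quantified, not eyeballed: the target
registration error (TRE) at the SLN centres compares the estimated and
true transforms directly.

A property worth noting: with fiducial initialization the
post-registration TRE sits at the *fiducial localization noise floor*
(sub-voxel, set by voxelization of the marker spheres) and is therefore
essentially independent of the misalignment bounds — at 2 mm voxels the
measured medians were 0.72 / 0.39 / 0.34 mm for bounds of 2°/4 mm,
5°/10 mm and 10°/20 mm. The regression suite asserts robustness (all
medians below one SPECT voxel) rather than strict monotonicity in the
bounds, which a noise-floor-dominated estimator cannot exhibit.

## AR projection and overlay metrics

A pinhole camera (default f = 1000 px, 1280x720, no lens distortion,
placed 245 mm above the SLN midpoint looking down the board) renders a
3D segment to a 2D mask: every voxel centre is mapped by the transform,
projected, rasterized to the nearest pixel, and the footprint is
solidified by morphological closing with a 3x3 element. Occlusion is
ignored, matching metric definitions on plain 2D surfaces. Before
projection the pipeline resamples each SLN segment to half the CT voxel
size so the projected point cloud is denser than the pixel grid and the
closing yields a solid footprint.

For each SLN, `makeOverlayPair()` renders the same segment twice:
`s1` (the AR surface) with the *estimated* transform and `s2` (the
ground-truth visible surface) with the *true* transform — the digital
stand-in for the node seen in the endoscopic image, which isolates
registration error from segmentation differences. The metrics are:

* normalized barycenter distance
  $d(b_1, b_2) / r$ with $r = \sqrt{\mathrm{area}/\pi}$, the
  pseudo-radius. $r$ is taken from `s1` (following the study's own
  figure definition); the variant normalized by `s2` is also reported
  (`ratio_r2`) since the prose is ambiguous between the two.
* coverage rate $|s_1 \cap s_2| / |s_2|$, the fraction of the visible
  surface covered by the AR surface.

Both are computed by exact pixel counting on identical pixel grids
(mismatched grids are an error, never silently resized) and agree with
a naive per-pixel oracle to counting precision.

## Numerical and degenerate-input choices

* Trilinear interpolation for scalar volumes, nearest-neighbour for
  label maps and masks; out-of-field voxels take a declared fill value
  (`NA` inside the MI metric, so they are excluded).
* Connected components use 26-connectivity; component ordering is by
  size with first-voxel tie-break, so results are independent of voxel
  iteration order.
* Constant images make MI degenerate: warning and MI = 0; registration
  of a constant volume is an error.
* A reflection-only Procrustes optimum is folded back to a proper
  rotation and logged.
* All randomness (misalignment draw, CT noise, Poisson counts) is
  seeded per stage with seeds derived from the per-repetition seed, so
  every run is bit-reproducible and repetitions are independent.

## Problem sizes and runtime

The default experiment voxelizes the phantom at 1 mm
(180 x 140 x 110), renders two CT volumes and one SPECT volume per
repetition, and runs 20 repetitions in roughly 6-7 minutes on one CPU;
the regression suite uses 2 mm grids for most registration tests. These
sizes were chosen so the full study runs comfortably on a laptop while
keeping the 15 mm sphere's voxelization error under 2%.

## What the synthetic study does and does not show

The generator reproduces the geometry, resolutions, contrast ordering
and noise character of the physical phantom study, with known ground
truth for every stage. It does not reproduce: tomographic SPECT
reconstruction artifacts (attenuation, scatter, OSEM convergence),
CT beam hardening, gelatin deformation, endoscope lens distortion, or
any soft-tissue motion — the phantom is rigid by construction, as was
the physical one. Passing the end-to-end bounds here therefore
demonstrates that the *fusion and overlay machinery* attains the
reported accuracy under controlled rigid conditions; it does not
predict in-vivo performance, where deformation dominates (the study
itself flags this as the open clinical question).
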