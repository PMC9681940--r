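# arfusion

Fusion of preoperative SPECT/CT with intraoperative CT, and
augmented-reality (AR) overlay accuracy metrics, on a digital pelvic
phantom — an end-to-end, fully reproducible digital twin of a
sentinel-lymph-node (SLN) surgical-guidance validation study.

## What it does

Preoperative SPECT/CT lymphoscintigraphy locates the pelvic sentinel
lymph nodes; to guide surgery, those functional findings must be fused
with an intraoperative CT and projected into the endoscopic view. This
package implements and evaluates that pipeline on a synthetic phantom
with known ground truth:

1. **Phantom generator** — a radiopaque pelvis-like arch, an iliac-like
   vessel tree, two fillable SLN spheres (8 mm left, 15 mm right) and a
   calibration board of 8 spherical fiducials, voxelized into a label
   map (`buildPhantomLabelMap()`).
2. **Acquisition simulation** — a CT-like render (1 mm voxels, Gaussian
   noise) and a SPECT-like render (4.4 mm voxels, 10 mm FWHM Gaussian
   PSF, Poisson counting noise) under a seeded, bounded rigid
   misalignment between the two sessions (`renderCT()`,
   `renderSPECT()`, `sampleRigidMisalignment()`).
3. **Segmentation** — threshold + connected-component extraction of
   bone, vessels, SLNs and fiducials on CT; isocontour hotspot
   detection on SPECT (`segmentCT()`, `segmentSpectHotspots()`,
   `detectFiducials()`).
4. **Registration** — closed-form fiducial registration (Kabsch /
   orthogonal Procrustes, with fiducial registration error) initializing
   a 6-DOF mutual-information refinement; the result is a 4x4
   homogeneous matrix used for trilinear resampling
   (`registerPoints()`, `registerRigidMI()`, `resampleVolume()`).
5. **AR overlay scoring** — each fused SLN segment is rendered through
   a pinhole camera twice: with the estimated transform (the AR surface
   `s1`) and with the true transform (the ground-truth visible surface
   `s2`). Accuracy is scored by the **normalized barycenter distance**

   d(b1, b2) / r,   r = sqrt(area(s1) / pi)

   and the **coverage rate**

   |s1 n s2| / |s2|

   (`makeOverlayPair()`, `normalizedBarycenterDistance()`,
   `coverageRate()`, `overlayReport()`).

`runExperiment()` orchestrates all of it over a list of seeds and
aggregates medians/IQRs; everything is bit-reproducible per seed.

## Worked example

```r
library(arfusion)

cfg <- validateConfig(config = list(misalignment = list(seeds = 1:6)))
rep <- runExperiment(cfg, verbose = FALSE)
rep
#> ExperimentReport: 6 seeds (0 failed)
#>   normalized barycenter distance (median): left 0.0025, right 0.0019
#>   coverage rate (median):                  left 99.94%, right 99.87%
#>   SLN target registration error (median):  left 0.0288 mm, right 0.0144 mm
#>   fiducial registration error (median):    0.1427 mm
```

Each of the 6 seeds simulated a misaligned preoperative SPECT/CT and an
intraoperative CT, registered them, and scored the AR overlay per SLN.
A median normalized barycenter distance of ~0.002 means the AR
barycenter lands within a few thousandths of a pseudo-radius of the
true node centre; a median coverage above 99.8% means the AR surface
covers essentially the whole visible node. The fiducial registration
error (~0.14 mm) is the RMS residual of the marker alignment and sets
the accuracy floor of the whole chain.

Per-seed detail is in `rep$overlay` (areas, barycenters, d, r, ratio,
coverage per SLN); `runExperiment(cfg, outputDir = "out")` additionally
writes NIfTI volumes, plain-text 4x4 matrices, PNG masks and JSON/CSV
reports. A thin CLI with the same stages is installed at
`system.file("cli", "arfusion", package = "arfusion")`.

In *oracle mode* (`runExperiment(cfg, oracle = TRUE)`) the true
transform replaces the registration, which must give exactly ratio 0
and coverage 1 for every seed — the pipeline's self-check.

## Vignette

`vignettes/phantom-fusion-methods.Rmd` documents the models and their
assumptions, the coordinate conventions, every tunable parameter with
its default and rationale, numerical/degenerate-input choices, and what
the synthetic study does and does not demonstrate.
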