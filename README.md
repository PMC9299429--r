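# retrogate

Retrospective **intrinsic respiratory gating** and missing-angle-tolerant
iterative reconstruction for cone-beam micro-CT scans of **several mice
imaged simultaneously** on one bed — aimed at preclinical imaging groups
quantifying contrast-enhanced liver tumors (e.g. hepatocellular carcinoma
models) in high-throughput settings.

Under inhalation anesthesia mice breathe in short gasps separated by long
quiescent phases. The diaphragm sweep during each gasp mixes lung into the
cranial liver edge, producing a hypodense gradient and blurring small
hypodense tumors in the contrast-enhanced liver. Because only a minority
of projections are corrupted, they can be detected **from the projection
data itself** (no breathing pads) and simply **discarded** — provided the
reconstruction tolerates missing angles. In a multi-mouse scan, another
mouse's gasp matters only at gantry angles where its silhouette overlaps
the mouse of interest (MOI) on the detector, so overlap-aware gating
discards far fewer projections than a conservative
every-mouse-counts rule.

## Method core

For each mouse of interest:

1. **Coarse preview** reconstruction from all projections.
2. A sphere ROI is placed at the MOI's diaphragm; for every projection the
   **mean intensity inside the projected sphere** gives a raw curve
   `r(a)`, and the same readout of the forward-projected preview gives a
   baseline `b(a)` capturing the angular dependence of the rotation.
3. The motion score is the median-high-passed residual,
   `s(a) = (r - b)(a) - med_9[(r - b)](a)` (sliding median, radius 4).
4. Given a rejection fraction RF, exactly `round(RF * n)` projections with
   the most extreme scores are rejected.
5. The kept projections are reconstructed by **weighted least squares**,
   `min_x sum_kept w (A x - b)^2`, with Poisson-like weights `w = I / I0`
   and 30 iterations of linear conjugate gradient on the normal equations
   `A' W A x = A' W b`; rejected angles are omitted, never substituted.

`A` is a cone-beam line-integral projector (trilinear sampling at
half-voxel steps) with an exactly matched adjoint. A parametric
four-mouse breathing phantom (bed, soft-tissue body, lung/liver split at a
moving diaphragm, hypodense tumors, Poisson noise) generates test data
with ground-truth motion labels that emulate the manual 0–10 labeling
protocol (labels >= 3 = discard).

## Worked example

Simulate the packaged four-mouse breathing phantom, gate mouse 1, and
reconstruct:

```r
library(retrogate)

geom <- geometry_preset("desk")        # 360 angles, 96 x 72 detector
spec <- default_phantom_spec()         # 4 mice, gasps of 5 every 22 proj.
sim  <- simulate_scan(spec, geom, seed = 42)

roi  <- roi_sphere(c(-15, 0, 0), 8)    # at mouse 1's diaphragm
mask <- gate_mouse(sim$projections, geom, roi, rejection_fraction = 0.2,
                   coarse = list(dims = c(50, 30, 32), voxel_size = 0.8,
                                 n_iterations = 8),
                   polarity = "highest", moi_index = 1)
mask
#> <rejection_mask> RF 0.2 (highest): 72 of 360 projections rejected, MOI 1

gating_agreement(mask, sim$labels$labels[, 1])$agreement_pct
#> [1] 95.55556
```

95.6% of the 360 keep/discard decisions match the ground-truth motion
labels — the intrinsic score recovers both the mouse's own gasps and
overlapping neighbors' gasps. Reconstructing with and without the mask
shows what gating buys (under a minute each at this desk scale):

```r
pp  <- preprocess_projections(sim$projections, geom, sigma_px = 2,
                              bin_factor = 2)   # smooth + bin conditioning
cfg <- recon_config(c(50, 30, 32), voxel_size = 0.8, n_iterations = 15)
vol_all   <- mu_to_hu(reconstruct_gated(pp$projections, pp$geometry, NULL, cfg))
vol_gated <- mu_to_hu(reconstruct_gated(pp$projections, pp$geometry, mask, cfg))

slope <- function(v) line_profile_slope(v, c(-15, 0, 1), c(-15, 0, -6),
                                        fit_segment = c(1.5, 6.5))$slope
round(c(ungated = slope(vol_all), gated = slope(vol_gated)), 1)
#> ungated   gated
#>    26.8    14.6
```

The liver-edge profile slope (HU/mm, the quantitative readout of the
hypodense edge artifact) halves with gating; the edge-versus-center
difference shrinks and the liver/tumor contrast-to-noise ratio rises
accordingly (see `edge_center_difference()`, `cnr()` and `rf_sweep()`).

A command-line front-end wrapping the same functions is installed at
`inst/cli/retrogate` with subcommands
`simulate | gate | reconstruct | evaluate | sweep | report`.

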