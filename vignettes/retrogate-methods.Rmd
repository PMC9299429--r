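---
title: "Intrinsic respiratory gating for multi-mouse micro-CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic respiratory gating for multi-mouse micro-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retrogate)
```

## The problem

Contrast-enhanced micro-CT of liver tumors in mice is degraded by
respiratory motion: the diaphragm sweeps craniocaudally during each breath,
mixing lung contributions into the cranial liver edge. In reconstructions
this appears as a hypodense gradient toward the diaphragm and as blurring
that hides small hypodense tumors in the radiodense, contrast-enhanced
liver. In high-throughput settings several mice are scanned simultaneously
on one bed, so the motion of *every* animal can corrupt the projections of
the animal being reconstructed — but only at gantry angles where the two
animals' silhouettes overlap on the detector.

Under inhalation anesthesia (isoflurane), mice settle into a
characteristic pattern: long quiescent phases interrupted by short gasps.
Only a minority of projections are motion-corrupted, so instead of
re-binning or interpolating, the corrupted projections can simply be
discarded and the remaining ones reconstructed with a model-based
iterative method that tolerates missing angles.

`retrogate` implements this pipeline end to end: a cone-beam projector
with a matched adjoint, a projected-sphere motion score with
rejection-fraction thresholding per mouse of interest (MOI), a weighted
least-squares conjugate-gradient reconstruction, the image-quality metrics
used to evaluate liver imaging, and a synthetic breathing multi-mouse
phantom that makes every stage testable without scanner data.

## Forward model and reconstruction

### Geometry and projector

The scanner is modeled as a circular cone-beam system: source at distance
SID from the isocenter (default 117.578 mm), flat detector at SDD
(default 297.459 mm, magnification ~2.53), gantry rotating in the x–y
plane with the animal axis along z, step-and-shoot, equidistant angles
over a full rotation. Volumes are cell-centered grids of linear
attenuation (mm^-1); Hounsfield units convert through
`HU = 1000 (mu - mu_water) / mu_water` with `mu_water = 0.02` mm^-1, a
representative value for the ~55 kV effective spectrum.

`forward_project()` integrates the attenuation along each source-to-pixel
ray with trilinear interpolation at a fixed nominal step of half a voxel,
each sample scaled by the actual step length. `backproject()` scatters
with the identical trilinear weights along the identical sample positions,
so the pair is a matched transpose by construction: the inner-product
identity `<Ax, y> = <x, A'y>` holds to rounding error (about 1e-16 in the
test suite, far inside the 1e-4 engineering bound asserted there). A
matched pair matters because conjugate gradient assumes a symmetric
positive semidefinite normal operator; unmatched projector/backprojector
pairs can stall or diverge.

The detector model is monochromatic Beer–Lambert, `I = i0 exp(-p)`,
optionally composed with a quadratic polynomial response
`p' = c0 + c1 p + c2 p^2` (identity by default) that stands in for vendor
beam-hardening and detector-response corrections; the vendor's actual
curve is not public, and the polynomial is a configurable placeholder,
not a reproduction.

### Weighted least squares and conjugate gradient

Reconstruction minimizes the weighted squared difference between simulated
and measured pixels over the *kept* projections only,

    cost(x) = sum_kept w (A x - b)^2,

by plain linear conjugate gradient on the normal equations
`A' W A x = A' W b` with implicit operators, zero initialization and a
fixed iteration count (default 30). Rejected frames are omitted, never
substituted or interpolated — the normal operator simply loses those
terms, which is what makes arbitrary missing angles unproblematic for a
least-squares formulation. Weights follow a Poisson-like noise model: the
variance of `-log(I/i0)` is approximately `1/I`, so `w = I / i0`
(normalized to max 1) down-weights strongly attenuated, noisy rays. No
regularization or nonnegativity constraint is applied; noise control is
left to projection-domain smoothing and binning, mirroring practice on the
real system.

The weighted cost is tracked per iteration from the CG recurrences (no
extra forward projections) and asserted nonincreasing on every run. On a
small system materialized column by column (3^3 volume, 4 angles, 60 x 27
matrix) the CG solution matches a dense weighted normal-equations solve to
1e-6 relative, which is the definitive correctness oracle for the solver;
self-consistency on a smooth 64^3 phantom at 180 angles (relative RMSE
<= 0.05 inside the support) checks projector and solver jointly at scale.

### Projection preprocessing

Measured projections are conditioned before the log transform: isotropic
Gaussian smoothing (1.34 px standard deviation, reflect boundaries)
followed by non-overlapping 3 x 3 *mean* binning. Mean rather than sum
pooling keeps values in the intensity domain so the Poisson-like weights
can be computed from binned intensities; whether the vendor bins by mean
or sum is unknown, and mean is the unit-preserving choice. Dimensions not
divisible by the bin factor are cropped at the trailing edge (with a
message), and the binned geometry's detector offset is shifted by half the
crop so the optical axis stays put.

## Intrinsic gating

Per mouse of interest:

1. **Coarse preview** — a fast low-resolution reconstruction from all
   projections (4 x coarser voxels, 5 CG iterations, unit weights).
2. **Raw curve** — a sphere is placed at the MOI's diaphragm; for each
   projection the mean intensity inside the projected sphere (pixels whose
   rays pass within the sphere radius of its center) gives one sample.
3. **Baseline** — the same curve read from the forward-projected coarse
   volume (through the detector model), capturing the angular dependence
   of the rotating geometry; it is subtracted from the raw curve.
4. **High-pass** — a sliding-window median (radius 4, window 9, reflect
   boundaries) of the residual estimates the remaining slow trend; its
   subtraction leaves the motion score.
5. **Thresholding** — exactly `round(RF * n)` projections are rejected by
   rank on the score, where RF is the rejection fraction.

### Score polarity

On intensity-domain curves, a gasp moves the diaphragm caudally, replaces
radiodense liver with lung along the rays through the ROI, and *raises*
the projected-sphere intensity, so motion-corrupted projections sit in the
**highest** tail of the score. Descriptions of the underlying commercial
implementation reject the *lowest* values of their motion parameter, which
implies an internally sign-flipped (for example log-domain) curve; since
the sign depends on a domain convention that is not public, the polarity
is an explicit configuration enum (`lowest`, `highest`, `absolute`).
`select_rejections()` defaults to `lowest` for compatibility with that
description, while every packaged-phantom workflow (and `run_config()`)
uses `highest`, which is the correct polarity for curves computed in the
intensity domain as this package does. `absolute` ranks by magnitude and
is the robust fallback when the curve domain is unknown, at the price of
promoting both noise tails.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| ROI diameter | 8 | mm | large enough that overlapping neighbors' diaphragm motion projects into the sphere; small enough to keep the gasp signal from being diluted below the curve noise |
| median radius | 4 | projections | window 9; passes gasp episodes up to ~4–5 projections long, follows (and cancels) anything longer |
| rejection fraction | 0.2 | — | matches the motion-corrupted fraction under the packaged breathing statistics; the sweep facilities exist to re-derive it per dataset |
| coarse preview | 2 x voxels, 8 iterations | — | the baseline needs the angular intensity trend, not image quality, but a too-coarse preview leaves residual trend that leaks into the score; half-resolution with a few extra iterations measurably improves agreement over a 4 x preview |

The median radius and the gasp duration interact structurally: a sliding
median of window `2r + 1` can only reject episodes shorter than about
half its window. Gasps spanning more projections than that are *followed*
by the filter and vanish from the score. At the packaged angular sampling
(360 projections per rotation) gasps last ~5 projections, inside the
usable regime; anyone re-parameterizing the phantom (or gating real data
with much coarser angular sampling) should keep `gasp_duration <= median
window / 2`.

## The synthetic multi-mouse phantom

The phantom emulates the published study conditions: four mice side by
side on a bed cylinder, each a soft-tissue ellipsoid (semi-axes
3.5 x 3.5 x 11 mm) containing an organ ellipsoid split at the diaphragm
plane into lung (-500 HU) and contrast-enhanced liver (400 HU) with two
hypodense 2 mm tumors (60 HU); bed -200 HU, air -1000 HU. Tissue values
are invented but representative of ExiTron-enhanced liver protocols; they
are configuration, not measurements. The desk-scale grid is 100 x 60 x 64
voxels at 0.4 mm, scanned over 360 angles onto a 96 x 72 detector with
1.2 mm pitch — chosen so a full simulate–gate–reconstruct–evaluate cycle
runs in minutes on one CPU. The published full-scale protocol (1440
projections, 1944 x 1536 detector, 80 um voxels) is retained as the
`"full"` geometry preset.

### Breathing kinematics and calibration

Each mouse's diaphragm displacement is zero outside gasps; within a gasp
it follows a raised-cosine pulse (cos^2 ramps around a full-amplitude
plateau, `ramp_frac = 0.7`), peaking at 1.2 mm caudal excursion. Gasps
recur every 22 projections (with integer onset jitter, SD 2) and last 5
projections. These numbers are calibrated to the published per-mode
projection fractions rather than guessed: with them, a mouse's own motion
discards ~13.5% of projections (published single-mouse value: 14.78%) and
the overlap-aware union discards ~21% (published: 22.22%), so the
motion-corrupted fraction sits at the published optimal rejection fraction
of 0.2. Breathing deforms only the diaphragm interface and liver contents
(rigid axial shift); there is no tissue compression model — sufficient to
produce the edge-hypodensity artifact, not a biomechanical simulation.

### Ground-truth labels

The manual labeling protocol is formalized as: label
`= round(10 * max_m rel_m * w_m)` per projection and MOI, where `rel_m`
is mouse `m`'s displacement relative to its own amplitude and `w_m` is 1
for the MOI itself, 0 for mice whose silhouettes do not overlap the MOI
at that angle, and the *squared* projected-overlap depth for mice that
do. The quadratic devaluation models the raters' graded judgment that "a
very slight overlap" is nearly irrelevant: a grazing overlap affects only
a thin strip at the MOI silhouette's margin, where the other animal's
attenuation change is also weakest, so the visible impact falls off
faster than linearly with overlap depth. Overlap itself is computed by
perspective-projecting each mouse's bounding cylinder onto the detector
axis and intersecting intervals — a conservative binary test (used for
the rejection-mode simulations) with a graded variant (used for labels).
Labels at or above 3 count as manual discards.

Noise is Poisson at a photon budget of `i0 = 1e4` counts per unattenuated
(desk-scale, effectively binned) detector pixel, seeded and reproducible.

### What the phantom does not emulate

Anatomically realistic anatomy (lobulated liver, airways, skeleton),
cardiac motion, contrast-agent pharmacokinetics, scatter, spectral
(polychromatic) physics, detector defects and gain maps, bed vibration,
and continuous-rotation blur. Passing tests on the phantom therefore
demonstrate the pipeline's *mechanics* — scoring, thresholding,
missing-angle reconstruction, metric computation — under controlled
motion; they do not certify performance on any particular scanner's raw
data.

## Evaluation metrics

* `line_profile_slope()` — trilinear-sampled profile from A to B at
  half-voxel spacing; ordinary least-squares slope (HU/mm) over an
  explicit fit segment. The hypodense edge gradient steepens the slope;
  gating flattens it.
* `edge_center_difference()` — mean of spherical ROIs centrally in the
  liver minus mean at the cranial edge; motion makes the edge hypodense.
* `cnr()` — liver-tumor contrast over the noise SD of a homogeneous bed
  region (sample SD of voxels). Increasing RF first improves contrast
  (consistency) then degrades CNR (fewer photons), producing an interior
  optimum.
* A note on the CNR denominator at desk scale: the published protocol
  derives noise from a homogeneous bed area, which on real 80 um scans is
  photon-noise dominated. At the package's desk voxel sizes photon noise
  largely averages out and the bed's residual variability is dominated by
  deterministic sampling/streak artifacts. Those artifacts are the
  quantity that actually degrades when angles are missing, so the
  rejection-fraction sweep measures the CNR denominator over the whole
  homogeneous bed interior ([bed_noise_mask()]), which tracks the
  artifact level stably; small spherical bed ROIs are retained for
  full-resolution comparisons. Consequently desk-scale CNR values
  characterize the artifact tradeoff, not absolute photon statistics.
* `gating_agreement()` — per-projection binary keep/discard match between
  the algorithmic mask and thresholded manual labels, in percent, with
  Cohen's kappa for context. The published evaluation does not spell out
  its agreement definition; per-projection binary match is the natural
  reading and is what this package reports.
* `simulate_rejection_modes()` — the three gating strategies
  (single-mouse, overlap-based, additive/breathing-pad) evaluated on the
  same labels; their rejection sets are provably nested, so used fractions
  are always ordered.

## Numerical choices

* Rejection count `k = round(RF * n)` uses half-up rounding; ties in the
  score break toward the lower projection index. The published method does
  not state its quantization; both choices are explicit here so masks are
  bit-reproducible.
* Sliding-median boundaries reflect (symmetric, edge sample included);
  window is `2 * radius + 1`.
* The CG cost trace is computed from the recurrence
  `f <- f - alpha * p.r + alpha^2/2 * p.q`, exact in exact arithmetic; a
  tolerance of `1e-8 * cost[1]` absorbs rounding before the monotonicity
  warning triggers.
* Degenerate inputs are rejected loudly: empty keep sets, nonpositive
  intensities (clamped with a warning in `log_transform()`), spheres
  containing no voxel centers, ROI spheres projecting off the detector
  (error names the angle).
* The unregularized least-squares reconstruction rings (Gibbs overshoot)
  at the sharp lung/liver interface of the hard-edged phantom; without
  projection smoothing the overshoot at the liver edge can exceed the
  motion-induced hypodensity and invert the edge-center readout. The
  evaluation workflows therefore apply the protocol's Gaussian smoothing
  before reconstruction (on the desk detector, which is already
  binned-equivalent, `sigma_px = 1.34`, `bin_factor = 1`), which damps
  the ringing to below the artifact signal. Real anatomy has softer
  interfaces and the real chain smooths and bins identically, so this is
  a fidelity choice, not a workaround.
* Desk-scale problem sizes used in the test-suite and acceptance runs:
  64^3 recon grids at 180 angles for solver self-consistency, the
  100 x 60 x 64 phantom at 360 angles for gating, reduced grids
  (50 x 30 x 32, binned detector) for the rejection-fraction sweep. These
  are the package's development-scale study conditions; the full protocol
  runs through the same code paths via the `"full"` preset.

## Orchestration

`run_simulate()`, `run_gate_and_reconstruct()` and `run_evaluate()` drive
the full pipeline from a single YAML-backed [run_config()] (see
`inst/extdata/example_config.yaml`): simulation writes the projection
stack as multi-page TIFF with a JSON sidecar plus label/trace CSVs;
gating+reconstruction writes per-mouse MetaImage volumes, rejection CSVs
and sinogram rejection-map PNGs; evaluation writes the mode-comparison,
agreement and image-metric tables and a Markdown report. Every step
echoes the resolved configuration and seed into the output directory, so
a run is reproducible byte-for-byte from its config alone. The
`inst/cli/retrogate` script exposes the same steps as shell subcommands
(`simulate | gate | reconstruct | evaluate | sweep | report`).

## Known limitations

* The binary overlap test uses bounding cylinders and slightly
  over-covers ellipsoidal bodies at grazing angles.
* The graded rater model (squared overlap depth) is one defensible
  formalization of "devalued accordingly"; real raters are not that
  consistent.
* Near-axial gantry angles of an in-row bed make all animals overlap at
  once; gasp episodes then crowd the motion curve and the radius-4 median
  partially follows them, which is the dominant source of residual
  gating/label disagreement (a few percent). The same failure mode must
  exist in any single-curve median-high-pass scheme.
* ROI placement is an explicit input; there is no automatic diaphragm
  detection (listed as future work for the original method as well).
* The beam-hardening stand-in is a polynomial on the line integrals; no
  spectral physics is simulated.
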