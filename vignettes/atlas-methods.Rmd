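---
title: "Building and validating probabilistic subcortical atlases with atlasforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating probabilistic subcortical atlases with atlasforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasforge)
```

## The problem

Small subcortical gray-matter nuclei — the putamen, caudate, pallidal
segments, the dopaminergic midbrain, and their neighbours — are hard to
segment automatically, and even expert manual delineation disagrees at the
boundaries. A now-standard remedy is to average high-resolution T1w/T2w
images from many subjects into group templates, have several observers
label each structure repeatedly on several such templates, and fuse the
delineations into a *probabilistic* atlas: a per-voxel map of the fraction
of delineations that included the voxel. The probabilistic form keeps the
observers' uncertainty instead of discarding it, supports probability-
weighted volumetry, and can be thresholded into deterministic labels when
a hard segmentation is needed.

`atlasforge` implements this construction and validation methodology as a
reusable toolkit, modelled on the build of the CIT168 subcortical atlas
(16 nuclei, 3 observers, 8 validation templates at 0.7 mm isotropic
resolution): multi-observer label fusion, hemispheric reflection warps,
probability-weighted volumetry with a percent laterality index, cumulative
relative frequency (CRF) uncertainty curves, and Dice / directed-Hausdorff
rater-reliability reports. A synthetic phantom generator reproduces the
whole study design so that every stage can be exercised — and its
statistical behaviour verified against closed-form ground truth — without
downloading any imaging data.

## Geometry conventions

All volumes live on a `voxel_grid`: an array shape plus a 4×4
voxel-to-world affine (RAS+ world coordinates in mm, 0-based voxel
indices). The affine is authoritative; spacing is *defined* as the column
norms of its 3×3 block, and 1 mm³ = 1 µl, so the canonical 0.7 mm template
grid has `voxel_volume_ul()` = 0.343 µl. Grids built from a spacing alone
are centred on the world origin, which places the mid-sagittal plane
x = 0 through the middle of the grid — the convention for AC–PC-aligned
templates, and the default reflection plane throughout.

## Label fusion and deterministic labels

Fusion is unweighted voxel-wise averaging (`build_prob_label`,
`fuse_atlas`): with 24 delineations (3 observers × 8 templates) a voxel
labelled by all of them gets probability 1, one labelled by 16 gets 2/3.
No observer-performance weighting (STAPLE and relatives) is attempted —
simple averaging is the method being packaged, and the per-voxel value has
the direct frequency interpretation that the CRF curves and the volumetry
rely on.

`prob2det` converts a probabilistic atlas to an index map by assigning
each voxel to the region of maximal probability *strictly above* the
threshold (default 0.5 — a voxel at exactly 0.5 stays background). Ties
between regions are broken by vocabulary order, deterministically, and
counted in an attribute so that silent arbitration is visible. Raising the
threshold can only shrink regions; the test suite checks this monotonicity
exhaustively on a toy atlas.

The CRF of a label is the cumulative distribution of its probabilities
over its *non-zero* voxels: `crf(t)` = #{voxels with 0 < p ≤ t} /
#{voxels with p > 0}. Flat curves rising only near 1 indicate
consistently delineated labels; convex curves with mass at low
probabilities indicate unreliable boundaries. The default threshold set is
100 evenly spaced values in (0, 1].

## The reflection warp

Left-hemisphere labels are mapped to the right hemisphere by a *reflection
warp*: a mirror reflection about the mid-sagittal plane, then an affine,
then optionally a dense displacement field computed by an external
diffeomorphic registration. The composition maps each left-hemisphere
point to its anatomically equivalent right-hemisphere point, so a
consistent labelling bias in the left hemisphere maps to the same bias on
the right, while genuine left–right asymmetry in location, shape or volume
is preserved.

Design choices worth knowing:

* **The diffeomorphic optimiser is not implemented.** The chain accepts an
  externally computed displacement field (world-space mm vectors on a
  grid, ITK-style) or none. The parameters used for the published template
  build are recorded verbatim in `syn_preset()` for users driving ANTs.
  Only the affine leg (`register_affine`) is internal: 9 DOF (translation,
  rotation, anisotropic scale about the fixed-image centre),
  multi-resolution mean-squares descent, deterministically initialised at
  the identity — no random numbers, so results are reproducible. A
  translation-only pass at the coarsest pyramid level precedes the full
  9-DOF descent; without it the optimiser can fall into a rotation-
  coupled local minimum for multi-millimetre shifts.
* **Pull-back sampling.** Chains store forward maps; resampling maps each
  output voxel centre through the chain inverse and samples the input
  there. Displacement fields are inverted on the fly by fixed-point
  iteration (tolerance 0.01 voxel, at most 20 iterations). Points mapped
  from outside the input field of view evaluate to 0.
* **Third-order B-spline interpolation with clipping.** Probabilistic
  labels are resampled with a proper interpolating cubic B-spline
  (recursive prefilter, mirror boundaries). Cubic interpolation overshoots
  at sharp edges — a step-edge probability map resampled through a
  half-voxel shift *will* leave [0, 1] — so outputs are clipped and the
  pre-clip range is kept in an attribute. Whether the original ANTs
  pipeline clipped after interpolation is not documented anywhere we know
  of; we clip and say so. Binary labels are resampled with
  nearest-neighbour unless explicitly promoted to probability.
* **Exact reflections.** `reflect_midsagittal` requires the grid to be
  axis-aligned in world x and symmetric about the plane, and is then an
  exact array flip: a bit-exact involution that preserves foreground
  counts. Oblique grids are rejected rather than silently resampled.
* The right-hemisphere output is sampled on the native template grid (not
  an upsampled one); nothing in the method requires a finer target grid.

## Volumetry and laterality

`prob_volume` integrates a probabilistic label — the sum of voxel
probabilities times the voxel volume — optionally against hemisphere
weights. Voxels centred exactly on the mid-sagittal plane are split half
to each hemisphere to avoid a systematic bias; left + right weights form a
partition of unity. The percent laterality index is

L = 100 (V_left − V_right) / (V_left + V_right),

positive when the left volume is larger. `volume_table` reports volumes at
full float precision; rounding to presentation precision (integer µl,
one-decimal laterality) is a formatting option only, because laterality
recomputed from *rounded* volumes does not always reproduce a laterality
computed from the unrounded ones. The packaged reference table
(`cit168_volume_table()`) illustrates this directly: for seven of its
sixteen rows (MN, STH, HN, VeP, SNr, VTA, EXA) the printed laterality is
inconsistent with the printed integer volumes, and the accessor flags the
nine self-consistent rows.

## Rater reliability

Two complementary similarity measures (`dice`, `directed_hausdorff`):

* **Dice**, D = 2|A∩B| / (|A|+|B|) — overlap relative to the mean volume.
  Dice is volume-sensitive: at fixed absolute boundary disagreement, small
  labels score much worse than large ones, so Dice under-reports the
  reliability of small nuclei. The phantom suite reproduces this law
  directly (mean inter-observer Dice non-decreasing across volume tiers at
  fixed jitter).
* **Directed Hausdorff**, H(A,B) = the maximum over A's voxels of the
  minimum Euclidean world-space distance to B's voxels — order-sensitive
  (H(A,B) = 0 iff A ⊆ B), reported in mm so anisotropic grids are handled
  correctly. The fast path is an exact Euclidean distance transform of B
  read at A's voxels (valid whenever the grid's world metric is separable
  along voxel axes); oblique grids fall back to exact brute force, and the
  all-pairs implementation is also exported as the reference oracle.

Empty labels are an *error* for both metrics, never a default 0 or 1 — a
silently defaulted metric value would corrupt every downstream summary.

`pairwise_report` mirrors the validation design: inter-rater mode pairs
observers within each template (3 observers × 8 templates → 24 comparisons
per region); intra-rater mode pairs templates within each observer (3 ×
C(8,2) = 84 per region; a `complement` option restricts to the
split/complement halves of each validation draw, since the published
design does not state which template pairs were used — all unordered pairs
is the default). Each unordered pair reports the mean of the two directed
Hausdorff values, with both raw directions retained. `summarize_similarity`
gives per-region mean and sample SD (n−1) with honest n.

## The phantom generator

`phantom_spec` / `make_study` emulate the study's structure: ellipsoidal
ground-truth regions in the left hemisphere, a mirrored right hemisphere
with a controlled per-region right/left volume ratio r (so the true
laterality is known in closed form, L = 100(1−r)/(1+r)), and a panel of
observers who each delineate every region on every template.

* **Ground truth.** Each region is an approximate signed-distance field to
  an ellipsoid passed through a Gaussian edge of scale
  `boundary_softness` (mm). The 0.5 iso-surface is the exact ellipsoid
  whatever the softness, so the analytic volume 4/3·π·abc is available as
  ground truth. Regions overlapping at the 0.5 level are rejected.
* **Observers.** An observer's label thresholds the signed distance after
  adding a spatially smooth, zero-mean perturbation (white noise smoothed
  at twice the boundary softness, normalised to unit variance) with
  amplitude `jitter`·√(π/2), so the expected absolute boundary
  displacement equals `jitter` mm. Smooth, spatially coherent noise is the
  point: human boundary disagreement is correlated along the boundary, and
  voxel-wise iid noise would make Hausdorff statistics absurdly large.
  In the multi-region study the per-cell labels are forced mutually
  exclusive the way a human's are — an observer paints one integer image —
  by assigning contested voxels to the region with the most negative
  jittered distance.
* **Determinism.** Every draw derives from the master seed through an
  injective per-(template, observer, region) stream-splitting scheme;
  the same spec yields byte-identical studies.
* **Defaults.** 64³ voxels at 0.7 mm (the template resolution, desk
  scale), 3 observers, 8 templates, boundary softness 0.7 mm (one voxel)
  and jitter 0.7 mm (one voxel). One voxel of expected boundary
  disagreement is the natural unit for expert raters on a high-contrast
  template.

### What the phantoms do and do not show

A geometric fact governs what to expect from these simulations: zero-mean
boundary jitter *inflates* the expected volume of a convex region by
roughly σ²/2 times the integrated mean curvature of its surface (for a
sphere, a factor 1 + 3σ²/R²). At one voxel of jitter this is negligible
for putamen-sized structures and large for habenula-sized ones — which is
precisely why the published methodology reports probabilistic volumes from
*fused* labels of large-sample templates, and why Dice degrades for small
nuclei. Consequently the parameter-recovery suite uses a large ellipsoid
(semi-axes 5, 4, 3 mm; analytic volume 251.33 µl) with sub-voxel jitter
(0.3 mm) and softness 0.35 mm: conditions under which fused volumes are
provably recoverable to within 5%, laterality to within a tenth of a
percentage point, and the deterministic P>0.5 masks to Dice ≥ 0.9 against
truth. The reliability suites keep the 1-voxel default jitter, where a
>5000-voxel sphere calibrates to a mean inter-observer Dice of ≈ 0.82 —
the frozen acceptance band (0.75, 0.88) comes from that calibration run.

Laterality recovery is asserted to one percentage point on the percent
index. At 0.7 mm resolution, hard-edged phantoms show quasi-random
discretisation scatter of ±0.4 points; the soft-edged fields integrate
more stably (≈ 0.1 point). A *relative* 1% criterion on L would be below
the discretisation floor of the stated grid and is not claimed.

The phantoms emulate the study's *structure*, not MRI physics: no bias
fields, no noise spectra, no intensity inhomogeneity, no inter-subject
registration error, and ellipsoids rather than real morphology. Passing
tests demonstrate that the estimators are correctly implemented and
statistically well-behaved under the modelled observer noise — not that
any particular real dataset meets the model.

### Problem sizes

The suites run on one CPU in minutes: registration recovery uses 32³
two-blob images (20 seeded translation cases, ≈ 0.3 s each); the
distance-transform oracle comparison uses 200 random label pairs on grids
up to 12³; the Dice-volume law uses four sphere tiers with 21
inter-observer comparisons each on the 64³ grid. These sizes were chosen
so the full statistical behaviour is exercised while the suite stays
comfortably interactive; every quantitative band quoted above was fixed
from calibration runs at exactly these sizes before being frozen into the
tests.

## Numerical notes and degenerate inputs

* Probability maps arriving from upstream B-spline interpolation may
  overshoot [0, 1] by a few 1e-7 (float storage); `read_volume` clips
  overshoot within 1e-6 with a warning and rejects anything larger.
* Binary NIfTI files holding a single non-zero label id k (ITK-SNAP
  export convention) are normalised to {0, 1} at load; files holding
  several ids must be split by id first.
* `dice`/`directed_hausdorff` on empty labels, `crf` on all-zero maps and
  `laterality(0, 0)` raise errors rather than inventing values.
* `make_validation_split` uses seeded sampling without replacement and
  restores the caller's RNG state; the original study's RNG is
  unrecoverable, so reproducibility within this toolkit is the goal, not
  reproducing the original draw.
* Registration is deterministic but local: it is intended for the small
  corrections of a reflection warp (millimetres, degrees, a few percent
  scale), not for arbitrary-pose initial alignment.

## Command line

The `atlasforge` script (installed under `exec/`) wraps the package
functions: `synth`, `build-prob`, `prob2det`, `crf`, `metrics`, `volumes`
and `reflect`, exchanging NIfTI volumes, 4×4 text affines and TSV
manifests/reports. The R functions are the primary interface; the script
adds nothing beyond argument parsing.
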