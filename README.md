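# atlasforge

Tools for building and validating **probabilistic brain atlases** from
repeated manual segmentations by multiple observers on shared template
grids — the methodology behind modern probabilistic subcortical atlases
such as CIT168 (16 subcortical nuclei delineated by 3 observers on 8
group-average validation templates at 0.7 mm isotropic resolution).

For atlas builders and segmentation methodologists, the package provides:

* **Label fusion** — voxel-wise simple averaging of binary delineations
  into probabilistic labels (`build_prob_label`, `fuse_atlas`), with the
  per-voxel value interpretable as the fraction of delineations that
  included the voxel.
* **Reflection warps** — mapping left-hemisphere labels to anatomically
  equivalent right-hemisphere points via mid-sagittal reflection → affine
  → optional dense displacement field, resampled with third-order B-spline
  interpolation and clipped to [0, 1] (`reflection_warp`, `apply_chain`,
  `register_affine`). The diffeomorphic leg is delegated to an external
  backend; the published SyN parameters are recorded in `syn_preset()`.
* **Volumetry and laterality** — probability-weighted volumes in µl by
  spatial integration per hemisphere, and the percent laterality index
  *L* = 100 (V<sub>l</sub> − V<sub>r</sub>) / (V<sub>l</sub> + V<sub>r</sub>)
  (`prob_volume`, `laterality`, `volume_table`).
* **Deterministic labels** — strict *P* > 0.5 maximum-probability
  labelling with vocabulary-order tie-breaking (`prob2det`).
* **Uncertainty curves** — cumulative relative frequency (CRF) of each
  label's probabilities over its non-zero voxels (`crf`).
* **Rater reliability** — Dice coefficient *D* = 2|A∩B|/(|A|+|B|) and
  directed Hausdorff distance *H*(A,B) = max<sub>a∈A</sub>
  min<sub>b∈B</sub> ‖a−b‖ in mm (exact distance-transform fast path,
  brute-force oracle exported), with the inter-rater (observer pairs per
  template) and intra-rater (template pairs per observer) report designs
  (`dice`, `directed_hausdorff`, `pairwise_report`,
  `summarize_similarity`).
* **Synthetic phantoms** — a fully seeded generator reproducing the whole
  study design (ellipsoid ground truth with soft edges, mirrored right
  hemisphere with controlled volume asymmetry, smooth-noise observers on
  multiple templates) so every stage is testable against closed-form
  ground truth (`phantom_spec`, `make_study`).

I/O covers NIfTI-1 volumes (via RNifti), 4×4 text affines, displacement
fields as 4-D vector NIfTI, and TSV manifests/reports. A thin command-line
wrapper (`exec/atlasforge`) exposes `synth`, `build-prob`, `prob2det`,
`crf`, `metrics`, `volumes` and `reflect`.

## Worked example

Simulate a small two-region study (3 observers × 8 templates, sub-voxel
observer jitter, right hemisphere 5% smaller than the left), fuse it, and
validate every estimator against the analytic ground truth:

```r
library(atlasforge)

spec <- phantom_spec(
  regions = data.frame(acronym = c("Pu", "RN"),
                       cx = c(-9, -9), cy = c(-9, 9), cz = c(0, 0),
                       ax = c(5, 3), ay = c(4, 2.7), az = c(3, 2.4)),
  boundary_softness = 0.35, jitter = 0.3,
  n_observers = 3, n_templates = 8, asymmetry = 0.95, seed = 42)

study <- make_study(spec)
atlas <- fuse_atlas(study$labels)
atlas
#> <prob_atlas> 2 regions (Pu, RN) on 64x64x64 voxels

summarize_similarity(pairwise_report(study$labels, mode = "inter"))
#>   region dice_mean dice_sd hausdorff_mean_mm hausdorff_sd_mm  n sd_degenerate
#> 1     Pu     0.853  0.0156              1.40           0.160 24         FALSE
#> 2     RN     0.769  0.0341              1.22           0.142 24         FALSE

volume_table(study$truth_left, study$truth_right, round_presentation = TRUE)
#>   region v_left_ul v_right_ul laterality_pct
#> 1     Pu       257        245            2.5
#> 2     RN        86         81            2.5

prob_volume(atlas$labels$Pu)
#> [1] 259.8   # analytic truth: 4/3 * pi * 5*4*3 = 251.3 ul
```

Reading the output: each region gets 24 inter-rater comparisons
(C(3,2) observer pairs × 8 templates). The larger putamen phantom scores a
higher Dice than the smaller red-nucleus phantom at identical boundary
jitter — Dice is volume-sensitive, which is exactly why the Hausdorff
distance (here ~1.2–1.4 mm) is the better metric for small nuclei. The
measured laterality (2.5%) recovers the analytic
100 (1 − 0.95)/(1 + 0.95) = 2.56% from the asymmetry ratio, and the fused
probabilistic volume lands within 3.4% of the closed-form ellipsoid
volume.

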