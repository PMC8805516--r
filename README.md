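# aneuscan

Candidate-based detection of cerebral aneurysms on time-of-flight MR
angiography (TOF-MRA)-like volumes, with an emphasis on *false-positive
reduction by multidimensional fusion*: alongside conventional planar (2D)
and stereoscopic (3D) convolutional classifiers, a fused MD model combines
multi-view maximum-intensity-projection (MIP) features with raw-voxel
features so that 3-D shape can veto 2-D look-alikes (bifurcations, vessel
curvature) and vice versa.

The full pipeline:

* **Preprocessing** — trilinear resampling to an isotropic 0.3906 mm grid,
  Nyúl–Udupa histogram standardization, artery extraction at the
  three-sigma intensity level.
* **Candidate extraction** — multiscale Hessian selective-enhancement
  filtering. With eigenvalues ordered |λ₁| ≥ |λ₂| ≥ |λ₃| and σ²
  normalization: blob = σ²λ₃²/|λ₁| (λ₁,λ₂,λ₃ < 0), line =
  σ²|λ₂|(|λ₂|−|λ₃|)/|λ₁| (λ₁,λ₂ < 0), plane = σ²(|λ₁|−|λ₂|) (λ₁ < 0).
  Cubic patches are cropped at blob-response candidates and labelled
  positive / partial / negative by annotation containment.
* **MIP panels** — 15 views per patch (3 canonical + ±30°/±45° tilts about
  X, Y, Z), vertically concatenated into the 2D branch's input.
* **Classifiers** — SE-ResNet-style branches (residual stages with
  squeeze-and-excitation gating, global average pooling) built and trained
  inside the package (compiled 2-D/3-D convolution kernels, Adam, binary
  cross-entropy); the MD model concatenates both branches' pooled features
  under one head, trained from scratch simultaneously.
* **Aggregation** — candidates with p > 0.5 vote; 26-connected footprint
  components with ≥ 6 votes ("more than five candidate voxels") become
  detections; detections closer than 16 voxels (≈ 6.25 mm) are merged.
* **FROC evaluation** — sensitivity (pooled over aneurysms) vs FPs/case,
  operating points at 80% sensitivity and 3 FPs/case, size- and
  location-stratified reports.
* **Synthetic phantoms** — a seeded generator of vascular phantoms (spline
  vessels with bifurcations, spherical wall aneurysms of 3–15 mm,
  per-aneurysm ground-truth masks) makes the whole pipeline testable
  without patient data. NIfTI in/out throughout.

## Worked example

```r
library(aneuscan)

cfg <- experiment_config(
  phantom = phantom_config(volume_shape = c(72, 72, 72), n_aneurysms = 2,
                           aneurysm_diameter_range_mm = c(3, 5.5)),
  n_volumes = 10,
  scales_mm = c(0.8, 1.2, 1.8),
  min_response_q = 0.45, candidate_mode = "dense", patch_side = 16,
  prefilter_retention = NA,
  net = net_config(patch_side = 16, branch_depth = 2, base_channels = 8,
                   se_reduction = 4, epochs = 8),
  archs = "md", seed = 11)
res <- run_experiment(cfg)
print(res)
#> <aneu_experiment>
#>   md: max sensitivity 1.000 @ 0.00 FPs/case; 0.00 FPs/case @ 80% sens
print(res$froc$md)
#>   threshold fps_per_case sensitivity
#> 1 0.9901684          0.0         0.5
#> 2 0.9896257          0.0         1.0
#> 3 0.9593979          0.5         1.0
#> 4 0.8698773          1.0         1.0
```

Ten phantoms (8 train/validation, 2 test) are generated, preprocessed and
filtered; the fused MD classifier is trained on the training cases and the
two held-out test cases are scored. The printed FROC rows sweep the region
score: at the strictest thresholds the model finds 1 of 2, then both test
aneurysms at 0 FPs/case, and only at looser thresholds do false positives
appear (0.5 then 1.0 per case) — i.e. both aneurysms are detected before
the first FP. `res$stratified$md` breaks sensitivity down by aneurysm size
bin (<3.0, 3.0–5.9, 6.0–8.9, ≥9.0 mm) and location, and
`res$operating_points$md` reports the fixed operating points.

Individual stages are exported (`generate_cohort()`, `resample_isotropic()`,
`nyul_train()`/`nyul_apply()`, `extract_arteries()`, `shape_filter()`,
`dense_candidate_points()`, `crop_and_label()`, `build_panel()`,
`build_2d()/build_3d()/build_md()`, `train_net()`, `detect_case()`,
`froc_curve()`, …); see the methods vignette
(`vignettes/aneuscan-methods.Rmd`) for the model, its assumptions, and the
design decisions. A thin CLI lives at `inst/scripts/aneuscan`
(`aneuscan phantom|run --n N --seed S --out DIR`).

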