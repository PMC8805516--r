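---
title: "Candidate-based aneurysm detection on TOF-MRA-like volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-based aneurysm detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Unruptured cerebral aneurysms appear on time-of-flight MR angiography
(TOF-MRA) as blob-like bulges on bright, tubular arteries. Automated
detectors reach high sensitivity but emit many false positives (FPs),
typically at vessel bifurcations and sharp curves, which look locally
blob-like. `aneuscan` implements a candidate-based detection pipeline whose
central idea is *multidimensional fusion*: a planar classifier reading
multi-view maximum-intensity projections (MIPs) and a stereoscopic
classifier reading the raw voxel cube are trained jointly, so the fused
model can use 3-D shape to veto 2-D look-alikes and vice versa.

The stages, in order:

1. **Preprocessing** — trilinear resampling to an isotropic 0.3906 mm grid;
   Nyúl–Udupa histogram standardization onto a common intensity scale;
   artery extraction by thresholding at mean + 3 sd of the (foreground)
   intensities.
2. **Candidate extraction** — a multiscale Hessian selective-enhancement
   filter bank with blob-, line- and plane-like responses; candidate voxels
   are taken where the blob response is high inside the artery mask; cubic
   patches are cropped around them.
3. **Labelling** — a patch is *positive* if it contains an entire annotated
   aneurysm, *partial* if it overlaps one without containing it (partials
   are excluded from training), *negative* otherwise.
4. **Pre-filter** — gradient-boosted trees over hand-crafted features
   (sphericity, filter-response statistics, component geometry) remove
   obvious negatives at an operating point retaining at least 99% of
   positives.
5. **Classifiers** — three variants share one recipe: SE-ResNet-style
   branches (strided stem convolution, residual stages with
   squeeze-and-excitation channel gating, global average pooling) ending in
   a fully connected sigmoid head. The 2D branch reads the 15-view MIP
   panel, the 3D branch the raw patch, and the MD model concatenates both
   branches' pooled features before a single head, trained from scratch
   simultaneously.
6. **Aggregation** — candidates with probability strictly above 0.5 vote;
   26-connected components of their footprints inside the artery mask that
   collect at least 6 votes ("more than five candidate voxels") become
   detection regions; regions closer than 16 voxels (about 6.25 mm at the
   working spacing) are merged.
7. **Evaluation** — free-response ROC (FROC): a detection is a true
   positive iff it shares at least one voxel with an annotated aneurysm;
   sensitivity is pooled over aneurysms; FPs are counted per case. Reported
   operating points: maximum sensitivity with its FPs/case, FPs/case at 80%
   sensitivity, sensitivity at 3 FPs/case, plus size- and location-
   stratified sensitivities.

## The 15 MIP views

Fifteen projections are generated per patch: the three canonical axis
views, plus the canonical view tilted by ±30° and ±45° about each of the X,
Y and Z axes. A tilt about an axis is applied to a canonical view *not*
aligned with that axis (X-tilts tilt the Y-view; Y- and Z-tilts tilt the
X-view), because rotating a view about its own projection axis only spins
the image in-plane and adds no information. The published description of
this view set does not enumerate the orientations; the enumeration used
here is the only natural reading that yields exactly 15 views, and it is
isolated in one function (`orientation_set()`) so an alternative set is a
one-line change.

Rays of a rotated projection that leave the patch cube are ignored rather
than zero-padded, and a ray that misses the cube entirely (possible at tile
corners) takes the patch minimum. This keeps every panel pixel inside the
patch's intensity range and makes a constant patch project to a constant
tile, which the zero-padding alternative would violate.

## Hessian filter bank

With Hessian eigenvalues ordered `|l1| >= |l2| >= |l3|` at Gaussian scale
sigma (responses sigma²-normalized, division guarded by 1e-12):

* blob: `s² l3²/|l1|` where all three eigenvalues are negative;
* line: `s² |l2|(|l2|-|l3|)/|l1|` where `l1, l2 < 0`;
* plane: `s² (|l1|-|l2|)` where `l1 < 0`.

Derivatives are central differences on the smoothed grid, with a sampled,
sum-normalized Gaussian kernel truncated at 4 sigma and reflected
boundaries; a one-voxel border is left at zero. On an analytic Gaussian
blob of scale `s0` the theoretical response at the center is
`s² A s0³/(s0²+s²)^{5/2}`, maximized near `s = sqrt(2/3) s0`; the test
suite checks the implementation against this closed form to within 5%, and
checks that an infinite cylinder yields zero blob but positive line
response on its axis.

The default scale set {0.6, 1.0, 1.6, 2.4, 3.6} mm covers the 3–15 mm
aneurysm range; the phantom study uses {0.8, 1.2, 1.8} mm matched to its
3–5.5 mm implants.

## Candidate density and the vote rule

The vote rule ("positive iff more than five candidate voxels agree")
presumes *dense* candidates — many overlapping candidate voxels per lesion.
Two extractors are provided. `extract_candidate_points()` returns
NMS-thinned local maxima of the blob response (useful for sparse seeding
and for the scale-selection tests); `dense_candidate_points()` returns all
suprathreshold in-mask voxels on a stride-2 grid and is the default for
experiments, because thinned maxima can never reach six votes on a single
lesion. The candidate floor is a configurable quantile of the in-mask blob
response (95th by default for the sparse mode; the phantom study uses the
45th so that tube-only negatives are well represented).

One consequence of formalizing "part of the artery" as a 26-connected
component of positive-candidate footprints: raising the decision threshold
tau removes candidates and can occasionally *split* one region into two
that each still clear the vote minimum, so the number of detections is not
strictly monotone in tau. The footprints do nest, however (each higher-tau
footprint is contained in the lower-tau footprint union), and that is the
invariant the tests assert.

## Hand-crafted features and surface area

Sphericity is `pi^(1/3) (6V)^(2/3) / A`. Surface area `A` is estimated as
the integrated gradient magnitude of the Gaussian-smoothed (sigma = 1
voxel) component indicator. A raw count of exposed voxel faces
over-estimates a sphere's area by a factor approaching 1.5, and correcting
that factor globally would over-credit axis-aligned shapes (a square
column would score "rounder" than a sphere); the smoothed-gradient
estimator is orientation-unbiased because the derivative of a smoothed
step integrates to exactly one per unit interface area.

## Networks

No pretrained weights or external frameworks are involved; the
convolutional kernels (2-D and 3-D forward/backward passes) are compiled
in the package and verified against finite-difference gradients in the
development process, with determinism contracts in the test suite. Design
choices where the source description left the values open:

* **Architecture** — a strided 3×3(×3) stem, then `branch_depth` residual
  stages; stage channels double each stage; every stage after the first
  downsamples by 2. Each block is conv–ReLU–conv with an SE gate (global
  pooling, bottleneck of width `channels / se_reduction`, sigmoid scaling)
  and an identity or 1×1 projection shortcut. No batch normalization: at
  the data scales targeted here, plain He-initialized blocks with Adam are
  stable and keep the parameter count and the determinism story simple.
* **Loss and optimizer** — binary cross-entropy on logits with Adam
  (default lr 1e-3, batch 32), positives weighted inversely to prevalence
  (switchable). The best-validation-epoch weights are returned.
* **Splits** — always at case level; 20% of training cases (or an explicit
  list) form the validation set; 4-fold case-level cross-validation
  (`cross_validate()`) is the sanctioned hyperparameter tuner.
* **No augmentation** — axis flips of the 3-D patch have no cheap
  counterpart on the already-built 15-view panel, so consistent
  augmentation of the fused model would require rebuilding panels every
  epoch; given the phantom scale it was dropped entirely rather than
  implemented inconsistently per branch.

## The phantom generator

Clinical TOF-MRA with expert aneurysm annotations is not distributable
with a package, so every stage is exercised on seeded synthetic phantoms:

* smooth random spline centerlines (one guaranteed bifurcation when at
  least two vessels are present) with a near-plug-flow radial intensity
  profile and a per-vessel signal factor drawn from [0.75, 1.05],
  emulating flow-dependent TOF signal;
* spherical aneurysms centered one vessel radius outside the wall so they
  protrude hemispherically, with equivalent diameters drawn uniformly from
  the configured range (capped at 15 mm — larger aneurysms are outside the
  modelled population) and intensity matching their parent vessel;
* additive Gaussian noise over a constant background.

Default signal levels (vessel 100, background 20, noise sd 10) are a
design choice: the source study reports no scanner intensity statistics,
so the phantom SNR is a free parameter set to a plausibly realistic
vessel-to-background contrast of 8 noise sd, not calibrated to any
dataset. The generator reproduces the geometry that drives FPs
(bifurcations, curvature) but **not** MR flow physics, skull/soft-tissue
background, intensity inhomogeneity, or anatomical arterial trees;
location labels are the synthetic strings "trunk" / "bifurcation" /
"distal". Tests passing on phantoms therefore demonstrate the pipeline's
mechanics and its relative model comparisons, not clinical performance.

## Study problem sizes

The end-to-end study configuration used by the tests and the acceptance
script runs 50 phantoms of 72³ voxels (32 train / 8 validation / 10 test
cases, about 2 aneurysms of 3–5.5 mm each), 16-voxel patches, three filter
scales, and compact networks (depth 2, base 8 channels, 5 epochs). These
sizes were chosen so a full three-architecture experiment completes in a
few minutes on one CPU while still leaving each model a learnable margin
over the constant predictor and a non-trivial FROC comparison; the
directional headline — the fused model matching the single-branch models'
sensitivity with no more FPs than the worse of them — is asserted over
three seeds by majority.

At this scale the hand-crafted features separate tube-only negatives from
aneurysms almost perfectly, so an active pre-filter removes nearly every
negative and leaves the classifiers nothing to learn and the FROC
comparison degenerate. The study configuration therefore disables the
pre-filter (`prefilter_retention = NA`); the pre-filter surface itself is
exercised and its ≥99% positive-retention operating contract asserted on
overlapping synthetic feature distributions. On clinical-scale data, where
feature distributions overlap heavily, it would remain on (the default),
and a config switch controls whether it also runs at inference.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based voxel indices; world position is
  `(index - 1) * spacing`; grids are axis-aligned (no oblique affines).
* Intensity interpolation is trilinear; masks use nearest neighbour.
* Nyúl–Udupa landmarks are the deciles, anchored at the 1st/99th
  percentiles mapped to [0, 100]; values outside the clip bounds clamp.
  Constant (degenerate-histogram) volumes are an error for normalization
  and yield an empty artery mask with a warning for thresholding — keeping
  everything would flood the candidate stage.
* The pre-filter threshold is the empirical `1 - retention` quantile
  (type 1) of positive scores, so the retention bound holds exactly on the
  set it was chosen on.
* Region representative points are footprint centroids rounded to the
  nearest voxel; merging closer-than-16-voxel regions keeps the
  highest-scoring member's representative point and score. Merging is by
  connected components of the proximity graph, so results do not depend on
  candidate or region order.
* `>0.5` and `>5 votes` are strict comparisons; `>= 16 voxels` apart means
  distinct detections.
* All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce every array bit-for-bit.

## Known limitations

* Phantoms lack real anatomy and MR physics (see above); absolute
  sensitivities/FP rates on phantoms say nothing about clinical data.
* The exact published 15-view enumeration and network hyperparameters are
  not public; both are configurable here and documented as this package's
  own defaults.
* Only axis-aligned isotropic geometry is supported in I/O.
* The FROC sweep variable is the region score (maximum member
  probability) with the vote rule applied at the fixed tau = 0.5; sweeping
  tau itself is possible via configuration but not the default.
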