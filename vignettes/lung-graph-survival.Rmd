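---
title: "Methods: anatomical lung-graph survival modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical lung-graph survival modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the package's own account of its methods: the model
and its assumptions, the tunable parameters, what the synthetic world does
and does not emulate, and the design decisions taken where the underlying
method description left choices open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The model

Each patient is represented as an undirected 10-node graph. Four nodes are
airway landmarks found by image analysis — the trachea root, the carina
(the bifurcation of the trachea into the main bronchi), and the distal
point of each main bronchus. Five nodes are the lung lobes (LUL, LLL,
RUL, RML, RLL), taken from a lobe label map supplied as input (or from the
phantom's ground truth; lobe segmentation itself is out of scope). One
node is the tumor, attached by an edge to every lobe it overlaps.

The fixed backbone is the anatomical tree the landmarks trace:

```
ROOT — CENTER;  CENTER — LEFT, RIGHT;
LEFT — LUL, LLL;  RIGHT — RUL, RML, RLL;  TUMOR — host lobe(s)
```

"Connected in their natural ways" admits several readings; we resolved it
as this bronchus-mediated tree because it is exactly the anatomy the four
landmarks describe, and we document it prominently since graphs with
lobes wired directly to the carina would be an equally literal reading.
Topology depends only on tumor lobe membership, never on image content
(a property the test suite asserts for all 31 lobe subsets).

Every node carries a 96-dimensional feature derived from a 64×64×64
intensity patch: the patch is encoded by a 3D CNN, globally
average-pooled to 1024 channels, and linearly reduced to 96. The
predictor is a stack of 1–4 SageConv blocks. Per block and node $v$:

$$h'(v) = \mathrm{LN}\!\big(\mathrm{Drop}\big(\mathrm{ReLU}\big(W\,[\,W_s h(v)\,;\,
\mathrm{LSTM}(h(u) : u \in N(v))\,]\big)\big)\big)$$

The LSTM aggregator consumes the neighbor sequence and its final hidden
state is the aggregate. An LSTM is order-sensitive, and no neighbor order
is canonical in an undirected graph; we fix it to the canonical role order
(`ROOT, CENTER, LEFT, RIGHT, LUL, LLL, RUL, RML, RLL, TUMOR`) so that
every forward pass is deterministic and permutation of storage order
cannot change a prediction (asserted in tests). Mean readout over the ten
node embeddings feeds a fully connected head with a sigmoid; the output is
calibrated as a 5-year mortality risk — higher score, higher predicted
risk of death within 60 months.

### Training

Binary cross-entropy on the 5-year label, 100 epochs, learning rate
initialized at 0.01 and multiplied by 0.1 on a validation-loss plateau
with a floor of 10⁻⁵, weight decay 5·10⁻⁵. Those five constants follow
the reference recipe; everything else was unreported and is a package
choice:

| parameter | default | rationale |
|---|---|---|
| optimizer | Adam (β₁ 0.9, β₂ 0.999) | the de-facto default for this family; plain SGD at lr 0.01 diverged on layer-norm nets in early experiments |
| hidden width | 128 (32 in tests) | unreported; tests shrink it to fit one CPU |
| dropout | 0.3 | unreported; mid-range default |
| batch size | 32 graphs | unreported; disjoint-union batching |
| plateau patience | 10 epochs, factor 0.1 | only init/min rates are stated |
| loss | BCE | the model "outputs a survival label"; BCE is the canonical choice for a sigmoid head |
| model selection | best-validation-loss epoch | consistent with the plateau monitor |

Weight decay is applied as an L2 term added to every gradient (classic
Adam-with-weight-decay, not decoupled). Gradients for the whole network —
BPTT through the LSTM, the concat/linear path, dropout and layer
normalization — are hand-derived and verified against central finite
differences at tolerance 10⁻⁴ in the test suite.

## Image analysis choices

**Seed selection.** The reference method "randomly picked a seed point
from non-background region"; we replaced this with a deterministic rule —
the largest sub-−950 HU component in the superior quarter of the volume
that does not touch the in-plane boundary (ambient air does), taking a
deep-air voxel (< −980 HU) nearest the component's top-slice centroid.
Rationale: reproducibility, and the tracheal tree the method describes
requires the seed to be in the airway anyway.

**Region growing.** Neighbors (26-connectivity) with HU strictly below
the threshold are admitted; the threshold relaxes from −980 HU in +20 HU
steps up to −500 HU. Leak control: a step that multiplies the mask volume
by more than 2.0 is rolled back and growth stops; a mask covering more
than 40% of the volume boundary raises a leak error. None of these
constants are stated by the reference; they are standard adaptive
region-growing practice. `segment_airway()` first applies a 3×3×3 box
filter — at noise SD 20 HU, unsmoothed volumes occasionally grow small
noise blobs at the bronchus tips that displace the distal landmarks.

**Skeletonization.** Distance-ordered homotopic thinning: border voxels
are peeled in increasing chamfer-(3,4,5) distance order whenever they are
simple (removal preserves the local foreground 26-topology and background
6-topology) and not curve endpoints. The result is unit-wide, connected,
and centered; end caps erode by up to the tube radius — an inherent
property of homotopic thinning, harmless here because landmarks are
defined by geodesic extremes, not by exact endpoints. Spurs shorter than
5 voxels are pruned before landmark search; thinning artifacts otherwise
create fake branch points near the carina.

**Landmarks.** Root = most superior endpoint (volumes are oriented
superior = low z, patient-left = high x). Carina = branch point of degree
≥ 3 with the shortest skeleton geodesic to the root. Left/right = the
skeleton point at maximal geodesic distance from the carina on each side
of its sagittal plane, restricted to points whose root-geodesic passes
through the carina. The original search procedure is in unpublished
supplementary material; this reconstruction follows the stated
root/carina/distal definitions and is flagged as a reconstruction.

**Patches.** Landmark cubes are fixed 64³ crops centered on the landmark
(center voxel at 0-based index 32), padded with −1000 HU (air — outside
the volume is physically absence). Lobe and tumor regions have variable
size; how they were fed to a fixed-input encoder is unstated. We crop the
bounding box (lobe patches additionally mask foreign tissue to −1000 HU,
the conservative reading) and trilinearly resample to 64³ so all ten
nodes share one encoder input shape. Intensities are clipped to
[−1000, 400] HU (the standard lung window, lumen through soft tissue) and
min-max scaled; normalized arrays carry a flag so repeated normalization
is a no-op — the affine map itself is deliberately not a projection.

## Feature reduction: "linear ridge transform"

The reference reduces 1024-dimensional pooled CNN features to 96 with "a
linear ridge transform", with no target or penalty stated. A supervised
ridge regression on outcomes would leak labels into node features before
graph training, so we reject that reading. We implement ridge-shrunk PCA:
center on the training rows, project on the top 96 right singular
vectors, and shrink direction $i$ by $s_i^2/(s_i^2+\lambda)$ — the same
shrinkage ridge regression applies along principal directions. λ = 0
reproduces plain PCA scores (asserted against a direct SVD oracle);
λ defaults to 1.0 (a package choice; the spectrum of pooled features is
orders of magnitude above 1, so the default shrinks only near-null
directions). The fit records the training-set identifiers and the
reducer is never refit at application time; rank-deficient fits leave
trailing directions at exactly zero. Signs follow the
largest-magnitude-loading-positive convention.

The default encoder is a small fixed-seed randomly initialized 3D CNN
(3³ stride-2 conv ×2, then a 1×1×1 expansion to 1024 channels). The
pretrained medical ResNet the reference used is an external artifact we
neither train nor distribute; the encoder is an interface, and random
convolutional features preserve enough low-order intensity/texture
statistics for the synthetic world's signal. The 1×1 expansion commutes
with global average pooling; `encode_patch()` pools first (identical
result, verified in tests, far less memory).

## The synthetic world

The phantom emulates the geometry the pipeline depends on, not CT
physics: an elliptical soft-tissue thorax (0 HU) spanning the full z
extent (so the trachea enters embedded in tissue, as in a neck slice);
two lung ellipsoids (−800 HU) split into five lobe compartments by axial
planes; a Y-shaped airway (trachea radius 4 mm entering at the top,
carina 40 mm deep, main bronchi at 35°/30° from vertical, radius 3 mm)
carved at −1000 HU; one spherical tumor (+40 HU) placed near its host
lobe's centroid, fully inside the lobe and clear of the airway; Gaussian
noise (SD 20 HU). Defaults: 128³ voxels at 1.25 mm — a half-scale thorax
that keeps a full phantom under half a second on one CPU.

Survival is exponential: $T \sim \mathrm{Exp}(h_0 e^{\beta d})$ with
baseline hazard $h_0 = 0.0018$/month, planted effect
$\beta = \log 2$ per cm of diameter $d$, administrative censoring at 84
months, and diameters uniform on 8–40 mm (draws exceeding a lobe's
geometric capacity are deterministically reassigned to the
largest-capacity lobe; capacities were calibrated once against the
default geometry). $h_0$ was chosen once so the 5-year labels are
roughly balanced at the mean diameter; the 84-month horizon exceeds 60
months so every patient's 5-year label is defined. Recurrence uses half
the death hazard, giving RFS columns the same machinery can analyze.
Host lobes are drawn with upper-lobe predominance as in real cohorts.

**Label convention.** The 5-year label is 1 for death within 60 months, 0
for survival past 60 months, and NA for patients censored alive before 60
months — excluded from classification but retained for KM/Cox. The
reference never states its handling of early-censored patients; exclusion
avoids label noise and matches common practice. Under the default
administrative horizon no label is NA.

**What a green test establishes.** The phantom has piecewise-constant
tissue classes, additive white noise, a two-generation airway, convex
axial lobes and a spherical tumor. It does not emulate partial-volume
effects, reconstruction kernels, respiratory motion, contrast phases,
airway wall thickness, fissure geometry, or tumor morphology. Green tests
therefore establish that the implementation is correct and that the
pipeline can recover a planted covariate through the full
image-to-graph-to-GNN path — not that the model reaches any particular
performance on clinical CT. The reference's headline test-set AUC is not
reproducible here by construction: it requires the multicenter cohort,
radiologist annotations and pretrained encoder weights, all external.

**Memory.** `generate_cohort()` returns the outcome table plus
per-patient phantom *specs*; volumes are materialized one at a time by
`cohort_sample()` and discarded after encoding (400 cached volumes would
need gigabytes).

## Evaluation statistics

All implemented from their definitions; the `survival` package appears
only as an independent oracle in tests.

- **Split**: per-stratum shuffling under the seed, exact global sizes
  ⌊0.75n⌋/⌊0.125n⌋/remainder apportioned to strata by largest remainder —
  1705 records give exactly 1278/213/214.
- **AUC**: midrank (ties half credit), equal to brute-force
  positive–negative pair counting (asserted for n ≤ 50). The 95% CI is a
  2000-replicate label-stratified bootstrap percentile interval with a
  fixed seed — the reference's CI method is unstated; the bootstrap is
  distribution-free and reproducible.
- **F2**: $(1+\beta^2)PR/(\beta^2 P + R)$ with β = 2; defined as 0 when
  precision and recall are both zero. Threshold metrics default to 0.5,
  overridable.
- **Risk groups**: median split, ties to low-risk — parameter-free and
  rank-invariant; whether the reference median-split or optimized its cut
  point is unstated.
- **Kaplan–Meier**: product-limit; S(0) = 1, drops only at event times.
- **Log-rank**: two-group chi-square with 1 df.
- **Cox**: single binary covariate, Newton–Raphson on the Breslow partial
  likelihood (for binary x the information reduces to
  $\sum_j d_j \bar x_j (1-\bar x_j)$), Wald CI and p. Breslow ties are
  the simplest correct default and the handler is isolated in
  `cox_score_info()` for swap-out.

## Numerical and testing notes

- Layer-norm ε = 1e-5; BCE computed in the numerically stable
  softplus form.
- All RNG flows through seeds; child seeds are derived arithmetically and
  kept below 2³¹. Same config ⇒ bit-identical cohorts, features, training
  histories and predictions (asserted).
- The planted-signal acceptance experiment uses a 400-patient cohort with
  ground-truth landmarks (the generator knows its own carina); the
  segmentation path is exercised separately by the landmark-recovery
  criteria. The three-seed robustness property varies the training seed
  on that fixed cohort: regenerating three 400-phantom cohorts would not
  fit the test-time budget.
- Acceptance and test runs use hidden width 32 and ≤ 60 epochs — a
  CPU-budget reduction the learning criterion explicitly allows.

## Known limitations

- The NIfTI codec is minimal: little-endian NIfTI-1, axis-aligned
  geometry, five datatypes. It exists because no NIfTI reader ships in
  this R stack; swap in a full reader for clinical data.
- Orientation canonicalization assumes volumes already follow the
  documented convention (superior = low z, patient-left = high x);
  arbitrary affines are not reoriented.
- The default encoder is untrained; it is a stand-in satisfying the
  encoder interface, not a substitute for pretrained medical features.
- Homotopic thinning erodes tube end caps by up to the tube radius;
  landmark logic is insensitive to this, but the raw skeleton length of a
  capped cylinder reflects it.
- Lobe segmentation, the clinical baseline models, external-cohort
  validation and multi-GPU training are out of scope.
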