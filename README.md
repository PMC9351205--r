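# lungraph

Anatomical lung-graph survival modeling from chest CT, in R.

Early-stage non-small-cell lung cancer outcomes depend not only on the
tumor but on its anatomical context. `lungraph` represents each patient's
chest CT as a 10-node anatomical graph — four airway landmarks (trachea
root, carina, left and right distal main bronchus), the five lobes (LUL,
LLL, RUL, RML, RLL) and one tumor node attached to its host lobe(s) — and
trains a GraphSAGE-style graph neural network with an LSTM neighbor
aggregator to predict 5-year overall survival. The package is aimed at
methodologists who want a fully inspectable, dependency-light
re-implementation of this kind of imaging-graph survival pipeline: every
stage, from region growing to Cox regression, is implemented in the
package and verified against independent oracles.

## Pipeline

1. **Airway segmentation** — adaptive region growing from a
   deterministically selected trachea seed: voxels with HU below a
   threshold relaxed upward from −980 HU in 20 HU steps are admitted;
   a step that multiplies the mask volume by more than ×2 (a leak into
   parenchyma) is rolled back.
2. **Skeletonization and landmarks** — distance-ordered homotopic
   thinning to a unit-wide centerline; root = most superior endpoint,
   carina = branch point nearest the root, left/right = deepest skeleton
   point on each side of the carina.
3. **Patch sampling** — ten 64×64×64 patches per patient (4 landmark
   cubes, 5 masked lobe crops, 1 tumor crop), clipped to the lung window
   [−1000, 400] HU and scaled to [0, 1].
4. **Node features** — a 3D convolutional encoder pools each patch to a
   1024-vector (a fixed-seed random encoder ships by default; pretrained
   weights can be plugged in), then a ridge-shrunk principal-component
   reduction, fitted on training patients only, maps 1024 → 96: score on
   direction *i* is shrunk by s²ᵢ/(s²ᵢ+λ).
5. **Graph model** — stacked SageConv blocks: per node *v*,
   h′(v) = LayerNorm(Dropout(ReLU(W·[W_s h(v) ; LSTM(h(u): u ∈ N(v))]))),
   neighbors consumed in canonical role order; mean readout over the ten
   nodes; a fully connected head with a sigmoid outputs the 5-year
   mortality risk. Training: binary cross-entropy, Adam, weight decay
   5·10⁻⁵, 100 epochs, learning rate 0.01 reduced ×0.1 on
   validation-loss plateau with floor 10⁻⁵.
6. **Evaluation** — AUC (midrank, stratified-bootstrap 95% CI),
   sensitivity/specificity/precision/F2, stratified 75/12.5/12.5 splits,
   median-split risk groups, Kaplan–Meier, log-rank, and Cox proportional
   hazards (Newton–Raphson, Breslow ties).

A **synthetic phantom module** generates chest-CT-like volumes (soft-tissue
thorax, two lung ellipsoids, five lobe compartments, a Y-shaped airway
tree, one spherical tumor, Gaussian noise) plus exponential survival
times whose hazard rises 2× per cm of tumor diameter — a planted,
recoverable signal that makes every stage testable without patient data.

## Worked example

```r
library(lungraph)

s   <- generate_phantom(phantom_spec(seed = 7))
seg <- segment_airway(s$ct)
seg$landmarks
#>    root: (3, 65, 65)
#>  center: (34, 65, 66)
#>    left: (59, 65, 83)
#>   right: (61, 65, 49)

patches  <- patient_patches(s$ct, seg$landmarks, s$lobe_labels, s$tumor_annotation)
enc      <- default_encoder()
raw      <- t(vapply(patches, encode_patch, numeric(enc$channels), enc = enc))
reducer  <- fit_reducer(raw, lambda = 1, fitted_on = "P0001")
features <- apply_reducer(reducer, raw); rownames(features) <- rownames(raw)
g <- build_graph(features, s$tumor_annotation$lobes, "P0001", label = 1L)
g
#> <lung_graph> patient P0001: 10 nodes, 9 edges, tumor in LUL, label 1
```

The designed carina of this phantom is at voxel (33, 65, 65); the
segmentation-derived carina lands within 2 voxels. The graph has the
fixed 8-edge anatomical tree plus one tumor–LUL edge.

Survival statistics on a 300-patient synthetic cohort (true planted
effect: hazard doubles per cm):

```r
cohort <- generate_cohort(cohort_spec(n_patients = 300, seed = 1))
tab <- cohort$table
rec <- survival_records(tab$id, tab$os_months, tab$os_event)
grp <- factor(tab$tumor_diameter_mm > median(tab$tumor_diameter_mm),
              labels = c("small", "large"))
log_rank(grp, rec)
#> log-rank chi-square 22.5, p = 2.15e-06
cox_hr(as.integer(grp == "large"), rec)
#> Cox PH: HR 2.10 (95% CI 1.54-2.88), p = 3.6e-06, 165 events
```

Large-versus-small median split recovers a hazard ratio of ~2.1 — the
expected effect of the ~1.6 cm median diameter gap at the planted
log(2)/cm effect size.

For the full synthetic pipeline (cohort → graphs → training → metrics):

```r
res <- run_pipeline(pipeline_config("out/", n_patients = 200, seed = 1,
                                    landmark_mode = "truth", epochs = 60))
res$metrics$auc
```

or from the command line:

```sh
Rscript inst/cli/lungraph.R phantom --n 100 --seed 7 --out phantoms/
Rscript inst/cli/lungraph.R segment-airway --ct phantoms/P0001_ct.nii.gz --out seg/
Rscript inst/cli/lungraph.R run-all --n 200 --seed 1 --out out/
```

## Layout

- `R/phantom.R` — synthetic thorax + cohort generator
- `R/airway.R` — seed selection, region growing, thinning, landmarks
- `R/sampling.R` — the ten 64³ patches, HU normalization
- `R/features.R` — encoder interface + ridge-shrunk PCA reducer
- `R/lung_graph.R` — 10-node graph assembly and serialization
- `R/gcn.R` — SageConv/LSTM network, manual backprop, training loop
- `R/evaluation.R` — AUC/F2/KM/log-rank/Cox, stratified splitting
- `R/pipeline.R`, `R/nifti.R`, `R/volume.R` — orchestration and I/O
- `src/` — Rcpp voxel primitives (region growing, thinning, resampling,
  3D convolution)
- `vignettes/lung-graph-survival.Rmd` — the methods notes
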