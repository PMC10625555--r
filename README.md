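# cochleaseg

Fully automated **joint inner-ear segmentation and anatomical-landmark
localization** for volumetric CT, as an R package. One dual-headed 3D
U-Net simultaneously segments the labyrinth fluid space (cochlea,
vestibule, semicircular canals) and localizes the three landmarks that
matter for cochlear-implant planning — the **helicotrema** (apex of the
cochlear spiral), the **oval window** and the **round window** — via
Gaussian heatmap regression with argmax decoding. The helicotrema /
round-window pair initializes cochlear-duct-length (CDL) measurements,
so localization accuracy translates directly into a physical worst-case
CDL error.

The package is aimed at researchers in computational otology and medical
image analysis who want a transparent, CPU-reproducible reference
implementation of this pipeline, including every stage around the
network:

- isotropic resampling to the 99 µm working grid (trilinear /
  nearest-neighbour), NIfTI I/O, 3DSlicer-fiducial and JSON/CSV landmark
  formats;
- quantile clipping (0.01/0.99), z-normalization, and cluster-wise
  histogram matching for domain-shifted scans;
- overlapping sliding-window chunking (128³ chunks, stride 25) with
  voxel-mean fusion;
- stochastic training augmentation (quarter-turn and free-angle
  rotations, contrast scaling, Gaussian/Poisson noise; protocols *alpha*
  and *beta*);
- scheduled Gaussian heatmap targets (amplitude up, spread down at preset
  iteration milestones);
- the configurable network family: double-convolution blocks,
  channel cascade {32, 64, 128, 256, 320}, instance/batch normalisation,
  six activations, additive attention gating, deep supervision
  (terminals at 1/2–1/8 resolution);
- the composite loss (binary cross-entropy + soft Dice + heatmap MSE,
  decoupled AdamW weight decay λ = 0.025);
- training with gradient accumulation, trapezoidal learning rate,
  periodic validation, best+last checkpointing, k-fold planning;
- rotation test-time augmentation (10 supersamples) with per-voxel
  standard-deviation uncertainty maps whose volume mean flags
  out-of-distribution inputs;
- the full metric suite: DSC, IoU, volumetric similarity, Hausdorff and
  average Hausdorff distance, per-landmark Euclidean deviation, and
  mean/SD/median cohort tables.

The model is

```
L = L_CE + L_sDSC + L_MSE + (λ/2)·w²
```

optimized per chunk; landmark k's target heatmap is
`α · exp(−‖x − c_k‖² / 2β²)` on the voxel grid.

There is no deep-learning framework dependency: the network engine is a
compact reverse-mode autodiff tape over GEMM-based 3D convolutions
(RcppArmadillo / OpenBLAS), bitwise-reproducible on CPU from recorded
seeds. A synthetic cochlea-like phantom generator (conical-spiral tube +
vestibule ellipsoid + canal tori in bone-like background) makes every
stage testable without external imaging data.

## Worked example

Train the desk-scale configuration on synthetic phantoms and predict a
held-out volume (about five minutes on one CPU core):

```r
library(cochleaseg)

# 20 phantoms at 32^3: dark fluid-space structure in bright bone
cohort <- generate_cohort(20, shape = c(32, 32, 32), seed = 11)
insts <- lapply(cohort, function(p) {
  v <- preprocess_internal(p$volume)$volume   # clip + z-normalize
  cochleaseg:::prepare_instance(v$data, p$label$data, p$landmarks,
                                chunk = 32L, stride = 25L)
})

net <- build_network(network_config(levels = 2, channels = c(8, 16, 24),
                                    attention = "none"), seed = 2)
fit <- train_one_fold(net, insts[1:15], insts[16:20],
                      train_config(iterations = 300, accumulation = 2,
                                   peak_lr = 5e-3, validation_every = 75,
                                   seed = 3),
                      schedule = heatmap_schedule(c(0, 100, 250),
                                                  alpha = c(1, 5, 10),
                                                  beta = c(6, 4, 2)),
                      verbose = TRUE)
#> it 75   val DSC 0.9270  IoU 0.8640  MSE 0.00677  loss 0.1385
#> it 150  val DSC 0.9681  IoU 0.9382  MSE 0.02042  loss 0.0835
#> it 225  val DSC 0.9874  IoU 0.9752  MSE 0.01185  loss 0.0431
#> it 300  val DSC 0.9933  IoU 0.9866  MSE 0.04026  loss 0.0538

# held-out prediction: segmentation + landmarks in one pass
p <- cohort[[16]]
v <- preprocess_internal(p$volume)$volume
pred <- predict_volume(fit$net, v, chunk = 32L, stride = 25L, tta = FALSE)
evaluate_instance(pred$label$data, p$label$data, pred$landmarks, p$landmarks)
#>         dsc       iou       vs hd     avg_hd dev_helicotrema dev_oval_window
#> 1 0.9891641 0.9785605 0.996904  1 0.01082643        1.414214               1
#>   dev_round_window dev_average
#> 1         1.414214    1.276142
```

A DSC near 1 means the predicted fluid-space mask overlaps the ground
truth almost perfectly; deviations are Euclidean distances in voxel
units between decoded and true landmark positions (here ≤ 1.5 voxels
each).
With `tta = TRUE` the prediction additionally carries a per-voxel
uncertainty map; `uncertainty_summary()` of a domain-shifted scan is an
order of magnitude above an in-distribution one.

A shell interface wraps the same functions
(`inst/cli/cochleaseg simulate|preprocess|train|predict|evaluate`), each
run writing a JSON manifest from which it can be replayed.

## Package layout

| Module | Contents |
|---|---|
| `R/volume.R`, `R/io.R` | volume/label/landmark types, NIfTI + fiducial I/O, isotropic resampling |
| `R/phantom.R` | synthetic cochlea-like phantom generator |
| `R/preprocess.R` | clipping, z-normalization, histogram matching |
| `R/chunking.R` | sliding-window chunk grids and voxel-mean fusion |
| `R/augment.R` | training-time augmentation protocols |
| `R/heatmap.R` | Gaussian heatmap targets, schedules, argmax decoding |
| `R/autograd.R`, `src/` | autodiff tape and GEMM conv kernels |
| `R/model.R` | the dual-headed network family |
| `R/losses.R` | component and composite losses |
| `R/optim.R`, `R/training.R` | AdamW/SGD, trapezoid LR, training loop, folds |
| `R/inference.R` | TTA, full-volume prediction, uncertainty |
| `R/metrics.R` | DSC/IoU/VS/HD, landmark deviations, report tables |
| `R/config.R`, `R/cli.R` | YAML config validation, subcommands, manifests |
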