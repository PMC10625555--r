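---
title: "Joint inner-ear segmentation and landmark localization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inner-ear segmentation and landmark localization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cochlear-implant planning needs two things from a temporal-bone CT scan:
a segmentation of the inner-ear labyrinth fluid space (cochlea, vestibule,
semicircular canals — the cavity bounded by bone and by the round- and
oval-window membranes) and the positions of three anatomical landmarks —
the helicotrema at the apex of the cochlear spiral and the centres of the
oval and round windows. The landmark pair (helicotrema, round window)
initializes cochlear-duct-length (CDL) measurements, which in turn drive
electrode selection and frequency mapping. `cochleaseg` implements a fully
automated pipeline that solves both tasks jointly with one volumetric
neural network and no manual interaction or postprocessing.

## Model

The network is a dual-headed 3D U-Net: a single convolutional encoder
distills context from a cubic input chunk; two structurally identical
decoders share that encoding. The *segmentation head* emits one channel
through a sigmoid, a pseudo-probability map the size of the input. The
*heatmap head* emits three linear (no output nonlinearity) channels, one
per landmark; a landmark estimate is the global argmax of its channel.

The building block is a double-convolution module — normalisation, 3×3×3
convolution, nonlinearity, applied twice. Downsampling is a stride-2
kernel-2 convolution; upsampling a stride-2 kernel-2 transposed
convolution; decoder levels concatenate the encoder skip feature. Channel
counts are held constant across a level transition and increase inside the
following block. The working configuration has four levels with channel
cascade 32, 64, 128, 256, 320, so a 128³ chunk passes through encoder
resolutions 64³, 32³, 16³, 8³. The test-scale configuration used
throughout the package's own studies has two levels and channels 8/16/24
on 32³ chunks — small enough to train on one CPU in minutes while
exercising every architectural element.

Options mirror the family's ablation axes: instance or batch
normalisation (identical for the batch-of-one-chunk training regime used
here, which is why both names map to one implementation), six
nonlinearities (leaky ReLU with slope 0.025 as the base, ReLU, PReLU,
GELU, SiLU, Mish), additive attention gating on the skip connections
(none / one head / global), and deep supervision: auxiliary 1×1×1 output
heads at decoder levels 2–4 (resolutions 1/2 to 1/8) compared against
downsampled targets.

### Loss

The training objective is the unweighted sum of a segmentation term, a
heatmap term and weight decay,

$$\mathcal{L} = \mathcal{L}_\mathrm{CE} + \mathcal{L}_\mathrm{sDSC}
  + \mathcal{L}_\mathrm{MSE} + \tfrac{1}{2}\lambda\,\mathbf{w}^2 ,$$

with binary cross-entropy plus soft Dice
($1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$,
$\varepsilon = 10^{-5}$) for segmentation and voxel-mean MSE between the
predicted and target heatmaps. MSE is voxel-mean rather than voxel-sum so
its scale does not depend on chunk size. Weight decay is decoupled: it is
applied by the AdamW step, never mixed into the loss value or the
gradient moments. The ablation variants (pure Dice, squared-denominator
Dice, log-cosh Dice, pure cross-entropy) are selectable. With deep
supervision, each term is a weighted sum over terminals with default
weights 1, 0.5, 0.25, 0.125 normalised to one — halving per resolution
step is standard practice; the reference protocol does not fix them.

### Heatmap targets and scheduling

The target for landmark $k$ at voxel $x$ is the Gaussian
$\alpha \exp(-\lVert x - c_k\rVert^2 / 2\beta^2)$, where $\beta$ acts as
the standard deviation ("spread") and $\alpha$ as the amplitude. Over
training the targets sharpen on a preset schedule: $\alpha$ never
decreases and $\beta$ never increases across milestones, guiding the
network from diffuse blobs it can learn early to peaked modes that decode
precisely. The default schedule (milestones 0 / 15 000 / 37 500 with
$(\alpha,\beta)$ = (1,6), (5,4), (10,2) voxels) satisfies that
monotonicity; the exact sequences of the reference protocol are not
published, so these are package defaults exposed in the configuration.
Decoding is pure argmax with ties broken to the lexicographically
smallest index; no sub-voxel refinement is attempted, matching how the
localization error is defined (in whole voxel units).

## Data flow

**Resampling.** Convolutional features are scale-sensitive, so every
input is first resampled to the isotropic working spacing (99 µm, the
native voxel size of the flat-panel CT protocol the method targets):
trilinear for intensities, nearest-neighbour for labels (keeping them
integral), coordinates rescaled per axis. Border samples replicate the
edge voxel so constant volumes stay constant.

**Normalisation.** In-domain scans are clipped at the 0.01/0.99 empirical
quantiles of the whole volume and z-normalised to zero mean, unit
standard deviation. Quantiles interpolate linearly between order
statistics; the standard deviation uses the population convention — both
conventions are arbitrary but fixed and tested. Scans from shifted
domains (different specimen preservation, scanner offsets) are
additionally histogram-matched: a monotone quantile mapping (256 levels)
onto a stored reference table computed from the training domain. The
matching is applied per intensity *cluster*, with cluster thresholds
supplied by the user — shifted cohorts show visually identifiable
contrast clusters, and delineating them is a judgement call this package
does not automate. Order of operations is clip → match → z-normalise;
rank statistics make the result invariant to monotone intensity
distortions of the input.

**Chunking.** Volumes are processed as overlapping cubic chunks (default
edge 128, isotropic stride 25) in a sliding-window grid whose final
origin per axis snaps to `dim − chunk`, guaranteeing full coverage
without padding; volumes smaller than the chunk edge are zero-padded
symmetrically and cropped after fusion. Overlapping chunk predictions are
fused by the unweighted voxel mean — the simplest rule consistent with
how test-time-augmentation supersamples are averaged, and isolated behind
the chunking module so a weighted alternative could be swapped in.

**Augmentation.** Training chunks are augmented stochastically: fixed
quarter-turn rotations (pure voxel permutations; about axis 1 only under
protocol *alpha*, about all three axes under *beta*), free-angle
rotations about a random coordinate axis (amplitude 30° for alpha, 45°
for beta; trilinear for intensities, nearest-neighbour for labels, exact
rotation matrix for landmark coordinates), multiplicative contrast
scaling, and additive Gaussian or Poisson noise. Poisson noise shifts
intensities into a positive range, samples counts, and shifts back, since
z-normalised inputs can be negative. Per-transform application
probability defaults to 0.5 and the scale/noise magnitudes are config
values — the reference protocol does not print them.

**Inference.** Test-time augmentation runs every chunk through the
identity plus the nine quarter-turn rotations (90°/180°/270° about each
axis — 10 supersamples), inverts each transform on both head outputs, and
averages on the voxel level. The per-voxel population standard deviation
(divisor $N$) of the 10 segmentation supersamples is aggregated into an
uncertainty map; its volume mean is a scalar out-of-distribution signal —
domain-shifted or pathological inputs show a strongly elevated value.
The fused probability map is binarised at 0.5 (no threshold is published;
0.5 is the symmetric choice), and landmarks are decoded from the fused
full-volume heatmaps so the argmax is global rather than per-chunk.
There is deliberately no postprocessing (no largest-component filter, no
shape model).

## Training procedure

One iteration is one forward/backward pass of a chunk. Gradients are
accumulated over `accumulation` iterations and applied as their *mean*,
making the update invariant to the accumulation factor; the
accumulated-mean update equals the large-batch update to numerical
precision, which is a tested property. The optimizer is AdamW
($\lambda = 0.025$) with an SGD-momentum alternative; the learning rate
follows a trapezoid — linear warmup, plateau, linear anneal (default
10 % / 60 % / 30 %, peak $10^{-3}$; the reference values are not
published). Every `validation_every` iterations (default 750) the
segmentation head is scored with DSC and IoU and the heatmap head with
MSE and MAE on the validation instances, and both the best-by-validation-
DSC and the last parameter sets are checkpointed. Cross-validation uses
independent random resampling per fold (e.g. 38 train / 5 validation from
43), matching a random-selection protocol rather than a strict partition.

## The phantom generator

Real temporal-bone CT cannot ship with a package, so every stage is
exercised on synthetic phantoms that reproduce the *testable structure*
of the anatomy, not its true shape: a conical-spiral tube (cochlear
turns; radius decreasing from base to apex), an ellipsoidal vestibule,
three tori (semicircular canals), embedded as a dark fluid space
(400 intensity units) in bright bone (1800), with additive Gaussian noise
(sd 30). The helicotrema analog is the spiral's apex endpoint; the window
analogs are disc patches on the vestibule surface. Geometry is rasterised
by stamping balls along parametric curves, so the spec's rigid rotation
applies exactly to geometry and landmarks together, with no image
interpolation. Default parameters scale with the volume edge; at 32³ the
foreground occupies ~2 % of the volume, matching the sparsity of the real
structure in a temporal-bone field of view. Domain shifts are emulated by
contrast inversion (dry/embalmed-specimen analog) and constant intensity
offsets (scanner-offset analog).

What the phantoms do *not* model: true cochlear morphology and its
anatomical variation, partial-volume effects, beam hardening, metal
artefacts, and annotation noise. Passing the package's studies therefore
demonstrates that the pipeline's machinery is correct and that the joint
architecture can learn segmentation and localization from volumetric
contrast — it does not certify clinical performance on real scans.

## The scaled-down study

The package's end-to-end study (also what `scripts/acceptance.R`
recomputes) trains the two-level 8/16/24-channel dual-head network on 15
phantoms at 32³ for 300 iterations (accumulation 2, AdamW, peak learning
rate 5×10⁻³, compressed heatmap schedule with milestones 0/100/250) and
evaluates on 5 held-out phantoms: segmentation DSC/IoU/VS/HD and mean
landmark deviation, plus the TTA uncertainty contrast between
in-distribution phantoms and a contrast-inverted one. A single-task
segmentation-only variant (the heatmap decoder simply not run) is trained
identically to check multi-task parity. These problem sizes are the
package's chosen desk-scale study conditions; the acceptance suite
verifies that held-out segmentation and localization quality are reached
within them.

## Numerical engine and reproducibility

No deep-learning framework for R is assumed. The network runs on a small
reverse-mode automatic-differentiation tape; 3D convolutions and their
adjoints are GEMM-based (im2col tiled over z-planes so the unfold buffer
stays cache-resident) in C++ via RcppArmadillo, with analytic gradients
for every layer and loss validated against central finite differences.
Initialization is uniform with fan-in scaling from a recorded seed;
training, augmentation and phantom generation all draw from explicitly
seeded streams, so a full run is bitwise reproducible on CPU. All
computation is double precision.

Numerical conventions worth knowing: Dice smoothing $\varepsilon=10^{-5}$
in numerator and denominator; cross-entropy inputs clamped to
$[10^{-7}, 1-10^{-7}]$; population SD (divisor $N$) for TTA voxel
uncertainty but sample SD (divisor $N-1$) for cohort-level aggregate
tables, mirroring how each is used; Hausdorff distances are computed
between the full foreground voxel sets in voxel units, with the exact
maximum (no percentile robustification); empty masks make HD undefined
and raise an error rather than reporting 0; both-empty overlap scores are
defined as 1.

## Known limitations

- DICOM series cannot be read directly (no DICOM codec is available to
  the package); convert to NIfTI upstream.
- The engine is CPU-bound: the full 32–320-channel configuration on 128³
  chunks is far beyond desk-scale budgets, so full-size training runs are
  out of reach; the architecture is validated structurally (shape tracer
  plus forwards at smaller scales) and functionally at the test scale.
- Cluster thresholds for external preprocessing are user judgement, not
  an algorithm.
- Landmark decoding is integer-voxel argmax; sub-voxel refinement is out
  of scope.
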