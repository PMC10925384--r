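---
title: "Synthesis-trained skull-stripping: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesis-trained skull-stripping: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skull-stripping — isolating brain tissue from skull, scalp, neck and
background in a 3D head scan — is the first step of most neuroimaging
pipelines. Pediatric data makes it hard: the brain doubles in size over the
first two years, gray/white MRI contrast inverts around 6–9 months, motion is
common, and scans often include shoulders and chest. Tools tuned to adult
anatomy and contrast transfer poorly.

`pedistrip` implements a synthesis-based training strategy for this problem.
Instead of training a segmentation network on acquired images, every
optimization step renders a *synthetic* head scan from an anatomical label
map, with aggressively randomized geometry and intensity. The network never
sees the same image twice and cannot latch onto any one contrast, so it is
pushed toward contrast- and age-agnostic shape cues.

## The generative model

Each training step draws one whole-head label map $s$ and produces a pair
$(x, y)$:

1. **Spatial augmentation.** $s$ is resampled through the composition of a
   random affine (translation, rotation, per-axis scale, shear, all drawn
   uniformly from configured ranges) and a smooth nonlinear warp (Gaussian
   control-point offsets, trilinearly upsampled). Labels use
   nearest-neighbor interpolation. The image is rendered *from the warped
   map* rather than warped after rendering, so image and labels correspond
   exactly by construction; both carry a hash of the shared transform, and
   the test suite asserts it.
2. **Intensity synthesis.** Each label receives a mean drawn uniformly from
   `intensity_mean_range`, one global noise SD is drawn from
   `intensity_sd_range`, and voxels are sampled from the label's normal
   distribution (clamped at zero).
3. **Corruption.** In fixed order: multiplicative bias field
   (`exp` of a smooth random log-field), min–max normalization followed by
   random gamma exponentiation, random edge cropping, block-downsampling
   with nearest restoration, and Gaussian blur. Each fires with its own
   probability from its own derived random stream, so whether one corruption
   fires never perturbs another's draws.

The ground truth follows from the *augmented* label map: all labels with
role `brain` (ventricles included) are merged — extracerebral/sulcal CSF,
role `csf_nonvent`, is excluded, matching pipelines that want CSF-free
masks — then the space between folds is bridged with 10 iterations of
dilation followed by 10 of erosion (6-connected), and remaining 3D holes are
filled. The signed distance transform of that mask supports the regression
variant of the loss.

### Default sampling ranges

The source framework does not pin the sampling ranges, so the package fixes
its own, chosen to exceed the variability of acquired MRI (the `"full"`
preset, for 256 mm fields of view): translation ±15 mm, rotation ±45°,
scale [0.7, 1.3], shear ±0.1, warp control spacing 16 mm with 3 mm SD, label
means uniform on [0, 255], global SD on [1, 15], bias log-field SD 0.3 at
24 mm control spacing, gamma log-SD 0.3, crop ≤ 20 % per axis, downsampling
factors {1, 2, 4}, blur σ ∈ [0.1, 2] mm. Corruption probabilities are 0.9
(bias, gamma, blur), 0.3 (crop), 0.5 (downsample). The `"desk"` preset
scales the millimeter-valued ranges to the 48 mm phantom field of view
(translation ±5 mm, warp 12 mm/1.5 mm, bias control 16 mm, crop ≤ 15 %,
blur σ ∈ [0.1, 1] mm, downsampling factors {1, 2}); everything else is
unchanged. All values live in `synth_config()` and can be
overridden individually.

## Architecture and losses

The network is a 3D U-Net: two 3×3×3 convolutions with leaky-ReLU
(slope 0.2) per resolution level, 2× max-pooling down, nearest-neighbor
upsampling up (the first convolution after each upsampling acts as the
learned upsampling filter — chosen over transposed convolution to avoid
checkerboard artifacts), skip concatenation, and a 1×1×1 projection to
either two softmax channels (brain, background) or one linear channel
predicting the signed distance transform. Feature widths double per level
from `base_channels`, capped at `channel_cap`. The full-scale preset
(`unet_config_fullscale()`) has seven levels; worked examples and tests use
3-level networks on 48³ grids.

Because no deep-learning framework is available to R in this package's
dependency set, the network — forward pass, backpropagation, Adam — is
implemented in the package itself, with register-blocked direct-convolution
kernels in C++ behind a plain R API. The backward pass is verified against
central-difference numerical gradients in the test suite (relative error
~1e-8 at double precision). The convolution kernels also offer a
single-precision mode (`unet_config(precision = "single")`, ~1.5x faster on
one core and numerically ample for training — weights, optimizer state and
all other arithmetic stay double); the desk-scale runs use it, while
gradient verification runs in double. The projection head is initialized
near zero (weight SD 0.01) so early softmax outputs stay close to uniform:
with conventional He initialization the minority brain channel saturates to
zero probability within a few dozen steps of contrast-randomized training,
after which soft-Dice gradients (proportional to the predicted probability
through the softmax) are too small to escape within a desk-scale step
budget. This initialization choice was made from dedicated escape
experiments and is asserted indirectly by the end-to-end tests.

**Dice loss.** For channels $c \in \{j, k\}$ (brain, background),

$$D_c = \frac{2\sum_v y_c \hat y_c + \varepsilon}{\sum_v y_c^2 + \sum_v \hat y_c^2 + \varepsilon},
\qquad L = -\tfrac12 (D_j + D_k), \qquad \varepsilon = 10^{-6},$$

the standard two-channel soft Dice, ranging from −1 (perfect) to 0
(disjoint).

**SDT loss.** Weighted MSE between target and predicted signed distances:
voxels within $h$ mm of the boundary get weight 1, farther voxels weight
$b$ (defaults $b = 10^{-3}$, $h = 4$ mm), concentrating gradients near the
brain boundary. The *unweighted* variant (`usdt`) sets all weights to 1.

**Sign convention.** The package uses negative-inside everywhere. Boundary
voxels (mask voxels with an in-grid background face-neighbor) have distance
zero, so the exact mask recovery rule is `sdt <= 0`
(`sdt_to_mask()`), while continuous network predictions threshold at
`sdt < 0`. One consequence of defining the boundary on the mask side is that
the SDT of a mask's complement is not the exact voxelwise negation of the
mask's SDT (the two boundaries differ by one voxel layer); tests therefore
validate each SDT against an all-pairs oracle rather than by negation
symmetry.

## Training procedure

Stochastic gradient descent with Adam, batch size 1: each step draws one
label map uniformly (seeded), generates a fresh synthetic pair, derives the
targets, and takes one update. Validation runs every `validation_interval`
steps on held-out acquired-style images and always scores Dice against the
reference mask, so runs with different training losses are comparable: for
softmax networks the score averages the soft Dice of the brain probability
(graded, so plateau detection registers progress while the thresholded mask
is still empty) with the hard Dice of the thresholded mask (the deployment
metric, so checkpoint selection tracks it); SDT networks use the hard Dice
of the thresholded prediction. Training stops when validation fails to
improve by `plateau_min_delta` for `plateau_patience` consecutive
validations, or at `max_steps`; the best-validation checkpoint is returned.

Three optional stabilizers, all exposed in `train_config()` and all used by
the desk-scale preset, address pathologies observed in batch-1 training
under full appearance randomization: a global gradient-norm clip (0.5)
prevents bursts of large conflicting gradients from re-saturating the
softmax head mid-run (a collapse that is practically irreversible at this
step budget, see the head-initialization note above); a step learning-rate
decay (x0.5 every 150 steps from 1e-3) lowers the late-phase parameter
noise; and a tail weight average (`swa_start`) is validated against the
best single checkpoint and returned only when it scores better. Exponential
weight averaging over the whole trajectory (`ema_decay`) is also available
but measurably hurt held-out accuracy in this regime and is off by
default.

Defaults where the source framework is silent: learning rate 1e-4
(full-scale preset), patience 5, min-delta 1e-4. The desk-scale runs in the
tests and the acceptance script use learning rate 1e-3, chosen from a
single-image overfitting experiment during development (a 3-level, base-8
network reaches hard Dice > 0.95 on one fixed phantom image within ~100
steps at this rate), with patience 8 at a 25-step validation interval:
contrast-randomized training passes through a slow, noisy escape phase
before the validation loss moves, and tighter patience was observed to stop
runs mid-escape.

All randomness is derived from user seeds through a fixed stream-splitting
scheme, so training pairs and whole training runs are bit-reproducible on a
fixed single-threaded platform.

## Label-map preparation

Training label maps for real data are built by splicing manual brain labels
with pseudo-labels over the non-brain content:

1. **Non-uniformity correction** divides out a smooth multiplicative field
   estimated as a low-order (default quadratic) 3D polynomial fit to
   log-intensity over nonzero voxels. This is an in-repo polynomial model,
   not a full MRI inhomogeneity pipeline; it exists to balance the intensity
   distribution before clustering.
2. **A 6-component 1-D Gaussian mixture** is fitted by EM to the intensities
   outside the brain mask, with seeded k-means++ initialization, a variance
   floor, and a per-iteration log-likelihood trace asserted non-decreasing.
   The components carry no anatomical meaning, so they are canonicalized by
   ascending mean; hard assignments take the max-responsibility component
   with ties to the lowest index. The fit covers *all* non-brain voxels,
   including zero-valued background — whether background should be excluded
   is not specified by the source framework, and including it is recorded
   here as the package's choice (background then typically claims the
   lowest-mean component, which is itself useful synthesis variety).
3. **Splicing** keeps manual labels inside the brain mask and writes offset
   GMM component ids (role `nonbrain`) outside, recording per-voxel
   provenance.

## Evaluation

`conform()` resamples volumes to a canonical cubic grid (default 256³ at
1 mm³, LIA orientation) — trilinear for intensities, nearest-neighbor for
label maps and masks, a deliberate deviation from blanket linear
interpolation since interpolating integer labels is ill-defined.
`dice_metric()` is the volumetric overlap; `hausdorff_metric()` measures
boundary-to-boundary distances in world mm between boundary voxel centers
and reports either the classical maximum or a percentile variant (95th by
convention) — which variant the source reports is unstated, so both are
exposed. `error_map()` averages voxelwise disagreement across a cohort on a
shared conformed grid; nonlinear mid-space registration is out of scope, so
cohort error maps assume pre-aligned (conformed) masks.

## The phantom module

Phantoms stand in for manually labeled training data so the whole pipeline
is testable without downloads. Geometry is a superellipsoid head with nested
scalp, skull, and extracerebral-CSF shells around a brain subdivided into
white matter, cortical gray, deep gray, ventricles, cerebellum, and
brainstem; a smooth seeded radial perturbation (`shape_jitter`) makes the
shapes non-convex enough to exercise the closing and hole-filling stages.
Default grid 64³ at 1 mm; the desk preset (`desk_phantom_spec()`) is 48³
with proportionally thinner shells so a full train/evaluate loop runs on a
single CPU core. Phantom images assign fixed per-label means — T2-like
contrast inverts the gray/white ordering, mirroring the infant contrast
flip — plus unclamped Gaussian noise (unclamped so per-label sample means
remain unbiased in tests).

What the phantoms do *not* emulate: cortical folding (the jitter is
low-frequency, not gyral), motion and ghosting artifacts, partial-volume
boundaries, multi-subject anatomical variability, or shoulders/chest in the
field of view. Passing the desk-scale end-to-end test therefore shows the
*pipeline* (synthesis → targets → optimization → inference) converges and
generalizes across phantom perturbations and contrasts; it does not certify
accuracy on clinical data, for which full-scale label maps and 256³
training are required (supported, but outside the test surface).

## Problem sizes and numerical choices

The test suite and acceptance script run deliberately reduced sizes chosen
as the package's desk-scale working point: phantoms at 48³ (oracle checks on
8³–32³ grids), 3-level base-8 U-Nets (~100k parameters), up to 600
optimization steps with validation every 25. Oracle comparisons are
bit-exact for morphology and metrics, half-voxel for the distance transform
(the implementation is exact; the bound is the acceptance tolerance).

Degenerate inputs are refused loudly: all-foreground or all-background masks
for the SDT, empty masks for the Hausdorff distance, role tables without
brain labels, GMM fits with fewer distinct intensities than components,
grids not divisible by the pooling factor (the error names the level), and
SDT losses whose weights sum to zero (`b = 0` with an empty band). The
morphological closing pads the volume by `iterations + 1` voxels so it
behaves as on an unbounded domain — without padding, a dilation clipped at
the volume border erodes back too far, and on grids smaller than twice the
iteration count the closing can swallow the whole field of view. Boundary
detection for distances treats the grid edge as non-boundary unless an
in-grid background neighbor exists.

## Known limitations

- Desk-scale accuracy numbers are phantom-level, not clinical benchmarks.
- At the desk-scale step budget (at most 600 batch-1 updates), held-out
  phantom Dice at the selected checkpoint varies noticeably with the
  training seed (the test suite and acceptance script compute values in the
  high 0.8s to low 0.9s). A control experiment overfitting one fixed image
  reaches Dice > 0.95 within ~100 steps, so the spread reflects the short
  optimization budget under per-step appearance randomization — the
  published full-scale setting trains orders of magnitude longer — not a
  capacity or correctness limit of the implementation.
- The nonlinear warp uses smoothed control-point displacements and does not
  guarantee invertibility (none is claimed by the source framework either).
- The GMM is univariate per image; multi-image joint fits are out of scope.
- Training is single-threaded CPU; full-scale 256³ seven-level training is
  supported by the code paths but impractical without substantial compute.
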