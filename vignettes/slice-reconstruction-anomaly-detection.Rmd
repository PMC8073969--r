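---
title: "Unsupervised anomaly detection by adjacent-slice reconstruction"
author: "madgan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised anomaly detection by adjacent-slice reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Most neuroimaging pathology is rare, heterogeneous and expensive to label,
so supervised lesion classifiers are hard to train at scale. The approach
implemented here sidesteps labels entirely by exploiting one property of
healthy anatomy: its strong spatial consistency. A brain that is healthy on
slice $s_j$ through $s_{j+2}$ is highly predictable on slices $s_{j+3}$
through $s_{j+5}$. A model trained to continue healthy anatomy will keep
predicting *healthy* continuations when shown a diseased brain — and the
mismatch between prediction and reality becomes the anomaly signal.

**Step 1 — reconstruction.** An image-to-image GAN learns the map

$$(s_j, s_{j+1}, s_{j+2}) \mapsto (s_{j+3}, s_{j+4}, s_{j+5})$$

over all sliding triplets of axial slice stacks from healthy scans only
(a scan with $n$ slices contributes all $n-5$ setups; 35 for a 40-slice
scan). The three slices of a triplet are concatenated channel-wise like
the colour channels of an RGB image. The generator objective combines a
Wasserstein adversarial term (critic trained with gradient penalty,
weight $\lambda_{gp} = 10$) with a heavily weighted reconstruction term:

$$\mathcal{L}_G = -\mathbb{E}[C(G(x))] + 100 \cdot \ell_1, \qquad
  \ell_1 = \sum_{i=1}^{P} |x_i - x'_i|$$

where $P$ runs over every pixel of the 3-channel target. The $\ell_1$
term keeps reconstructions faithful for data near the training
distribution; the adversarial term keeps them anatomically crisp. Both
losses are *pixel sums*, not means — the weight 100 is defined against
the pixel-sum $\ell_1$, and changing the reduction would silently change
the balance of the objective. Batches aggregate per-sample sums by the
mean.

**Step 2 — diagnosis.** For an unseen scan, every triplet is
reconstructed with the generator in deterministic evaluation mode and
scored with

$$\ell_2 = \sum_{i=1}^{P} (x_i - x'_i)^2 ,$$

whose squared differences blow up on outliers — exactly the behaviour
wanted from an anomaly score. The scan-level score is the mean $\ell_2$
over all triplet sets (`whole` mode) or the maximum mean over any 10
consecutive sets (`top10` mode, which localises focal disease; ties break
toward the earliest window). Healthy/abnormal separation is summarised by
the ROC and its AUC, computed as the Mann–Whitney probability of
concordance with half-credit for ties — exact, threshold-free, and equal
to trapezoidal ROC integration.

Because interior slices belong to up to three overlapping target
triplets, the per-scan mean weights them accordingly. This follows
directly from the set enumeration; a per-pixel-normalised variant
(`mean_l2_per_pixel`) is reported alongside for cross-resolution
comparability.

## Architecture

The generator is U-Net-like: 4×4 strided convolutions down (batch norm +
leaky ReLU, no norm on the first layer), 4×4 stride-2 transposed
convolutions up (batch norm + ReLU) with skip connections, two dropout
layers (rate 0.5) in the two deepest decoder blocks, and a final linear
layer clamped to $[0,1]$. A sigmoid output was rejected deliberately:
most of a slice is background at exactly 0, where a sigmoid saturates
and starves gradients; the clamped linear map is identity-like in the
active range. At full scale the network has `depth = 4` encoder and
decoder levels on a 176×256 canvas.

The critic is a strided-convolution encoder (leaky ReLU, configurable 3
or 4 levels) with a final linear projection to one unbounded real score.
It uses **no normalisation layers**: the gradient penalty constrains the
critic's gradient per sample, and batch normalisation would couple
samples inside the penalty. The critic depth is configurable because the
published description of the discriminator is ambiguous; 3 levels is the
desk default, 4 the full-scale one.

**Self-attention.** The none/3/7-module variants insert SAGAN-style
self-attention blocks: 1×1 query/key projections at $C/8$ channels, a
value projection at $C/2$, softmax attention over all spatial positions
(a row-stochastic $P \times P$ matrix), and a learnable scalar gate
$\gamma$ initialised at 0 so insertion never perturbs a working network.
The exact insertion points are not fully specified in the published architecture diagram,
so the package places the 3-module variant after the deepest encoder
level, on the bottleneck, and after the deepest decoder level, and the
7-module variant adds the two next-larger feature-map scales on both
sides — following the published advice that attention helps most on
large feature maps while keeping the $P \times P$ matrix tractable.
Placements are overridable via `model_spec(sa_sites = ...)`.

## Training schedule

Adam (learning rate $2 \times 10^{-4}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$) updates critic then generator once per step; the
full-scale schedule is batch 16 for $1.8 \times 10^6$ steps. "Label
flipping once in three times" has no literal labels under a Wasserstein
critic, so it is realised as exchanging the real and reconstructed
batches' roles in the critic loss on every third step — a deterministic
schedule (exactly one third of steps) chosen over a Bernoulli(1/3) draw
for reproducibility; the stochastic variant sits behind
`train_control(flip_stochastic = TRUE)`. The step counter counts one
critic-plus-generator cycle.

Everything that needs gradients is implemented in the package:
convolution and transposed convolution (im2col + BLAS), batch norm,
attention, and — the delicate part — the gradient penalty's parameter
gradient. For a piecewise-linear critic the input gradient is a chain of
transposed convolutions through frozen activation masks; freezing the
masks makes that chain explicitly differentiable, and a second forward
pass through it yields the penalty's exact parameter gradients almost
everywhere. All backward passes are verified against central finite
differences in the test suite.

## The phantom generator

Real scans are optional everywhere: a parametric phantom supplies
volumes with precisely the statistical structure the method assumes.
Each healthy phantom renders nested smooth closed regions (ellipses
perturbed by order-2..4 angular harmonics): mid-grey outer tissue, a
brighter inner band, and a dark innermost cavity standing in for the
ventricles. Along the slice axis the geometry follows a deterministic
quadratic size profile plus a bounded random walk, with per-slice change
capped by `drift` (default 0.02 of the region radius) — so adjacent
slices correlate more than distant ones, the anatomy-continuation signal
the model learns. Gaussian noise (`noise_sd = 0.02`) approximates
acquisition noise. At `drift = 0, noise_sd = 0` all slices are
identical.

Two injectors create the two pathology archetypes the method targets:

* **atrophy** re-renders the cavity enlarged by `magnitude` (default
  0.4), tapered over a contiguous run covering ~70% of slices — a
  diffuse deformation, like ventricular enlargement in dementia;
* **hyperintense lesions** stamp `count` (default 3) compactly-supported
  Gaussian blobs of peak `magnitude` (default 0.5) above background,
  radius 3–6 px at the 64×64 desk canvas, over a contiguous slice run
  whose intensity profile waxes and wanes — like enhancing metastases on
  contrast MRI.

The lesion profile is Gaussian rather than a hard disk so detection
cannot ride on a trivial edge artefact. What the phantom deliberately
does *not* model: MRI physics (no sequence contrast, bias fields or
partial-volume effects), real anatomical variability, and registration
error. Passing desk-scale tests therefore demonstrates that the
*mechanism* — healthy-trained reconstruction error separating anomalous
scans — works end-to-end; it does not certify clinical performance,
which in the original experiments required over a thousand real scans and
$1.8 \times 10^6$ training steps.

## Numerical and design choices

* **Intensity normalisation** (unstated in the original method description): per-scan linear
  scaling mapping the 99.5th percentile to 1, then clamping. Per-scan
  (not per-slice) scaling preserves the inter-slice brightness gradients
  the model must learn; the percentile guards against hot pixels. A fixed
  external `scale` supports joint normalisation of pooled multi-sequence
  cohorts; per-scan is the default.
* **Canvas mapping**: a slice whose rows match the canvas and whose
  columns fall short is zero-padded symmetrically (176×240 → 176×256
  adds 8 columns per side — symmetric to avoid a lateral anatomy shift);
  anything else is resampled bilinearly with half-pixel centres
  (`align_corners` off), under which constant images are preserved.
* **Slice selection**: the anatomical criterion (mid-brain slices
  showing hippocampus/amygdala/ventricles) is replaced by an explicit
  index range, `select_slice_range()` — automated structure detection is
  out of scope and the criterion only restricts what enters the
  pipeline.
* **Indices** are 1-based in every user-facing report (`start_index`,
  `top10_start`), matching the $s_1 \dots s_n$ convention.
* **Adam betas** (0.5, 0.999) follow image-to-image GAN practice;
  `n_critic = 1` matches a single published step counter. Both are
  configurable.
* **Interpolation draws** for the penalty use one $\epsilon \sim U(0,1)$
  per sample, shared across that sample's pixels.
* **Seeds**: one global seed fans out to per-stage seeds through a
  deterministic hash (`derive_seed`), so stages are independently
  reproducible; identical config + seed reproduces cohorts, training
  trajectories and AUC tables bit-for-bit on the same BLAS.
* **Degenerate inputs**: scans shorter than 6 slices, empty score lists,
  single-class ROC inputs and non-healthy training scans raise classed
  validation errors; an all-zero scan normalises to itself with a
  warning; fewer than 10 sets makes `top10` fall back to `whole` with a
  note.

## Desk-scale problem sizes

The package's own experiments run on a 64×64 canvas with 30-slice
phantoms: 30 healthy scans (20 train / 10 held out) plus 15 scans per
anomaly class, a no-attention generator with `base_channels = 4`,
`depth = 3`, critic depth 3, trained 2,000 steps at batch 8 with the
standard learning rate $2 \times 10^{-4}$. These sizes were chosen once
as the smallest configuration that exercises every mechanism (skip
connections, batch norm, penalty, flip schedule) while training in
minutes on a single CPU core. The overfit-one-scan check uses a 32×32,
12-slice phantom and learning rate $10^{-3}$ — appropriate for a tiny
batch-4 problem where the full-scale rate is needlessly conservative —
and drives per-pixel $\ell_1$ below 0.02 within 500 steps.

Representative desk-scale output (seed 1, recomputed by
`scripts/acceptance.R`): held-out healthy scans score a mean whole-scan
$\ell_2$ well below lesion- and atrophy-injected scans, giving
AUC $\approx$ 0.99 for lesions and $\approx$ 1.0 for atrophy. Numbers of
this kind are regenerated, never stored: every figure the package
reports is recomputed from config + seed.

## Known limitations

* The published critic description ("a discriminator with 3
  decoders") is not implementable literally; the package uses a standard
  WGAN-GP critic with configurable depth and records the interpretation
  here.
* Attention placements are an informed reconstruction of an
  under-specified figure, not a verified match.
* Self-attention materialises the full $P \times P$ position matrix;
  at canvases much beyond 176×256 the largest-scale modules of the
  7-module variant become memory-bound.
* Training runs single-threaded on CPU through BLAS matrix products; the
  published 1.8M-step schedule is out of desk reach by design — the
  package targets method correctness, small-scale experiments and
  transfer of the exact objective, not GPU-scale training.
* Bit-level reproducibility holds for a fixed BLAS; across BLAS builds,
  floating-point sums may differ in the last ulps.
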