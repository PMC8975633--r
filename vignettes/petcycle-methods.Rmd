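---
title: "Attention-gated cycle-consistent translation of short-axis PET slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated cycle-consistent translation of short-axis PET slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcycle)
```

## The problem

PET image quality is tied to the scanner's photon-collection sensitivity,
which grows with the axial field of view (FOV). A total-body scanner
(~1940 mm axial coverage) produces markedly cleaner images than the
conventional short-axis devices (200–350 mm) that dominate clinical
practice. When the same acquisition is reconstructed twice — once from the
full detector range and once from a single short-axis segment — the result
is a pixel-aligned pair of a high-quality (HQ) and a low-quality (LQ) image
of identical anatomy. `petcycle` learns the LQ-to-HQ mapping from such pairs
with a cycle-consistent adversarial framework whose generators carry
convolutional block attention, and a supervised paired loss that exploits
the alignment.

## The model

Two generators translate between the LQ domain $A$ and the HQ domain $B$:
$G_{AB}: A \to B$ and $G_{BA}: B \to A$. Two patch critics $D_A$, $D_B$
judge each domain. The networks are:

* **Generator** — a 7×7 convolution to `base_channels` feature maps
  (reflection padding), an attention block, two 3×3 stride-2 down-sampling
  convolutions (batch norm + ReLU), `n_res_blocks` residual blocks at the
  bottleneck width (two 3×3 reflection-padded convolutions with batch norm;
  the rectifier follows the first convolution and the skip sum), two 3×3
  stride-2 transposed convolutions (batch norm + ReLU), a second attention
  block, a 7×7 convolution back to one channel, and a tanh squashing. That
  is six convolutions outside the residual/attention blocks, two attention
  blocks and nine residual blocks in the default configuration.
* **Critic** — four 4×4 convolution stages (C4S2-64, C4S2-128, C4S2-256,
  C4S1-512), LeakyReLU slope 0.2, batch norm from the second stage, then a
  4×4 stride-1 convolution to a one-channel raw score map. The score is not
  squashed: the adversarial term is a gradient-penalty critic objective, so
  raw scores are required.

**Attention.** Each block gates its feature map twice. Channel gates:
spatial average- and max-pooling produce two per-channel descriptors that
pass through one shared bottleneck network ($C \to C/r \to C$, rectified in
the middle, $r = 16$ by default), are summed element-wise and squashed by a
sigmoid. Spatial gates: channel-wise mean and max maps are stacked into a
two-channel descriptor and convolved with a single size-preserving kernel
(7×7 by default), then squashed. The map is multiplied by the broadcast
channel gates first, and the spatial gates are computed from the
channel-refined map — the sequential arrangement. Zeroing every attention
weight therefore yields gates of exactly 0.5 everywhere and an output of
$F/4$; this analytic point is pinned in the tests.

## The objective

$$\mathcal{L} \;=\; \mathcal{L}_{adv} + \lambda_c\,\mathcal{L}_{cyc}
 + \lambda_i\,\mathcal{L}_{id} + \lambda_s\,\mathcal{L}_{sup},
 \qquad (\lambda_c, \lambda_i, \lambda_s) = (10,\ 0.5,\ 0.5).$$

The adversarial part averages the two directions with a factor $\tfrac12$.
Each direction uses the gradient-penalty critic form: the critic minimises
$-\mathbb{E}[D(\text{real})] + \mathbb{E}[D(\text{fake})] +
\lambda\,\mathbb{E}[(\lVert\nabla_{\hat y} D(\hat y)\rVert_2 - 1)^2]$ with
$\hat y = \epsilon\,\text{real} + (1-\epsilon)\,\text{fake}$,
$\epsilon \sim U(0,1)$ per sample, and the generator minimises
$-\mathbb{E}[D(\text{fake})]$. The penalty coefficient $\lambda$ is not
fixed by the published description; the package defaults to the standard
value 10 and exposes it in `loss_weights()`. Cycle, identity and supervised
terms are per-pixel mean L1 norms — the mean (not the sum) keeps loss
magnitudes comparable across resolutions.

Three numerical choices deserve comment:

* **Normalisation in the critic vs the penalty.** Per-sample input
  gradients are ill-defined under batch statistics, because samples
  interact through the normalisation. The penalty term therefore freezes
  the critic's batch-norm statistics at their current batch values, making
  the penalised critic piecewise-affine in its input. The penalty value and
  its parameter gradient are then computed exactly for that function by a
  tangent (forward-over-reverse) pass; LeakyReLU has zero second derivative
  almost everywhere, so no approximation is involved away from the kinks.
  The tests confirm the parameter gradients against central finite
  differences of the frozen objective.
* **L1 at zero.** The subgradient `sign(0) = 0` is used; exact ties have
  measure zero under the simulator.
* **Degenerate penalty point.** If a per-sample gradient norm is exactly
  zero (an all-zero critic), the chain-rule coefficient is set to zero;
  the penalty value is still 1 per sample.

## Optimisation

Adam with $\beta_1 = 0.5$, $\beta_2 = 0.999$; learning rate $2\times10^{-4}$
for the first half of training, then a linear decay reaching zero at the
final epoch boundary (`lr_schedule()`); default 200 epochs and batch size
32. Critic and generators alternate strictly (`n_critic = 1` by default).
Both generators are updated jointly on the combined objective — gradient
flows through both cycle directions, the identity branches and the
supervised terms in a single accumulation. Batch norm uses batch statistics
during training and stored running statistics (momentum 0.1) at inference,
so inference is deterministic. Every random draw — weight initialisation,
batch shuffling, interpolation weights — derives from `train_config()$seed`,
and identical seeds reproduce loss histories bit for bit.

There is no replay pool of historical fakes: the critics always see the
current generator's output. The published training description does not
mention one, and at the scales exercised here strict alternation was
stable.

## The synthetic paired-phantom generator

Real paired short-axis/total-body data is access-restricted, so the package
ships a simulator that reproduces the *structure* of such data rather than
its anatomy:

* The HQ slice is a noise-free activity map: a constant background, a few
  elliptical "organs" with uniform random centres, semi-axes (between a
  tenth and roughly a third of the grid), orientations, and activities, plus
  small discs at `lesion_contrast` times the local activity — the
  high-uptake structures whose texture the translation must preserve.
  Overlapping organs are allowed, as projections of real organs overlap.
* The LQ member is derived from its own HQ slice (pixel alignment by
  construction): a Gaussian point-spread blur (`psf_sigma_lq`, default 1 px)
  models resolution loss; a scaled Poisson draw,
  $\text{Pois}(s\,c\,\text{blur}(x))/(s\,c)$, models count-limited
  acquisition, with the effective sensitivity $s \in (0, 1]$ standing in
  for the axial FOV (noise variance scales as $1/s$); additive Gaussian
  noise (sd 0.01) models the electronics. `count_scale` defaults to 50
  expected counts per unit activity at unit sensitivity, which at organ
  activities near one and $s = 0.15$ gives a relative noise level in the
  tens of percent — a visibly degraded image, comparable in spirit to a
  short-axis acquisition of a fast scan.

The mapping between sensitivity and a physical FOV in millimetres is
illustrative only; the simulator's contract is monotonicity (held-out mean
squared error rises strictly as $s$ drops, tested at 1.0, 0.3, 0.1), not
calibration to any scanner. What passing tests on phantoms shows is that
the pipeline — normalisation, networks, objective, optimisation, metrics —
functions and improves structured images corrupted by count-limited noise;
it does not show clinical image quality, anatomical realism, or robustness
to scanner-specific artefacts, none of which the phantoms contain.

Intensities are scaled to $[-1, 1]$ for training. The bounds are the
per-pair minimum and maximum of the HQ member, shared by its LQ member so
the pair sits on one scale, and recorded so denormalisation is exact.
Whether the original processing normalised per slice, per volume or per
dataset is not stated in the published description; per-pair/per-volume is
the implemented choice, logged into the dataset manifest.

## Metrics

`nrmse()`, `psnr()` and `ssim()` are computed on physical-scale
(denormalised) intensities, since both the peak intensity and the reference
energy are scale-dependent. NRMSE includes the printed ×100 factor; note
that published tables in this problem area often report the unscaled ratio
(values around 0.2–0.3), so `metric_config(nrmse_percent = FALSE)` exposes
that variant. PSNR uses the peak of the reference image by default; a fixed
dynamic range is available. SSIM uses the reference settings — 11×11
Gaussian window, $\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$, dynamic range
$\max - \min$ of the reference — averaged over valid window centres; the
window shape and size were not specified in the published description, so
both Gaussian and uniform windows are available. All three metrics are
validated against independent double-loop oracles, and
$\text{SSIM}(x, x) = 1$ is pinned to $10^{-9}$.

## Desk-scale problem sizes

The published study trained on tens of thousands of 150×150 slice pairs
for 200 epochs on GPUs; that regime is out of scope here. The package's
test suite exercises the full pipeline at sizes chosen for a single CPU:
32×32 phantoms, a reduced generator (`base_channels = 8`,
`n_res_blocks = 2`) and critic ladder (8–64), 54 training pairs at
sensitivity 0.15, batch size 8, 40 epochs, evaluated on 20 held-out pairs.
At these sizes training takes a few minutes per seed and the learned
mapping reliably lifts held-out mean SSIM above that of the raw LQ input;
the improvement property is asserted over three fixed seeds with a
two-of-three majority, since adversarial training at toy scale retains
some run-to-run variance. The same property at full scale is a claim the
desk-scale test supports but cannot prove.

## Known limitations

* 2D slice-wise processing only; no volumetric context across slices.
* The simulator has no anatomy, no attenuation or scatter physics, and no
  reconstruction (OSEM/TOF) modelling; sensitivity is a single monotone
  knob.
* The engine is vectorized base R; it is intended for desk-scale
  experiments and validation, not for the full published training regime.
* Radiologist-score evaluation (a 1–5 overall-impression/noise/lesion
  scale used in the original study) is documented but not implemented;
  only the quantitative triad is computed.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- make_dataset(phantom_spec(grid_size = 32, seed = 11),
                   degradation_spec(sensitivity = 0.15, seed = 12),
                   n_pairs = 60, split_seed = 13)
norm <- lapply(ds$train, function(p) normalize_pair(p)$pair)
model <- train_cycleagan(
  norm,
  train_config(epochs = 40, batch_size = 8, seed = 1),
  loss_weights(),
  generator_config(base_channels = 8, n_res_blocks = 2),
  discriminator_config(channel_ladder = c(8, 16, 32, 64)))
ev <- evaluate_translation(model, ds$test)
ev$before$summary   # LQ vs HQ
ev$after$summary    # translated vs HQ
```
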