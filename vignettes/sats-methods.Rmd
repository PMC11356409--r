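---
title: "Teacher-student polyp segmentation without target labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Teacher-student polyp segmentation without target labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sats)
```

## The problem

Polyp segmentation models trained on public endoscopy datasets degrade on
images from a new clinic: color balance, illumination, texture and artifacts
(for instance green or blue specular spots from different light sources)
shift the image distribution, and the new data typically has no pixel
annotations to fine-tune on. `sats` implements a self-adaptive
teacher-student protocol for exactly this setting: `k` annotated source
datasets, one unannotated target dataset.

The protocol has two phases:

1. **Teachers.** One segmentation network (GANet, below) is trained per
   source dataset on a 90/10 train/validation split, keeping the checkpoint
   with the best validation Dice. One reconstruction autoencoder is also
   pre-trained per source dataset on images alone, by minimizing mean
   squared reconstruction error.
2. **Student.** Every target image is segmented by all `k` teachers; the
   predictions are fused into a single soft pseudo-label by UDFusion
   (below); a fresh GANet — the student — is trained on these pseudo-labels.
   Target ground truth is never read during either phase (the package
   enforces this with a logged accessor around held-out labels).

## UDFusion: weighting teachers by distance and uncertainty

Teacher `i`'s prediction $\hat y^i(p,q)$ contributes to the fused
pseudo-label with a per-pixel weight that averages two signals:

$$\hat Y(p,q) = \sum_{i=1}^{k} \frac{u^i + v^i(p,q)}{2}\,\hat y^i(p,q)$$

* The **distribution weight** $u^i = \mathrm{softmax}_i(-D^i)$, where
  $D^i$ is the mean squared residual of the target image under source
  domain $i$'s autoencoder. An autoencoder reconstructs images from its own
  training distribution better than foreign ones, so a small $D^i$ means
  "this target image looks like source $i$", and that teacher is trusted
  more — for the whole image. $u$ is computed per target image, because the
  distances are functions of the individual image.
* The **uncertainty weight** $v^i(p,q) = \mathrm{softmax}_i(-U^i(p,q))$,
  with $U^i = -\hat y^i \log \hat y^i$ the per-pixel prediction entropy
  term. A confident teacher (prediction near 0 or 1) is trusted more — at
  that pixel.

Both weight families lie on the probability simplex, so the fusion is a
convex combination and $\hat Y$ stays within the range of the teacher
predictions. Three ablation modes replace the weights: `mean` ($w_i = 1/k$),
`distance_only` ($w_i = u_i$), `uncertainty_only` ($w_i = v_i$); a fourth
baseline trains a single teacher on all sources pooled
(`train_merged_baseline()`).

Two reading notes on the uncertainty term. First, the single-term entropy
$-y\log y$ is maximal at $y = e^{-1}$, not at $y = 0.5$; the two-term binary
entropy (maximal at 0.5) is available via `binary_entropy = TRUE` in
`generate_pseudo_labels()`, but the single-term form is the default.
Second, the logarithm is natural and stabilized as $\log(y + 10^{-8})$, so
$U(0) = 0$ holds in the limit.

## GANet: identify, then refine

The segmentation backbone mirrors how an endoscopist works: find the lesion
coarsely, then sharpen the boundary.

* **Encoder**: `D` residual blocks with stride-2 downsampling; channel
  width doubles per level (`base_channels` at the finest). Convolutions are
  bias-free and followed by instance normalization — per-sample, per-channel
  — so forward passes are deterministic and independent of batch
  composition; a convolution bias before normalization would be cancelled by
  the mean subtraction and receive no gradient.
* **Identify block** (deepest level): channel self-attention (a
  $c \times c$ row-stochastic attention over channel similarity) followed by
  spatial self-attention, then a $1{\times}1$ convolution + sigmoid
  producing the initial coarse mask $P_{ini}$.
* **Refine blocks** (one per remaining level, coarse to fine): with
  $P_{d+1}$ the previous mask and $O_{d+1}$ the previous features (both
  bilinearly upsampled $\times 2$, features channel-aligned by a
  $1{\times}1$ convolution), the block computes overall attention
  $z_d \leftarrow \mathrm{Attn}(z_d)$, foreground attention on the gated
  features $\mathrm{Attn}(P_{d+1} \odot z_d)$, background attention on the
  complement $\mathrm{Attn}((1-P_{d+1}) \odot z_d)$, and corrects

  $$z'_d = O_{d+1} - \gamma_1 z^{fg}_d + \gamma_2 z^{bg}_d,$$

  subtracting falsely-foreground features and restoring falsely-background
  ones. $\gamma_1, \gamma_2$ are learnable scalars initialized at 1 (the
  update rule gives no values and does not forbid learning them; the
  degenerate contract $\gamma_1 = \gamma_2 = 0 \Rightarrow z'_d = O_{d+1}$
  is kept exactly and unit-tested). A $1{\times}1$ convolution + sigmoid
  yields this level's finer mask.

Design points where the architecture description underdetermines the code,
resolved as follows:

* Spatial attention scores are computed **between spatial positions** — a
  $(wh) \times (wh)$ row-stochastic matrix from $Q^\top K / \sqrt c$ with
  $Q, K \in \mathbb{R}^{c \times wh}$ — not between channels; this is the
  only reading under which spatial attention is permutation-equivariant
  over positions, which the test suite checks.
* Masks gate features **softly** (no binarization inside the network): hard
  thresholds would kill gradients.
* Attention is single-head with no positional encoding; the overall,
  foreground and background branches have separate parameters.
* Every decoder level is supervised, including the identify block's
  $P_{ini}$ at the coarsest level.

## The multi-scale Tversky loss

Each level's mask $P_d$ is scored against the label bilinearly downsampled
to its size, with the Tversky loss
$1 - (TP + s) / (TP + \alpha FP + \beta FN + s)$ on soft counts, and the
levels are combined as $\sum_d \lambda_d L_d$. The level coefficients follow
$\lambda = 2^{\,i}$ over decoder order $i$ (identify block $i = 0$), so the
finest prediction — the one closest to the final output — carries the
largest weight; `constant`, `linear` ($\lambda = i$) and `pow3` schemes are
available for the coefficient sweep. The indexing deserves one sentence: the
prediction pyramid stores masks finest-first while coefficients grow with
decoder depth, and the package resolves this by always giving the finest
level the largest coefficient, which is the stated intent of the scheme.

Defaults: $\alpha = 0.3$, $\beta = 0.7$ (penalizing missed lesion pixels
harder, the usual choice for small-lesion sensitivity; the reference recipe
does not print its values), $s = 10^{-6}$ to guard empty masks. When the
target is a soft fused pseudo-label the same soft-count formulas apply
unchanged — binarizing the pseudo-label would discard the fusion weights,
so the student trains directly against $\hat Y \in [0,1]$.

## Synthetic benchmark

Real multi-clinic polyp data cannot ship with a package, so `sats`
generates its own study conditions. Each domain style fixes a base hue
(49° apart per domain id), illumination gain (steps of 0.22), texture
frequency, specular-spot color/rate, and noise level; any two distinct
domains differ by at least 10° of hue or 0.2 of gain, which is the margin
the autoencoder separation relies on. An image is a mucosa-like background
(vignette illumination, oriented sinusoidal texture) containing one
polyp — a rotated ellipse with low-frequency sinusoidal boundary
perturbation, hue-shifted +45° and brightened, with its own finer texture —
plus Poisson specular spots and Gaussian noise. Masks are single
4-connected components covering 2.5–38% of the image by construction.

The target domain's style is a convex combination of the source styles with
one dominant source at weight 0.75 plus a small perturbation, and its
bright spots are green/blue (absent from sources). The dominant index is
recorded in the benchmark metadata as `nearest_source`; it is the ground
truth for checking that the distribution weights select the right teacher.
The 0.75 weight keeps the target's hue unambiguously closest to one source
(circular hue mixing with a weaker dominant source can land nearly
equidistant between two sources, which would make "nearest" ill-defined).

What the generator does **not** emulate: instruments, folds, fluids,
motion blur, resolution differences, and multiple or zero polyps per image.
Passing tests on this benchmark show that the pipeline's machinery —
domain-distance weighting, fusion selectivity, pseudo-label training — works
when the domain shift is real but low-dimensional; they do not certify
performance on clinical images.

## Scaled-down study conditions

The test suite and the acceptance script exercise the full pipeline at desk
scale: 3 source domains x 60 images at 64x64, `D = 3`, `base_channels = 8`,
20 epochs, batch size 4, Adam at the reference recipe's learning rate 2e-4
with decay rates 0.9/0.999, 90/10 split. At this scale each teacher reaches
validation Dice well above 0.6 on the synthetic benchmark and the student
clears Dice 0.5 on held-out target labels. Unit tests use miniature
configurations (32x32, `D = 2`, 2-3 epochs) that exercise the code paths
without training to convergence.

## Numerical choices

* Softmax rows are computed with per-row max subtraction (exact, stable for
  arbitrary finite scores); the row-stochastic property is tested to 1e-6.
* Bilinear resampling uses half-pixel centers with clamped coordinates;
  weights are convex, so upsampled masks stay in $[0,1]$. A 4x4
  checkerboard downsampled to 2x2 gives exactly 0.5 everywhere (the test
  fixture's closed form).
* Gradients come from a small reverse-mode autodiff engine over R matrices
  (tape of closures; BLAS matmuls; two C++ kernels for row softmax). Its
  correctness is established by finite-difference checks through the entire
  network (relative error ~1e-8) and a gradient-reaches-every-parameter
  test.
* Training is deterministic given the configuration seed: every stage
  derives its own RNG stream; instance norm has no batch statistics; all
  reductions are sequential.
* Evaluation binarizes at 0.5. HD is the full Hausdorff distance (not the
  95th percentile). An empty predicted or true mask has no boundary; HD/MSD
  then fall back to the image diagonal and the event is counted in the
  report rather than silently scored.

## Known limitations

* The autoencoder distance is a proxy for distribution distance; it mostly
  tracks low-order color/illumination statistics. Domain shifts that
  preserve color statistics (e.g. geometric distortions) would not be
  detected.
* Pseudo-labels are generated once; there is no iterative self-training
  refresh.
* The attention decoder is quadratic in the number of spatial positions at
  each level, which bounds practical image sizes on CPU.
* With few source domains the fused pseudo-label can inherit correlated
  teacher errors; the uncertainty weight cannot correct a confidently wrong
  consensus.
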