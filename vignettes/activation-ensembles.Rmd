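---
title: "Learnable activations and stochastic activation-replacement ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learnable activations and stochastic activation-replacement ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activens)
```

## The problem and the approach

Convolutional networks trained on small biomedical image collections
(hundreds to a few thousand images) overfit badly. Two related remedies
motivate this package. First, replacing the fixed ReLU nonlinearity with
a richer, possibly *learnable* activation function changes what a network
of fixed topology can represent, at a negligible parameter cost. Second,
because no single activation wins consistently, ensembles of networks
that differ only in their activations — in particular networks whose
activation sites are *randomly* assigned functions from a pool — combine
by the sum rule into classifiers that reliably beat every stand-alone
member. `activens` implements the activation catalogue with exact
gradients, the replacement machinery, the training protocol, the fusion
and selection tools, and the statistics used to compare methods.

## The Mexican-hat family and its fixed ladders

The core of the catalogue is the Mexican ReLU (MeLU) family. A *Mexican
hat* is the triangular bump

$$\varphi_{a,\lambda}(x) = \max(\lambda - |x - a|,\, 0),$$

peaking at $x = a$ with value $\lambda$ and supported on
$[a-\lambda, a+\lambda]$. MeLU adds $k-1$ such bumps, each with a
per-channel learnable coefficient, to a PReLU backbone:

$$\mathrm{MeLU}(x) = \mathrm{PReLU}_{c_0}(x)
  + \sum_{j=1}^{k-1} c_j\, \varphi_{a_j, \lambda_j}(x).$$

The $(a_j, \lambda_j)$ are **fixed**, generated breadth-first by dyadic
subdivision of $[0, 4M]$ where $M$ is `max_input` (the assumed input
scale): the first hat peaks at $2M$ and vanishes at $0$ and $4M$; the
next two have half the half-width and peak at $M$ and $3M$; the next
level halves again. `build_melu_ladder(256, 8)` therefore yields centers
512, 256, 768, 128, 384, 640, 896 with half-widths 512, 256, 256, 128,
128, 128, 128 — and ladders scale linearly in `max_input`, so the unit
ladder is the same table divided by 256. Because a hat basis restricted
to a compact interval is dense in $L^2$, MeLU approximates any continuous
function there as $k$ grows, while `c = 0` makes it *exactly* ReLU — the
property that lets it replace pretrained ReLU layers without disturbing
the network at initialization.

GaLU replaces the bump by the zero-mean "Gaussian-type" hat
$\varphi g_{a,\lambda}(x) = \max(\lambda - |x-a|, 0) +
\min(|x - a - 2\lambda| - \lambda, 0)$ (an up-triangle followed by an
equal down-triangle, supported on $[a-\lambda, a+3\lambda]$). Its ladder
is derived from the MeLU ladder by halving each half-width and shifting
each center left by the new half-width (`derive_galu_ladder()`), which
reproduces the published unit-scale GaLU table exactly. The derivation
rule is taken from that table itself; the accompanying prose ("the same
set of fixed parameters") contradicts the printed values, and the table
is treated as ground truth.

The family's variants follow the same pattern: **Symmetric MeLU/GaLU**
evaluate the function at $x$ and $-x$ with shared coefficients (even by
construction, $|x|$ at initialization); **MeLU+GaLU** mixes the two
bases with a learnable per-channel weight $a$,
$f = \mathrm{PReLU}_{c_0}(x) + \sum_j c_j[(1-a)\varphi_j + a\,\varphi
g_j]$ — the formulas leave open whether the two halves share
coefficients, and sharing is chosen here so the function is exactly ReLU
at initialization; **Flexible MeLU** makes the centers $a_j$ learnable
(initialized at the ladder); **2D MeLU** acts on cyclic channel pairs
$(x_i, x_{i+1})$ with a $(k-1)^2$ coefficient grid over the 1D ladder,
Euclidean distance in the hat, and half-width $\lambda_{\max(u,v)}$ —
the norm, the pairing of the last channel, and $k$ (default 4 here) are
all conventions, since the defining equation fixes none of them.

## The rest of the catalogue

Fixed kinds follow their standard definitions: Leaky ReLU (slope 0.01),
ELU ($a = 1$), SELU (standard constants $\lambda \approx 1.0507$,
$\alpha \approx 1.6733$), Swish $x\,\sigma(\beta x)$ with $\beta = 1$
fixed or learnable, Mish $x \tanh(\mathrm{softplus}(\alpha x))$ with
$\alpha = 1$ fixed or learnable, PDELU with deformation $t = 0.9$ and
per-channel $\alpha$ initialized to 0 (ReLU-compatible), TanELU
$\mathrm{ReLU}(x) + a \tanh(x)$ with $a = 0$ at start, SRS
$x/(x/\alpha + e^{-x/\beta})$ with $\alpha = 3$, $\beta = 2$ at start
and both clamped at $10^{-6}$ after each update, and SReLU with its
four per-channel parameters.

Three places required a reading decision:

* **APLU.** The printed forward form uses
  $a_c \min(0, -x + b_c)$ (active for $x > b_c$) while the printed
  gradients branch on $x < b_c$. Only the original APLU form
  $a_c \max(0, -x + b_c)$ — hinges active *below* their location — is
  consistent with those gradients, and that form is implemented; the
  forward/backward pair passes the finite-difference audit.
* **Soft Learnable.** The printed negative branch is ambiguous between
  $\alpha \ln(1 + e^{\beta x/2})$ and $\alpha \ln((1+e^{\beta x})/2)$;
  only the latter is continuous at 0 and is used. `soft_learnable`
  fixes $\beta = 1$; `soft_learnable2` learns it.
* **SReLU initialization.** The source text states both
  $(a_l, a_r, t_l, t_r) = (0.5, 0.2, -2, 1.5)$ and "initialized as
  $a_l = 0, t_l = 0, t_r = \mathrm{maxInput}$". The former is the
  default (`preset = "operational"`); the latter is available as
  `preset = "reference"`, with $a_r = 1$ chosen so the function starts
  ReLU-like (the text does not give $a_r$).

**Gradients.** Every kind implements `grad_activation()`, returning the
input gradient and the gradient of every learnable parameter under an
arbitrary upstream weighting — i.e. exactly the backward pass a training
loop needs. At non-differentiable points the right-hand branch is used
(so the ReLU-family derivative at 0 is 1, matching the printed
$x \ge 0$ branches). The test suite audits all 25 kinds against central
finite differences ($h = 10^{-6}\max(1, |x|)$, points kept $\ge 10^{-3}$
from every kink, including the support circles of 2D MeLU) at relative
tolerance $10^{-4}$; observed errors are $\sim 10^{-9}$.

## Replacement plans and the TinyNet vehicle

A `layer_graph` abstracts a CNN as ordered layers with typed roles;
activation sites carry channel counts. `sample_replacement_plan()` draws
an activation for every site uniformly from a pool — independently per
site (`per_layer`, the default) or once per network (`per_network`);
both granularities appear in the literature the package follows, so the
choice is a flag. Plans serialize to JSON for exact replay, and
`apply_plan()` instantiates per-channel parameters with seeds derived
deterministically from one master seed.

Because no pretrained backbone can be (or should be) bundled, the
canonical experimental vehicle is **TinyNet**: conv(3×3, 8) → act →
maxpool → conv(3×3, 16) → act → maxpool → FC(32) → act → softmax head,
on 32×32 grayscale images. It is small enough to train in seconds on one
CPU yet has three activation sites of realistic channel widths. The
engine (im2col convolutions, 2×2 max pooling, softmax cross-entropy) is
written in plain R with BLAS matrix products; gradients for activation
parameters flow through `grad_activation()`, so a training run exercises
every hand-derived backward formula.

## Training protocol

`train_config()` captures the benchmark protocol: batch size 30, base
learning rate $10^{-4}$, 20 epochs (30 when the plan mixes activation
kinds, mirroring the slower convergence of stochastic architectures), a
×20 learning rate on the classifier head (hence 0.002), the relative
rate $\lambda^* = \lambda/\mathrm{maxInput}$ for APLU/Splash slope
parameters, their L2 penalty $0.001\sum a_c^2$ added to the loss, and
augmentation by independent axis flips plus two independent axis
rescales with factors uniform on $[1, 2]$, resampled back to the
original raster bilinearly (the re-entry interpolation is unspecified in
the protocol; bilinear is the ecosystem default). The optimizer is SGD
with momentum 0.9 — the protocol names only LR/BS/epochs, and momentum
SGD is the standard fine-tuning default of the ecosystem it ran in.

Two desk-scale departures, both package design choices:

* `desk_train_config()` uses base rate 0.002 and no augmentation. The
  $10^{-4}$ rate is a *fine-tuning* rate for pretrained weights; from
  scratch it cannot train TinyNet in 30 epochs. 0.002 is the largest
  rate that trains every pool member type stably on the toy tasks.
* Inputs are mean-centered (the training-set mean pixel is subtracted;
  the offset is stored on the model and applied at prediction).
  Without centering, unit-range images occasionally collapse
  from-scratch SGD runs for some seeds; with it, training is uniformly
  stable. This is standard CNN preprocessing, not part of the
  activation semantics.

For the same reason the desk experiments use the stochastic pools at
`max_input = 1`: `max_input` is the assumed input scale, and the
recipes' 255 corresponds to 8-bit-range inputs of pretrained backbones,
whereas toy images are unit-range (a 255-scale APLU draws its hinges far
outside the data's support). Both scales are constructible everywhere.

## Ensembles, selection, statistics

`sum_rule_fuse()` averages member probability matrices (the sum rule up
to $1/m$, keeping rows stochastic to $10^{-9}$); fusion is
permutation-invariant and idempotent. The named recipes (ENS, ENS_G,
eENS, eENS_G, ALL, eALL, 15ReLU) are member-key lists over a registry of
per-activation probability matrices at input scales 1 and 255; 15ReLU
fuses fifteen ReLU networks differing only in training seed. The pools
`stoc1`–`stoc3` follow the published enumerations; the fourth stochastic
recipe is not enumerated in the source (its pool table collides with
another table's numbering), so `stoc4` is configurable and defaults to
the `stoc2` pool.

`sffs_select()` implements sequential forward floating selection over
candidate models: at each step add the member with the largest fused-
accuracy gain, then conditionally drop the member whose removal most
improves the ensemble, until no improvement or a size cap. The selection
objective supports leave-one-context-out averaging (the published
selection uses leave-one-dataset-out). Ties break toward smaller
ensembles, then lexicographic member order, making selection
deterministic. Because all singletons are scored in the first forward
step and the best subset ever visited is returned, the result is never
worse on the selection data than the best single candidate — SFFS is not
guaranteed globally optimal, and the tests compare it against an
exhaustive-subset oracle on pools of eight.

`wilcoxon_signed_rank()` drops zero differences (the standard
convention; the protocol is silent), uses midranks for tied absolute
differences, and computes the p-value for $n \le 15$ *exactly* by
enumerating all $2^n$ sign assignments — valid under ties, where the
classical tabulated null is not — switching to the tie-corrected normal
approximation with continuity correction above that. Per-dataset pairing
is the default comparison unit. `average_rank()` ranks methods within
each dataset (midranks for ties; rank 1 = best accuracy) and averages
across datasets. `make_folds()` builds seeded *stratified* k-fold
assignments — stratification is assumed because several benchmark
datasets have tiny per-class counts — and records fixed train/test
partitions for the Tr-Te protocol.

## Synthetic data: what it shows and what it cannot

`make_toy_dataset()` generates seeded per-class PNG directories with
three signal families: Gaussian-blob position (class = blob location,
with ±1 px jitter), texture frequency (class = sinusoid frequency, phase
jitter bounded to $[0, \pi/4]$), and intensity-gradient orientation
(class = direction, with ±10% amplitude jitter). `sigma` adds Gaussian
pixel noise on the unit range; at `sigma = 0` every family is separable
by a raw-pixel nearest-centroid rule (the phase jitter is bounded
precisely so that this oracle works), and centroid accuracy is
non-increasing in `sigma`. Signal amplitudes were chosen once so that
TinyNet exceeds 90% at `sigma = 0.5` within the epoch budget on one CPU,
keeping ensemble-level directional comparisons meaningful.

`make_probability_fixtures()` manufactures labeled probability matrices
whose argmax accuracy hits prescribed targets exactly up to rounding
(the correct-row count is fixed, not sampled), for fusion and selection
tests with no training in the loop.

These fixtures emulate *controlled separability*, not medical imagery:
no class imbalance, no inter-observer label noise, no stain/illumination
variation, no resolution heterogeneity. Passing the desk experiments
demonstrates that the machinery — gradients, surgery, training, fusion,
selection, scoring — is correct and that the stochastic-ensemble effect
(fusion ≥ average member) materializes on a real training run; it does
not certify accuracy levels on any real dataset, which require the
original collections and pretrained backbones.

## Numerical choices and limitations

Problem sizes in the shipped tests: gradient audits use 50 draws per
kind; the desk experiment trains a 5-member stochastic ensemble plus
five ReLU re-trainings on a 4-class, 160-image, 32×32 task (20 epochs
for single-kind plans, 30 for mixed). Degenerate inputs error early:
empty pools, uncovered sites, single-class datasets, all-zero
difference vectors, classes smaller than the fold count. Non-finite
training loss raises an error rather than returning silently. The
engine is CPU-only and single-threaded by design; it is a correctness
vehicle, not a performance one. Known limitations: no weighted or
rank-level fusion (sum rule only), no adapters for third-party
pretrained weight formats, and the 2D MeLU conventions above are
conventions — alternative readings of its defining equation would give
a different (equally defensible) operator.
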