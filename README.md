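# activens

Learnable activation functions and activation-replacement ensembles for
small-image CNNs, in R.

Small and midsize image-classification datasets — the rule rather than the
exception in biomedical imaging — overfit large networks easily. One
effective remedy is to build ensembles of networks that differ only in
their activation functions, either by training one network per activation
or by *stochastically replacing* every activation site of a network with a
function drawn from a pool and fusing many such networks by the sum rule.
`activens` provides the complete toolkit behind that idea:

* **An activation catalogue of 25 kinds** with exact forward values, input
  gradients and learnable-parameter gradients: ReLU, Leaky ReLU, PReLU,
  ELU, SELU, PDELU, Swish (fixed and learnable β), Mish (fixed and
  learnable α), TanELU, SReLU, APLU, Splash, SRS, Soft Learnable (fixed
  and learnable β), and the Mexican-hat family — MeLU, GaLU, Small GaLU,
  MeLU+GaLU, Symmetric MeLU, Symmetric GaLU, Flexible MeLU and the
  channel-pairing 2D MeLU.
* **The fixed hat-parameter ladders** that define the MeLU/GaLU bases.
  MeLU is `PReLU_{c0}(x) + Σ_j c_j φ_{a_j,λ_j}(x)` with
  `φ_{a,λ}(x) = max(λ − |x − a|, 0)`; the `(a_j, λ_j)` come from a
  recursive dyadic subdivision of `[0, 4·maxInput]`, and GaLU replaces φ
  by a zero-mean "Gaussian" hat on a derived ladder.
* **Network surgery**: an abstract layer graph with activation sites, a
  built-in trainable TinyNet (two conv blocks + classifier), seeded
  deterministic or stochastic replacement plans, and preset pools
  (`stoc1`–`stoc4`).
* **Training**: SGD with momentum, per-layer learning rates (×20 on the
  classifier head; `λ* = λ/maxInput` for APLU/Splash slopes), the 0.001
  L2 slope penalty, and flip/rescale augmentation.
* **Ensembles and evaluation**: sum-rule fusion of class-probability
  matrices, named recipes (ENS, ENS_G, eENS, eENS_G, ALL, eALL, 15ReLU),
  SFFS member selection, stratified k-fold assignment, an exact
  (enumeration-based) Wilcoxon signed-rank test and average-rank
  summaries.
* **Synthetic data**: seeded multi-class PNG image datasets with
  controllable difficulty, so everything above runs desk-scale with no
  downloads.

## Worked example

```r
library(activens)

# The published MeLU ladder at maxInput = 256:
build_melu_ladder(256, 8)
#> Hat parameter ladder (max_input = 256, 7 hats)
#>  j a_j lambda_j
#>  1 512      512
#>  2 256      256
#>  3 768      256
#>  4 128      128
#>  5 384      128
#>  6 640      128
#>  7 896      128

# A seeded 4-class toy task and a 5-member stochastic ensemble:
tr <- make_toy_dataset(toy_spec(4, 40, 32, sigma = 0.5, seed = 10))
te <- make_toy_dataset(toy_spec(4, 25, 32, sigma = 0.5, seed = 99))
g  <- tiny_net_graph(32, 1, c(8, 16), 32, 4)
ens <- build_stochastic_ensemble(g, activation_pool("stoc1", max_input = 1),
                                 n_members = 5, tr, te$x,
                                 config = desk_train_config(seed = 3), seed = 7)
sapply(ens$member_probs, accuracy, labels = te$y)
#> [1] 96 93 99 95 98
accuracy(ens$fused, te$y)
#> [1] 100
```

The five member networks — identical up to the randomly assigned
activation functions at their three activation sites — score 93–99% on
the held-out images; averaging their softmax outputs (the sum rule) lifts
the ensemble to 100%, the behaviour stochastic activation ensembles are
built to exploit.

Gradient correctness of every kind is verifiable directly:

```r
sp <- activation_spec("melu", k = 8, max_input = 1)
p  <- init_params(sp, n_channels = 4, seed = 1)
g  <- grad_activation(sp, p, matrix(rnorm(8), 4))
names(g$d_params)
#> [1] "c0" "c"
```

A thin command-line wrapper for fusion lives in `inst/cli/fuse.R`:

```sh
Rscript inst/cli/fuse.R --inputs m1.csv,m2.csv --out fused.csv
Rscript inst/cli/fuse.R --recipe ENS_G --max-input 255 --registry probs/ --out fused.csv
```

## Vignette

`vignettes/activation-ensembles.Rmd` documents the model family, the
ladder construction, every design decision taken where the underlying
formulas are ambiguous, the training protocol, and what the synthetic
benchmarks do and do not demonstrate.
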