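test_that("fixed activations reproduce hand-computed values", {
  ev <- function(kind, x, ...) {
    sp <- activation_spec(kind, ...)
    eval_activation(sp, init_params(sp, 1L), x)
  }
  expect_identical(ev("relu", c(-3, 4)), c(0, 4))
  expect_equal(ev("leaky_relu", -5), -0.05)
  expect_equal(ev("elu", -1), exp(-1) - 1)
  expect_equal(ev("selu", 1), 1.0507009873554805)
  expect_equal(ev("swish", 2), 2 * stats::plogis(2))
  expect_equal(ev("mish", 1), tanh(log(1 + exp(1))))
})

test_that("PReLU with a set slope follows its two branches", {
  sp <- activation_spec("prelu")
  p <- init_params(sp, 1L)
  p$c0 <- 0.25
  expect_equal(eval_activation(sp, p, -2), -0.5)
  expect_equal(eval_activation(sp, p, 3), 3)
})

test_that("MeLU equals PReLU plus the explicit hat summation", {
  sp <- activation_spec("melu", k = 8, max_input = 256)
  p <- init_params(sp, 1L)
  set.seed(4)
  p$c0 <- 0.1
  p$c <- matrix(stats::rnorm(7, 0, 0.5), 1)
  lad <- build_melu_ladder(256, 8)
  x <- seq(-200, 1200, length.out = 100)
  direct <- ifelse(x >= 0, x, p$c0[1] * x)      # independent summation oracle
  for (j in 1:7)
    direct <- direct + p$c[1, j] * pmax(lad$half_widths[j] - abs(x - lad$centers[j]), 0)
  expect_equal(eval_activation(sp, p, x), direct, tolerance = 1e-12)
})

test_that("2D MeLU with zero coefficients sums the paired ReLUs", {
  sp <- activation_spec("melu_2d")
  p <- init_params(sp, 4L)
  x <- matrix(stats::rnorm(4 * 6, sd = 2), 4, 6)
  y <- eval_activation(sp, p, x)
  xn <- x[c(2, 3, 4, 1), ]
  expect_equal(y, pmax(x, 0) + pmax(xn, 0))
})

test_that("ladder-based kinds collapse to ReLU at initialization", {
  x <- matrix(seq(-5, 5, length.out = 1e4), nrow = 1)
  for (kind in c("melu", "galu", "small_galu", "aplu", "tanelu",
                 "melu_plus_galu", "flexible_melu")) {
    sp <- activation_spec(kind)
    y <- eval_activation(sp, init_params(sp, 1L, seed = 2L), x)
    expect_identical(max(abs(y - pmax(x, 0))), 0, info = kind)
  }
  for (kind in c("symmetric_melu", "symmetric_galu")) {
    sp <- activation_spec(kind)
    y <- eval_activation(sp, init_params(sp, 1L), x)
    expect_identical(max(abs(y - abs(x))), 0, info = kind)
  }
})

test_that("symmetric variants are even for arbitrary shared coefficients", {
  for (kind in c("symmetric_melu", "symmetric_galu")) {
    sp <- activation_spec(kind)
    for (s in 1:5) {
      case <- draw_activation_case(kind, seed = 100 + s)
      y_pos <- eval_activation(case$spec, case$params, case$x)
      y_neg <- eval_activation(case$spec, case$params, -case$x)
      expect_lt(max(abs(y_pos - y_neg)), 1e-12)
    }
  }
})

test_that("Swish approaches ReLU as beta grows", {
  sp <- activation_spec("swish", constants = list(beta = 50))
  p <- init_params(sp, 1L)
  x <- c(seq(-8, -1, by = 0.05), seq(1, 8, by = 0.05))
  expect_lt(max(abs(eval_activation(sp, p, x) - pmax(x, 0))), 1e-6)
})

test_that("smooth negative-branch kinds vanish exactly at zero", {
  for (kind in c("pdelu", "srs", "soft_learnable", "soft_learnable2",
                 "elu", "selu")) {
    sp <- activation_spec(kind)
    p <- init_params(sp, 1L)
    if ("alpha" %in% names(p)) p$alpha <- p$alpha + 0.7  # non-trivial params
    expect_identical(eval_activation(sp, p, 0), 0, info = kind)
  }
})

test_that("seeded initialization is deterministic and zero-based", {
  sp <- activation_spec("aplu", max_input = 255)
  p1 <- init_params(sp, 2L, seed = 11L)
  p2 <- init_params(sp, 2L, seed = 11L)
  expect_identical(p1, p2)
  expect_true(all(p1$a == 0))
  expect_true(all(p1$b > 0 & p1$b < 255))
  expect_false(identical(p1$b, init_params(sp, 2L, seed = 12L)$b))

  fm <- activation_spec("flexible_melu")
  pf <- init_params(fm, 3L)
  expect_equal(pf$centers[2, ], build_melu_ladder(1, 8)$centers)
})

test_that("SReLU presets match their documented operating points", {
  op <- init_params(activation_spec("srelu"), 2L)
  expect_equal(unname(op$a_l), c(0.5, 0.5))
  expect_equal(unname(op$a_r), c(0.2, 0.2))
  expect_equal(unname(op$t_l), c(-2, -2))
  expect_equal(unname(op$t_r), c(1.5, 1.5))
  ref <- init_params(activation_spec("srelu", max_input = 255,
                                     constants = list(preset = "reference")), 1L)
  expect_identical(c(ref$a_l, ref$t_l, ref$t_r), c(0, 0, 255))
})

test_that("shape and key mismatches are rejected", {
  sp <- activation_spec("prelu")
  p <- init_params(sp, 3L)
  expect_error(eval_activation(sp, p, matrix(0, 2, 5)), "channels")
  p_bad <- p
  names(p_bad) <- "slope"
  expect_error(eval_activation(sp, p_bad, matrix(0, 3, 5)), "match")
  p_relu <- init_params(activation_spec("relu"), 3L)
  expect_error(eval_activation(sp, p_relu, matrix(0, 3, 5)), "kind")
  expect_error(activation_spec("not_a_kind"), "unknown")
})
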