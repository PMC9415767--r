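test_that("augmentation is identity-like on constant images and seeded", {
  img <- matrix(0.7, 24, 24)
  out <- augment_image(img, seed = 3)
  expect_equal(dim(out), dim(img))
  expect_lt(max(abs(out - img)), 1e-6)      # flips/rescales cannot change it
  noisy <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(augment_image(noisy, seed = 12), augment_image(noisy, seed = 12))
  expect_error(augment_image(array(0, c(0, 3))), "empty")
})

test_that("augmentation rescale factors are uniform on [1, 2]", {
  # factors are the 3rd/4th uniform draws of the augmentation RNG stream
  draws <- t(vapply(1:10000, function(s)
    activens:::with_seed(s, { stats::runif(2); stats::runif(2, 1, 2) }),
    numeric(2)))
  expect_gte(min(draws), 1)
  expect_lte(max(draws), 2)
  se <- sqrt(1 / 12) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1.5), 3 * se)
})

test_that("learning-rate schedule applies the head multiplier and the APLU rule", {
  g <- tiny_net_graph()
  plan <- uniform_plan(g, activation_spec("aplu", max_input = 255))
  cfg <- train_config(base_lr = 1e-4, final_layer_lr_multiplier = 20)
  sched <- build_lr_schedule(cfg, g, plan)
  expect_equal(sched$lr[sched$group == "head"], 0.002)
  expect_equal(sched$lr[sched$group == "conv1"], 1e-4)
  expect_equal(sched$lr[sched$group == "act1:a"], 1e-4 / 255)
  expect_equal(sched$lr[sched$group == "act1:b"], 1e-4)

  flat <- build_lr_schedule(train_config(base_lr = 1e-4,
                                         final_layer_lr_multiplier = 1),
                            g, uniform_plan(g))
  expect_true(all(flat$lr == 1e-4))
})

test_that("the APLU slope regularizer computes coeff * sum of squares", {
  sp <- activation_spec("aplu", constants = list(n_hinges = 2L))
  p <- init_params(sp, 1L)
  p$a <- matrix(c(0.1, -0.2), 1)
  expect_equal(aplu_regularization(p, 0.001), 5e-5)
  p$a[] <- 0
  expect_equal(aplu_regularization(p, 0.001), 0)
  p$a <- matrix(c(3, -4), 1)
  expect_equal(aplu_regularization(p, 0), 0)
  expect_error(aplu_regularization(init_params(activation_spec("relu"), 1L), 1),
               "APLU")
  sps <- activation_spec("splash", constants = list(n_hinges = 1L))
  ps <- init_params(sps, 1L)
  ps$a_pos[] <- 1; ps$a_neg[] <- 2
  expect_equal(aplu_regularization(ps, 0.5), 0.5 * 5)
})

test_that("training descends, is seed-deterministic, and matches ReLU at epoch 0", {
  tr <- toy_train_set(spc = 15L)
  g <- tiny_net_graph(32, 1, c(4, 8), 16, 4)
  cfg <- desk_train_config(seed = 5, epochs = 3, batch_size = 20)
  m1 <- train_model(g, uniform_plan(g), tr, cfg)
  expect_lt(tail(m1$trace$loss, 1), m1$trace$loss[1])
  expect_true(all(is.finite(m1$trace$loss)))
  m2 <- train_model(g, uniform_plan(g), tr, cfg)
  expect_identical(m1$trace, m2$trace)

  melu_cfg <- cfg
  m3 <- train_model(g, uniform_plan(g, activation_spec("melu")), tr, melu_cfg)
  expect_equal(m3$trace$loss[1], m1$trace$loss[1], tolerance = 1e-12)

  one_class <- tr
  one_class$y[] <- 1L
  expect_error(train_model(g, uniform_plan(g), one_class, cfg), "2 classes")
})

test_that("epoch budget defaults to 20 and rises to 30 for mixed plans", {
  g <- tiny_net_graph()
  cfg <- train_config()
  expect_equal(activens:::plan_epochs(cfg, uniform_plan(g)), 20L)
  mixed <- uniform_plan(g)
  mixed$site_assignments$act2 <- activation_spec("elu")
  expect_equal(activens:::plan_epochs(cfg, mixed), 30L)
  expect_equal(activens:::plan_epochs(train_config(epochs = 7), mixed), 7L)
})

test_that("PNG datasets round-trip through the directory loader", {
  dir <- withr::local_tempdir()
  ds <- make_toy_dataset(toy_spec(3, 4, 16, sigma = 0.2, seed = 8), dir = dir)
  back <- load_image_dataset(dir)
  expect_equal(dim(back$x), c(16, 16, 1, 12))
  expect_equal(back$y, ds$y)
  expect_equal(back$x, ds$x, tolerance = 1e-9)  # 8-bit quantized on both sides
  expect_equal(back$classes, ds$classes)
})

test_that("training configs read from YAML and loss traces write as CSV", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("batch_size: 10", "base_lr: 0.001", "epochs: 2",
               "augmentation: no", "seed: 4"), path)
  cfg <- read_train_config(path)
  expect_s3_class(cfg, "train_config")
  expect_equal(cfg$batch_size, 10L)
  expect_equal(cfg$base_lr, 0.001)
  expect_false(cfg$augmentation)

  trace <- data.frame(epoch = 0:1, loss = c(1.4, 1.1), accuracy = c(0.3, 0.6))
  out <- withr::local_tempfile(fileext = ".csv")
  write_loss_trace(trace, out)
  expect_equal(utils::read.csv(out), trace)
})
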