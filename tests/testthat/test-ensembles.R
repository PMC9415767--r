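test_that("probability matrices enforce row-stochasticity", {
  m <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
  pm <- probability_matrix(m, model_id = "m1")
  expect_s3_class(pm, "probability_matrix")
  expect_error(probability_matrix(matrix(c(0.7, 0.2, 0.2, 0.8), 2, byrow = TRUE)),
               "sum to 1")
  expect_error(probability_matrix(matrix(c(1.5, -0.5, 0.2, 0.8), 2, byrow = TRUE)),
               "nonnegative")
})

test_that("sum-rule fusion averages, is idempotent and permutation-invariant", {
  fx <- make_probability_fixtures(3, 60, 4, targets = c(0.9, 0.6, 0.4), seed = 2)
  ms <- fx$probs
  expect_equal(unclass(sum_rule_fuse(list(ms[[1]], ms[[1]]))),
               unclass(ms[[1]]), ignore_attr = TRUE)
  a <- probability_matrix(matrix(c(1, 0), 1))
  b <- probability_matrix(matrix(c(0, 1), 1))
  expect_equal(as.numeric(sum_rule_fuse(list(a, b))), c(0.5, 0.5))
  f123 <- sum_rule_fuse(ms)
  f321 <- sum_rule_fuse(rev(ms))
  expect_equal(unclass(f123), unclass(f321), ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(f123) - 1)), 1e-9)
  # fifteen copies of one model predict exactly like the model
  expect_equal(unclass(sum_rule_fuse(rep(ms[1], 15))), unclass(ms[[1]]),
               ignore_attr = TRUE)
  expect_error(sum_rule_fuse(list()), "non-empty")
  expect_error(sum_rule_fuse(list(a, probability_matrix(matrix(c(1, 0, 0), 1)))),
               "share")
})

test_that("SFFS returns the dominant model and drops harmful members", {
  fx <- make_probability_fixtures(4, 300, 4, targets = c(0.95, 0.3, 0.3, 0.3),
                                  seed = 5)
  sel <- sffs_select(fx$probs, fx$labels)
  expect_true(1L %in% sel)
  best_single <- max(vapply(fx$probs, accuracy, numeric(1), labels = fx$labels))
  expect_gte(attr(sel, "score"), best_single)
  # a single candidate is returned as-is
  one <- sffs_select(fx$probs[1], fx$labels)
  expect_identical(as.integer(one), 1L)
  expect_error(sffs_select(list(), fx$labels), "empty")
})

test_that("SFFS never falls below the best single model and tracks the
           exhaustive oracle on small pools", {
  for (s in 1:4) {
    fx <- make_probability_fixtures(8, 200, 4,
                                    targets = seq(0.35, 0.9, length.out = 8),
                                    seed = 40 + s)
    sel <- sffs_select(fx$probs, fx$labels)
    singles <- vapply(fx$probs, accuracy, numeric(1), labels = fx$labels)
    expect_gte(attr(sel, "score") + 1e-9, max(singles))
    # exhaustive oracle over all non-empty subsets
    best_exh <- -Inf
    for (mask in 1:(2^8 - 1)) {
      subset <- which(bitwAnd(mask, 2^(0:7)) > 0)
      best_exh <- max(best_exh, accuracy(sum_rule_fuse(fx$probs[subset]), fx$labels))
    }
    expect_lte(attr(sel, "score"), best_exh + 1e-9)
    expect_gte(attr(sel, "score"), max(singles))
  }
})

test_that("SFFS supports leave-one-context-out objectives", {
  ctxs <- lapply(1:3, function(ctx)
    make_probability_fixtures(4, 150, 3, targets = c(0.85, 0.7, 0.5, 0.34),
                              seed = 60 + ctx))
  cands <- lapply(ctxs, `[[`, "probs")
  labs <- lapply(ctxs, `[[`, "labels")
  sel <- sffs_select(cands, labs)
  expect_true(length(sel) >= 1)
  singles <- vapply(1:4, function(j)
    mean(vapply(1:3, function(ctx) accuracy(cands[[ctx]][[j]], labs[[ctx]]),
                numeric(1))), numeric(1))
  expect_gte(attr(sel, "score") + 1e-9, max(singles))
})

test_that("recipe member lists match their published definitions", {
  expect_setequal(recipe_members("ENS", max_input = 1),
                  paste0(c("melu_k8", "leaky_relu", "elu", "melu_k4", "prelu",
                           "srelu", "aplu", "relu"), "@1"))
  expect_setequal(recipe_members("ENS", max_input = 255),
                  paste0(c("melu_k8", "melu_k4", "srelu", "aplu", "relu"), "@255"))
  expect_setequal(recipe_members("ENS_G", max_input = 255),
                  c(recipe_members("ENS", max_input = 255),
                    "small_galu@255", "galu@255"))
  expect_setequal(recipe_members("eENS"),
                  c(recipe_members("ENS", 1), recipe_members("ENS", 255)))
  expect_length(recipe_members("15ReLU"), 15L)
  expect_true(all(grepl("^relu@seed", recipe_members("15ReLU"))))
  expect_true(all(recipe_members("ENS", 1) %in% recipe_members("ALL", 1)))
})

test_that("recipe fusion pulls the right members from a registry", {
  set.seed(1)
  keys <- unique(c(recipe_members("eENS_G"), recipe_members("eALL")))
  reg <- lapply(keys, function(k)
    make_probability_fixtures(1, 50, 3, targets = 0.7,
                              seed = sum(utf8ToInt(k)))$probs[[1]])
  names(reg) <- keys
  fused <- recipe_ensemble("ENS_G", reg, max_input = 1)
  byhand <- sum_rule_fuse(reg[recipe_members("ENS_G", 1)])
  expect_equal(unclass(fused), unclass(byhand), ignore_attr = TRUE)
  expect_error(recipe_ensemble("ENS", reg["melu_k8@1"], max_input = 1), "missing")
})

test_that("probability matrices round-trip through CSV", {
  fx <- make_probability_fixtures(1, 20, 5, targets = 0.8, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_probability_csv(fx$probs[[1]], path)
  back <- read_probability_csv(path, model_id = "m")
  expect_equal(unclass(back), unclass(fx$probs[[1]]), tolerance = 1e-6,
               ignore_attr = TRUE)
})
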