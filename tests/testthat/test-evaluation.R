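test_that("stratified folds balance classes and partition exactly once", {
  labels <- rep(1:2, each = 50)
  fa <- make_folds(labels, n_folds = 5, seed = 2)
  expect_equal(unname(table(fa$fold)), rep(20L, 5), ignore_attr = TRUE)
  for (f in 1:5)
    expect_equal(unname(table(labels[fa$fold == f])), c(10L, 10L),
                 ignore_attr = TRUE)
  expect_length(fa$fold, 100)
  expect_identical(fa$protocol, "5CV")
  expect_identical(fa$fold, make_folds(labels, 5, seed = 2)$fold)
  expect_false(identical(fa$fold, make_folds(labels, 5, seed = 3)$fold))
})

test_that("10-fold assignment of 304 samples gives fold sizes 30 or 31", {
  labels <- rep(1:10, length.out = 304)
  fa <- make_folds(labels, n_folds = 10, seed = 1)
  sizes <- as.integer(table(fa$fold))
  expect_true(all(sizes %in% c(30L, 31L)))
  # per-class fold sizes differ by at most one
  for (cl in 1:10) {
    cs <- table(factor(fa$fold[labels == cl], levels = 1:10))
    expect_lte(max(cs) - min(cs), 1)
  }
  expect_error(make_folds(c(1, 1, 2), n_folds = 2), "cannot be split")
})

test_that("the fixed train/test protocol records the supplied partition", {
  labels <- rep(1:2, each = 4)
  fa <- make_folds(labels, protocol = "TrTe",
                   trte_split = c(rep(FALSE, 4), rep(TRUE, 4)))
  expect_identical(fa$protocol, "TrTe")
  expect_equal(fa$fold, c(rep(1L, 4), rep(2L, 4)))
  expect_error(make_folds(labels, protocol = "TrTe"), "trte_split")
})

test_that("accuracy scores argmax predictions with low-index tie-breaking", {
  pm <- probability_matrix(diag(3)[c(1, 2, 3), ])
  expect_equal(accuracy(pm, c(1, 2, 3)), 100)
  expect_equal(accuracy(pm, c(1, 2, 1)), 100 * 2 / 3)
  uniform <- probability_matrix(matrix(0.25, 6, 4))
  expect_equal(accuracy(uniform, rep(1L, 6)), 100)  # ties go to class 1
  expect_equal(accuracy(uniform, rep(2L, 6)), 0)
  expect_error(accuracy(pm, 1:2), "mismatch")
})

test_that("exact signed-rank enumeration reproduces closed-form tails", {
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1),
                            alternative = "greater")
  expect_equal(r$p.value, 1 / 32)            # all-positive pattern of 2^5
  expect_equal(r$statistic, 15)
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(0, 1, 2, 3)), "at least 5")
})

test_that("exact enumeration agrees with the classical reference when untied", {
  set.seed(9)
  for (rep in 1:5) {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12)
    d <- x - y
    # rank() ties are measure-zero for continuous draws; reference is exact
    for (alt in c("two.sided", "greater", "less")) {
      ours <- wilcoxon_signed_rank(x, y, alternative = alt)$p.value
      ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = alt,
                                exact = TRUE)$p.value
      expect_lt(abs(ours - ref), 1e-10)
    }
  }
})

test_that("signed-rank p-values respect symmetry and monotone invariance", {
  set.seed(21)
  x <- stats::rnorm(10, 0.5)
  y <- stats::rnorm(10)
  pg <- wilcoxon_signed_rank(x, y, "greater")$p.value
  pl <- wilcoxon_signed_rank(y, x, "less")$p.value
  expect_equal(pg, pl)
  # ranks are invariant to positive affine rescaling of the scores
  f <- function(z) 7.3 * z - 2
  expect_equal(wilcoxon_signed_rank(f(x), f(y), "greater")$p.value, pg)
  # large-n path returns a sane approximate tail
  xn <- stats::rnorm(40, 0.8)
  yn <- stats::rnorm(40)
  pn <- wilcoxon_signed_rank(xn, yn, "greater")$p.value
  pref <- stats::wilcox.test(xn, yn, paired = TRUE, alternative = "greater",
                             exact = FALSE, correct = TRUE)$p.value
  expect_equal(pn, pref, tolerance = 1e-10)
})

test_that("average ranks use midranks and sum to m(m+1)/2 per dataset", {
  tab <- rbind(A = c(90, 70), B = c(80, 80), C = c(70, 90))
  expect_equal(average_rank(tab), c(A = 2, B = 2, C = 2))
  dom <- rbind(A = c(99, 98), B = c(90, 90), C = c(80, 70))
  expect_equal(average_rank(dom), c(A = 1, B = 2, C = 3))
  tied <- rbind(A = c(90, 90), B = c(90, 90))
  expect_equal(average_rank(tied), c(A = 1.5, B = 1.5))
  set.seed(3)
  m <- matrix(stats::runif(5 * 7, 60, 100), 5, 7)
  per_ds <- apply(m, 2, function(col) sum(rank(-col, ties.method = "average")))
  expect_true(all(per_ds == 5 * 6 / 2))
  expect_error(average_rank(rbind(c(1, NA))), "missing")
})

test_that("results tables round-trip through CSV with an Avg column", {
  m <- rbind(relu = c(CH = 90.1, HE = 85.2), melu = c(CH = 91.0, HE = 86.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(m, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_true("Avg" %in% names(df))
  expect_equal(df$Avg, rowMeans(m), ignore_attr = TRUE)
  back <- read_results_csv(path)
  expect_equal(back, m)
})
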