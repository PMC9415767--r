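#' Stratified cross-validation folds
#'
#' Assigns every sample to exactly one fold, stratified so that within
#' each class the fold sizes differ by at most one. The `TrTe` protocol
#' instead records a fixed, externally supplied train/test partition.
#'
#' @param labels Integer or factor label vector.
#' @param n_folds Number of folds (>= 2) for cross-validation protocols.
#' @param protocol `"CV"` (default; tag becomes e.g. `"5CV"`) or `"TrTe"`.
#' @param seed Integer seed for the stratified shuffle.
#' @param trte_split For `TrTe`: integer/logical vector marking the test
#'   partition (TRUE or 2 = test).
#' @return A `fold_assignment`: list with `fold` (integer per sample),
#'   `n_folds`, `protocol`.
#' @export
make_folds <- function(labels, n_folds = 5L, protocol = c("CV", "TrTe"),
                       seed = 1L, trte_split = NULL) {
  protocol <- match.arg(protocol)
  labels <- as.integer(as.factor(labels))
  if (protocol == "TrTe") {
    stop_if_not(!is.null(trte_split), "TrTe requires `trte_split`")
    fold <- as.integer(as.logical(trte_split)) + 1L
    stop_if_not(length(fold) == length(labels), "split length mismatch")
    return(structure(list(fold = fold, n_folds = 2L, protocol = "TrTe"),
                     class = "fold_assignment"))
  }
  stop_if_not(n_folds >= 2L, "`n_folds` must be >= 2 for cross-validation")
  counts <- table(labels)
  stop_if_not(min(counts) >= n_folds,
              sprintf("class with %d sample(s) cannot be split into %d folds",
                      min(counts), n_folds))
  fold <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # deal round-robin with a rotating start so fold sizes balance globally
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 protocol = sprintf("%dCV", n_folds)),
            class = "fold_assignment")
}

#' Classification accuracy of a probability matrix
#'
#' Percentage of samples whose argmax class equals the label, with argmax
#' ties broken toward the lowest class index.
#'
#' @param pred A `probability_matrix` (or plain matrix) with one row per
#'   sample.
#' @param labels Integer labels (1..K), same length as `nrow(pred)`.
#' @return Accuracy in percent (0..100).
#' @export
accuracy <- function(pred, labels) {
  pred <- as.matrix(pred)
  stop_if_not(nrow(pred) == length(labels), "prediction/label length mismatch")
  hard <- apply(pred, 1, which.max)          # which.max takes the first tie
  100 * mean(hard == as.integer(labels))
}

#' Wilcoxon signed-rank test
#'
#' Paired comparison of two score vectors. Zero differences are dropped;
#' absolute differences are ranked with midranks for ties. For n <= 15
#' pairs the p-value is exact, computed by full enumeration of all 2^n
#' sign assignments (valid under ties, unlike the classical null
#' distribution); for larger n the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Paired numeric score vectors.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return List with `statistic` (V, the positive-rank sum), `n` (pairs
#'   used) and `p.value`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  stop_if_not(length(d) > 0L, "all differences are zero")
  stop_if_not(length(d) >= 5L, "need at least 5 non-zero differences")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 15L) {
    # exact: V under random signs; enumerate all sign patterns
    bits <- as.matrix(expand.grid(rep(list(0:1), n)))
    Vperm <- as.vector(bits %*% r)
    p_greater <- mean(Vperm >= V - 1e-12)
    p_less <- mean(Vperm <= V + 1e-12)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p_greater <- stats::pnorm((V - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
    p_less <- stats::pnorm((V - mu + 0.5) / sqrt(sig2))
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  list(statistic = V, n = n, p.value = p)
}

#' Average rank of methods across datasets
#'
#' Ranks methods within each dataset (rank 1 = highest accuracy, midranks
#' for ties) and averages the ranks across datasets; lower is better.
#'
#' @param table Numeric matrix or data frame of accuracies, methods in
#'   rows, datasets in columns; no missing cells.
#' @return Named numeric vector of average ranks, in the input's method
#'   order.
#' @export
average_rank <- function(table) {
  m <- as.matrix(table)
  stop_if_not(!anyNA(m), "results table has missing cells")
  ranks <- apply(m, 2, function(col) rank(-col, ties.method = "average"))
  out <- rowMeans(ranks)
  names(out) <- rownames(m)
  out
}

#' Read/write a results table as CSV
#'
#' Rows are methods (first column `method`), columns are datasets; an
#' `Avg` column is appended on write.
#'
#' @param table Numeric matrix, methods in rows.
#' @param path File path.
#' @return `write_results_csv` returns `path` invisibly;
#'   `read_results_csv` returns the accuracy matrix (without `Avg`).
#' @export
write_results_csv <- function(table, path) {
  m <- as.matrix(table)
  df <- data.frame(method = rownames(m) %||% paste0("m", seq_len(nrow(m))),
                   m, Avg = rowMeans(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("method", "Avg")), drop = FALSE])
  rownames(m) <- df$method
  m
}
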