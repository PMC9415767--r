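#' Class-probability matrices
#'
#' The exchange currency of the ensemble machinery: an
#' `n_samples x n_classes` matrix of nonnegative class probabilities whose
#' rows sum to 1 (softmax outputs of one model on one evaluation set).
#'
#' @param values Numeric matrix, rows summing to 1 within 1e-9.
#' @param model_id Optional model identifier.
#' @param dataset_id Optional dataset/fold identifier.
#' @return A `probability_matrix`.
#' @export
probability_matrix <- function(values, model_id = NA_character_,
                               dataset_id = NA_character_) {
  values <- as.matrix(values)
  stop_if_not(all(values >= 0), "probabilities must be nonnegative")
  stop_if_not(max(abs(rowSums(values) - 1)) <= 1e-9,
              "every row must sum to 1 within 1e-9")
  structure(values, class = c("probability_matrix", "matrix", "array"),
            model_id = model_id, dataset_id = dataset_id)
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf("<probability_matrix | %d samples x %d classes | model %s>\n",
              nrow(x), ncol(x), attr(x, "model_id")))
  invisible(x)
}

#' Read/write probability matrices as CSV
#'
#' Layout: a `sample` column followed by one column per class
#' (`class_1`, ...).
#'
#' @param mat A `probability_matrix`.
#' @param path File path.
#' @param model_id Identifier attached on read.
#' @return `write_probability_csv` returns `path` invisibly;
#'   `read_probability_csv` returns a `probability_matrix`.
#' @export
write_probability_csv <- function(mat, path) {
  df <- data.frame(sample = seq_len(nrow(mat)), unclass(mat))
  names(df) <- c("sample", paste0("class_", seq_len(ncol(mat))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probability_csv
#' @export
read_probability_csv <- function(path, model_id = NA_character_) {
  df <- utils::read.csv(path)
  stop_if_not("sample" %in% names(df), "CSV must contain a `sample` column")
  df <- df[order(df$sample), ]
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  m <- m / rowSums(m)                       # absorb CSV rounding
  probability_matrix(m, model_id = model_id)
}

#' Sum-rule fusion
#'
#' Averages member class-probability matrices elementwise (the sum rule up
#' to the constant 1/m, so rows remain probabilities). Invariant under
#' member permutation and idempotent on identical members.
#'
#' @param members Non-empty list of `probability_matrix` objects sharing
#'   sample and class counts.
#' @return A fused `probability_matrix`.
#' @export
sum_rule_fuse <- function(members) {
  stop_if_not(length(members) >= 1L, "member list must be non-empty")
  d1 <- dim(members[[1]])
  for (m in members)
    stop_if_not(all(dim(m) == d1), "all members must share sample and class counts")
  acc <- Reduce(`+`, lapply(members, unclass))
  probability_matrix(acc / length(members), model_id = "fused")
}

#' Build and fuse a stochastic activation-replacement ensemble
#'
#' Draws `n_members` independent replacement plans from `pool` (seeds
#' derived from `seed`), trains one TinyNet per plan, and fuses the
#' members' test-set probabilities by sum rule.
#'
#' @param graph A `layer_graph`.
#' @param pool List of [activation_spec()] candidates (see
#'   [activation_pool()]).
#' @param n_members Number of member networks (>= 1).
#' @param dataset Training dataset (see [train_model()]).
#' @param test_x Test image array `H x W x C x N`.
#' @param config A [train_config()]; each member trains with a derived
#'   seed.
#' @param seed Master seed for plan sampling and member training.
#' @param granularity Plan granularity, passed to
#'   [sample_replacement_plan()].
#' @return List with `models`, `plans`, `member_probs` (list of
#'   `probability_matrix`) and `fused`.
#' @export
build_stochastic_ensemble <- function(graph, pool, n_members, dataset, test_x,
                                      config = desk_train_config(), seed = 1L,
                                      granularity = "per_layer") {
  stop_if_not(n_members >= 1L, "`n_members` must be >= 1")
  plan_seeds <- derive_seeds(seed, n_members)
  train_seeds <- derive_seeds(seed + 1L, n_members)
  models <- vector("list", n_members)
  plans <- vector("list", n_members)
  probs <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    plans[[i]] <- sample_replacement_plan(graph, pool, granularity = granularity,
                                          seed = plan_seeds[i])
    cfg <- config
    cfg$seed <- train_seeds[i]
    models[[i]] <- train_model(graph, plans[[i]], dataset, cfg)
    probs[[i]] <- predict_model(models[[i]], test_x,
                                model_id = sprintf("stoc_%02d", i))
  }
  list(models = models, plans = plans, member_probs = probs,
       fused = sum_rule_fuse(probs))
}

# Fused accuracy of a candidate subset (mean over validation contexts).
subset_score <- function(candidates, labels, subset) {
  if (is.list(candidates[[1]])) {           # one list of members per context
    mean(vapply(seq_along(candidates), function(ctx)
      accuracy(sum_rule_fuse(candidates[[ctx]][subset]), labels[[ctx]]),
      numeric(1)))
  } else {
    accuracy(sum_rule_fuse(candidates[subset]), labels)
  }
}

#' Sequential forward floating selection of ensemble members
#'
#' Greedy forward selection of the member giving the largest gain in
#' sum-rule fused accuracy, followed after each addition by a conditional
#' backward step that excludes the member whose removal most improves the
#' fused accuracy, iterated until no improvement is possible or
#' `max_size` is reached. The best subset ever visited is returned; ties
#' are broken toward the smaller ensemble, then toward lexicographically
#' earlier member order. The result is never worse on the selection data
#' than the best single candidate.
#'
#' For leave-one-dataset-out selection, pass `candidates` as a list of
#' validation contexts (each a list of per-model `probability_matrix`) and
#' `labels` as the matching list of label vectors; the objective is then
#' the mean fused accuracy over contexts.
#'
#' @param candidates List of `probability_matrix` (one context) or list of
#'   such lists (multiple contexts).
#' @param labels Integer label vector, or list of vectors (one per
#'   context).
#' @param max_size Maximum ensemble size.
#' @return Integer vector of selected candidate indices, with the achieved
#'   score in attribute `"score"`.
#' @export
sffs_select <- function(candidates, labels, max_size = NULL) {
  stop_if_not(length(candidates) >= 1L, "empty candidate list")
  n_cand <- if (is.list(candidates[[1]])) length(candidates[[1]]) else length(candidates)
  if (is.list(candidates[[1]])) {
    stop_if_not(is.list(labels) && length(labels) == length(candidates),
                "labels must be a list matching the validation contexts")
    for (ctx in seq_along(candidates))
      stop_if_not(length(candidates[[ctx]]) == n_cand,
                  "all contexts must hold the same candidates")
  }
  max_size <- max_size %||% n_cand
  score <- function(s) subset_score(candidates, labels, s)

  best_subset <- integer(0)
  best_score <- -Inf
  # prefer higher score; then smaller subset; then lexicographic order
  better <- function(sc, s) {
    if (sc > best_score + 1e-12) return(TRUE)
    if (sc < best_score - 1e-12) return(FALSE)
    if (length(s) != length(best_subset)) return(length(s) < length(best_subset))
    isTRUE(all(s == best_subset)) || (paste(s, collapse = ",") <
                                        paste(best_subset, collapse = ","))
  }
  cur <- integer(0)
  cur_score <- -Inf
  repeat {
    remaining <- setdiff(seq_len(n_cand), cur)
    if (length(remaining) == 0L || length(cur) >= max_size) break
    gains <- vapply(remaining, function(j) score(sort(c(cur, j))), numeric(1))
    j_star <- remaining[which.max(gains)]
    new_score <- max(gains)
    if (length(cur) > 0L && new_score <= cur_score + 1e-12) break  # no improvement
    cur <- sort(c(cur, j_star))
    cur_score <- new_score
    if (better(cur_score, cur)) { best_subset <- cur; best_score <- cur_score }
    # floating backward step(s)
    while (length(cur) > 2L) {
      drops <- vapply(cur, function(j) score(setdiff(cur, j)), numeric(1))
      r_star <- cur[which.max(drops)]
      if (max(drops) > cur_score + 1e-12 && r_star != j_star) {
        cur <- setdiff(cur, r_star)
        cur_score <- max(drops)
        if (better(cur_score, cur)) { best_subset <- cur; best_score <- cur_score }
      } else break
    }
  }
  structure(best_subset, score = best_score)
}

#' Named ensemble recipes
#'
#' Member lists of the fusion recipes evaluated in the benchmark:
#' `ENS` fuses the core ladder/piecewise set (at `max_input = 1`:
#' MeLU k=8, Leaky ReLU, ELU, MeLU k=4, PReLU, SReLU, APLU, ReLU; at
#' `max_input = 255` only the scale-sensitive subset MeLU k=8, MeLU k=4,
#' SReLU, APLU, ReLU); `ENS_G` adds Small GaLU and GaLU; `ALL` fuses every
#' registered kind at the given scale (ReLU included); the `e`-prefixed
#' variants (`eENS`, `eENS_G`, `eALL`) take the union over both input
#' scales; `15ReLU` fuses 15 ReLU models differing only by training
#' stochasticity.
#'
#' `recipe_members()` returns the member keys (`"<kind>@<max_input>"`,
#' with `_k4`/`_k8` suffixes for the two MeLU orders and `@seedNN` keys
#' for `15ReLU`); `recipe_ensemble()` fuses the matching matrices from a
#' named registry.
#'
#' @param name Recipe name.
#' @param max_input Input scale (1 or 255) for the single-scale recipes.
#' @param all_kinds Kinds fused by `ALL`/`eALL` (defaults to every
#'   registered kind; configurable because very slow members may be
#'   dropped in practice).
#' @return `recipe_members()`: character vector of registry keys.
#' @export
recipe_members <- function(name = c("ENS", "ENS_G", "eENS", "eENS_G", "ALL",
                                    "eALL", "15ReLU"),
                           max_input = 1, all_kinds = activation_kinds()) {
  name <- match.arg(name)
  key <- function(kinds, mi) paste0(kinds, "@", mi)
  ens <- function(mi) {
    if (mi == 1)
      key(c("melu_k8", "leaky_relu", "elu", "melu_k4", "prelu", "srelu",
            "aplu", "relu"), mi)
    else
      key(c("melu_k8", "melu_k4", "srelu", "aplu", "relu"), mi)
  }
  ens_g <- function(mi) c(ens(mi), key(c("small_galu", "galu"), mi))
  all_keys <- function(mi) {
    kinds <- sub("^melu$", "melu_k8", all_kinds)
    kinds <- unique(c(kinds, "melu_k4"))
    key(kinds, mi)
  }
  switch(name,
         ENS = ens(max_input),
         ENS_G = ens_g(max_input),
         eENS = c(ens(1), ens(255)),
         eENS_G = c(ens_g(1), ens_g(255)),
         ALL = all_keys(max_input),
         eALL = c(all_keys(1), all_keys(255)),
         `15ReLU` = sprintf("relu@seed%02d", 1:15))
}

#' @rdname recipe_members
#' @param registry Named list of `probability_matrix` objects keyed as in
#'   [recipe_members()].
#' @return `recipe_ensemble()`: the fused `probability_matrix`.
#' @export
recipe_ensemble <- function(name, registry, max_input = 1,
                            all_kinds = activation_kinds()) {
  keys <- recipe_members(name, max_input = max_input, all_kinds = all_kinds)
  missing <- setdiff(keys, names(registry))
  stop_if_not(length(missing) == 0L,
              sprintf("registry is missing member(s): %s",
                      paste(missing, collapse = ", ")))
  sum_rule_fuse(registry[keys])
}
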