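#' Abstract layer graphs with activation sites
#'
#' A `layer_graph` is an ordered list of layers, each a list with fields
#' `id`, `role` (one of `conv`, `fully_connected`, `activation_site`,
#' `pooling`, `classifier_head`) plus role-specific geometry. Activation
#' sites carry a channel count; exactly one layer is the final classifier
#' head. The graph abstracts "every ReLU layer of a CNN" without tying the
#' package to any pretrained topology.
#'
#' @name layer_graph
NULL

new_layer_graph <- function(layers, input_shape) {
  ids <- vapply(layers, `[[`, "", "id")
  stop_if_not(!anyDuplicated(ids), "layer ids must be unique")
  roles <- vapply(layers, `[[`, "", "role")
  stop_if_not(sum(roles == "classifier_head") == 1L,
              "graph must contain exactly one classifier head")
  stop_if_not(any(roles == "activation_site"),
              "graph must contain at least one activation site")
  for (l in layers[roles == "activation_site"])
    stop_if_not(l$n_channels >= 1L, "activation-site channel counts must be positive")
  structure(list(layers = layers, input_shape = input_shape),
            class = "layer_graph")
}

#' Build the TinyNet test graph
#'
#' A small convolutional network used as the canonical desk-scale vehicle
#' for replacement and ensemble experiments: two 3x3 same-padding
#' convolution blocks (each followed by an activation site and 2x2 max
#' pooling), one fully connected layer with an activation site, and a
#' softmax classifier head. Input images are square and single-channel by
#' default.
#'
#' @param input_size Image side length in pixels (must be divisible by 4).
#' @param in_channels Number of input image channels.
#' @param conv_channels Length-2 integer vector of convolution widths.
#' @param fc_units Width of the fully connected layer.
#' @param n_classes Number of output classes.
#' @return A `layer_graph`.
#' @export
tiny_net_graph <- function(input_size = 32L, in_channels = 1L,
                           conv_channels = c(8L, 16L), fc_units = 32L,
                           n_classes = 4L) {
  stop_if_not(input_size %% 4 == 0, "`input_size` must be divisible by 4")
  layers <- list(
    list(id = "conv1", role = "conv", out_channels = conv_channels[1]),
    list(id = "act1", role = "activation_site", n_channels = conv_channels[1]),
    list(id = "pool1", role = "pooling"),
    list(id = "conv2", role = "conv", out_channels = conv_channels[2]),
    list(id = "act2", role = "activation_site", n_channels = conv_channels[2]),
    list(id = "pool2", role = "pooling"),
    list(id = "fc1", role = "fully_connected", units = fc_units),
    list(id = "act3", role = "activation_site", n_channels = fc_units),
    list(id = "head", role = "classifier_head", units = n_classes)
  )
  new_layer_graph(layers, input_shape = c(input_size, input_size, in_channels))
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph | %d layers | input %s>\n", length(x$layers),
              paste(x$input_shape, collapse = "x")))
  for (l in x$layers) cat(sprintf("  %-6s %s\n", l$id, l$role))
  invisible(x)
}

#' Enumerate the activation sites of a graph
#'
#' @param graph A `layer_graph`.
#' @return A data frame with columns `site_id`, `layer_index`,
#'   `n_channels`, in stable layer order.
#' @export
enumerate_activation_sites <- function(graph) {
  stop_if_not(inherits(graph, "layer_graph"), "expected a layer_graph")
  idx <- which(vapply(graph$layers, `[[`, "", "role") == "activation_site")
  stop_if_not(length(idx) > 0L, "graph has no activation sites")
  data.frame(site_id = vapply(graph$layers[idx], `[[`, "", "id"),
             layer_index = idx,
             n_channels = vapply(graph$layers[idx], function(l) as.integer(l$n_channels),
                                 integer(1)),
             stringsAsFactors = FALSE)
}

#' Sample a stochastic activation-replacement plan
#'
#' Assigns an activation spec from `pool` to every activation site of the
#' graph. With `granularity = "per_layer"` each site's spec is drawn
#' independently and uniformly from the pool; with `"per_network"` one
#' uniform draw is applied to all sites. Identical seeds give identical
#' plans.
#'
#' @param graph A `layer_graph`.
#' @param pool Non-empty list of [activation_spec()] objects.
#' @param granularity `"per_layer"` (default) or `"per_network"`.
#' @param seed Integer seed.
#' @return An object of class `replacement_plan`: list with
#'   `site_assignments` (named list site id -> spec), `granularity`,
#'   `pool`, `seed`.
#' @export
sample_replacement_plan <- function(graph, pool,
                                    granularity = c("per_layer", "per_network"),
                                    seed = 1L) {
  granularity <- match.arg(granularity)
  stop_if_not(length(pool) > 0L, "activation pool must be non-empty")
  for (sp in pool) stop_if_not(inherits(sp, "activation_spec"),
                               "pool entries must be activation_spec objects")
  sites <- enumerate_activation_sites(graph)
  draws <- with_seed(seed, {
    if (granularity == "per_network")
      rep(sample.int(length(pool), 1L), nrow(sites))
    else
      sample.int(length(pool), nrow(sites), replace = TRUE)
  })
  assignments <- stats::setNames(pool[draws], sites$site_id)
  structure(list(site_assignments = assignments, granularity = granularity,
                 pool = pool, seed = as.integer(seed)),
            class = "replacement_plan")
}

#' Build a uniform (single-activation) plan
#'
#' Convenience constructor assigning the same spec to every site, e.g. the
#' all-ReLU baseline plan.
#'
#' @param graph A `layer_graph`.
#' @param spec An [activation_spec()].
#' @return A `replacement_plan`.
#' @export
uniform_plan <- function(graph, spec = activation_spec("relu")) {
  sites <- enumerate_activation_sites(graph)
  structure(list(site_assignments = stats::setNames(rep(list(spec), nrow(sites)),
                                                    sites$site_id),
                 granularity = "per_network", pool = list(spec), seed = NA_integer_),
            class = "replacement_plan")
}

#' @export
print.replacement_plan <- function(x, ...) {
  cat(sprintf("<replacement_plan | %s | %d sites>\n", x$granularity,
              length(x$site_assignments)))
  for (id in names(x$site_assignments)) {
    sp <- x$site_assignments[[id]]
    cat(sprintf("  %-6s -> %s (max_input %g)\n", id, sp$kind, sp$max_input))
  }
  invisible(x)
}

#' Apply a replacement plan to a graph
#'
#' Instantiates per-channel learnable activation parameters (via
#' [init_params()]) at every activation site according to the plan. Site
#' seeds are derived deterministically from `seed`, so the same call is
#' bit-reproducible. Non-site layers are untouched; tensor shapes are
#' unchanged, and a plan assigning only ladder-based kinds leaves the
#' freshly initialized network functionally identical to the all-ReLU
#' graph.
#'
#' @param graph A `layer_graph`.
#' @param plan A `replacement_plan` covering every site of `graph`.
#' @param seed Integer seed for parameter initialization.
#' @return The graph with each activation-site layer augmented by `spec`
#'   and `params` fields.
#' @export
apply_plan <- function(graph, plan, seed = 1L) {
  stop_if_not(inherits(plan, "replacement_plan"), "expected a replacement_plan")
  sites <- enumerate_activation_sites(graph)
  missing <- setdiff(sites$site_id, names(plan$site_assignments))
  stop_if_not(length(missing) == 0L,
              sprintf("plan does not cover site(s): %s", paste(missing, collapse = ", ")))
  site_seeds <- derive_seeds(seed, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    li <- sites$layer_index[i]
    sp <- plan$site_assignments[[sites$site_id[i]]]
    graph$layers[[li]]$spec <- sp
    graph$layers[[li]]$params <- init_params(sp, sites$n_channels[i],
                                             seed = site_seeds[i])
  }
  graph
}

#' Serialize / deserialize a replacement plan
#'
#' Plans are written as JSON text mapping each site id to its activation
#' name and hyperparameters, enabling exact experiment replay.
#'
#' @param plan A `replacement_plan`.
#' @param path File path.
#' @return `write_plan` returns `path` invisibly; `read_plan` returns a
#'   `replacement_plan` (with an empty pool, sufficient for [apply_plan()]).
#' @export
write_plan <- function(plan, path) {
  enc <- lapply(plan$site_assignments, function(sp)
    list(kind = sp$kind, k = sp$k, max_input = sp$max_input,
         constants = sp$constants))
  jsonlite::write_json(list(granularity = plan$granularity, seed = plan$seed,
                            sites = enc),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path)
  assignments <- lapply(obj$sites, function(e)
    activation_spec(e$kind, k = e$k, max_input = as.numeric(e$max_input),
                    constants = lapply(e$constants, function(v)
                      if (is.integer(v)) as.numeric(v) else v)))
  structure(list(site_assignments = assignments,
                 granularity = obj$granularity,
                 pool = unique(assignments),
                 seed = obj$seed %||% NA_integer_),
            class = "replacement_plan")
}

#' Preset activation pools for stochastic ensembles
#'
#' Named pools used by the stochastic replacement recipes (all at
#' `max_input = 255` unless overridden): `stoc1` is the nine-function
#' ladder-heavy pool (MeLU k=8/k=4, Leaky ReLU, ELU, PReLU, SReLU, APLU,
#' GaLU, Small GaLU); `stoc2` adds ReLU, Soft Learnable, PDELU, learnable
#' Mish, SRS, learnable Swish and Swish; `stoc3` is `stoc2` without the
#' MeLU/GaLU family; `stoc4` defaults to the `stoc2` pool.
#'
#' @param name One of `"stoc1"`, `"stoc2"`, `"stoc3"`, `"stoc4"`.
#' @param max_input Input scale passed to each member spec.
#' @return List of [activation_spec()] objects.
#' @export
activation_pool <- function(name = c("stoc1", "stoc2", "stoc3", "stoc4"),
                            max_input = 255) {
  name <- match.arg(name)
  mk <- function(kind, k = NULL) activation_spec(kind, k = k, max_input = max_input)
  stoc1 <- list(mk("melu", 8L), mk("leaky_relu"), mk("elu"), mk("melu", 4L),
                mk("prelu"), mk("srelu"), mk("aplu"), mk("galu"), mk("small_galu"))
  extra <- list(mk("relu"), mk("soft_learnable"), mk("pdelu"),
                mk("mish_learnable"), mk("srs"), mk("swish_learnable"), mk("swish"))
  stoc2 <- c(stoc1, extra)
  if (name == "stoc1") return(stoc1)
  if (name %in% c("stoc2", "stoc4")) return(stoc2)
  drop <- vapply(stoc2, function(sp) sp$kind %in% c("melu", "galu", "small_galu"),
                 logical(1))
  stoc2[!drop]
}
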