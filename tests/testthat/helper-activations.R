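# Shared helpers: randomized activation fixtures and the central
# finite-difference gradient oracle.

# Draw a spec + perturbed parameters + kink-avoiding evaluation points.
draw_activation_case <- function(kind, seed, n_channels = 3L, m = 5L,
                                 max_input = 1) {
  spec <- activation_spec(kind, max_input = max_input)
  params <- init_params(spec, n_channels, seed = seed)
  set.seed(seed + 1L)
  for (nm in names(params)) {
    scale <- if (nm %in% c("b", "t_l", "t_r", "centers")) 0.1 else 0.4
    params[[nm]] <- params[[nm]] + stats::rnorm(length(params[[nm]]), 0, scale)
  }
  if (kind == "srs") {                     # keep well inside the valid region
    params$alpha <- abs(params$alpha) + 1
    params$beta <- abs(params$beta) + 1
  }
  if (kind %in% c("soft_learnable", "soft_learnable2"))
    params$alpha <- abs(params$alpha) + 0.2
  x <- matrix(stats::rnorm(n_channels * m, 0, 1.5 * max_input), n_channels, m)
  for (it in 1:80) {                       # nudge points off subgradient kinks
    d <- kink_distance(spec, params, x)
    if (all(d > 1.5e-3)) break
    x[d <= 1.5e-3] <- x[d <= 1.5e-3] + 4e-3
  }
  list(spec = spec, params = params, x = x)
}

# Max relative error between analytic gradients and central differences
# (h = 1e-6 * max(1, |value|)), over d_input and every learnable parameter.
fd_gradient_error <- function(spec, params, x, upstream = NULL) {
  up <- if (is.null(upstream)) matrix(1, nrow(x), ncol(x)) else upstream
  g <- grad_activation(spec, params, x, up)
  L <- function(p, xx) sum(up * eval_activation(spec, p, xx))
  rel <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))
  err <- 0
  for (i in seq_along(x)) {
    h <- 1e-6 * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    err <- max(err, rel((L(params, xp) - L(params, xm)) / (2 * h), g$d_input[i]))
  }
  for (nm in names(g$d_params)) {
    for (i in seq_along(params[[nm]])) {
      h <- 1e-6 * max(1, abs(params[[nm]][i]))
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      err <- max(err, rel((L(pp, x) - L(pm, x)) / (2 * h), g$d_params[[nm]][i]))
    }
  }
  err
}

# Small 4-class blob datasets reused by training/ensemble tests.
toy_train_set <- function(seed = 10L, spc = 40L, sigma = 0.5)
  make_toy_dataset(toy_spec(4L, spc, 32L, sigma = sigma, seed = seed))

toy_test_set <- function(seed = 99L, spc = 25L, sigma = 0.5)
  make_toy_dataset(toy_spec(4L, spc, 32L, sigma = sigma, seed = seed))
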