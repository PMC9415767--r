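#' Activation function specifications
#'
#' An `activation_spec` is an immutable description of one activation kind
#' together with its fixed hyperparameters: the hat-count order `k` for the
#' MeLU/GaLU family, the input scale `max_input` (1, 255 or 256 in typical
#' use), and any fixed scalar constants the kind's formula references
#' (leaky slope, ELU scale, PDELU deformation `t`, fixed Swish `beta`,
#' APLU hinge count, SReLU preset, ...). Learnable per-channel parameters
#' live in a separate [init_params()] object.
#'
#' @param kind One of the names returned by [activation_kinds()].
#' @param k Hat-count order for ladder-based kinds (2, 4 or 8); defaults
#'   per kind (MeLU 8, GaLU 4, Small GaLU 2, 2D MeLU 4).
#' @param max_input Positive input scale; scales the hat ladders and the
#'   APLU hinge-initialization range linearly.
#' @param constants Named list overriding the kind's fixed scalars.
#' @return An object of class `activation_spec`.
#' @examples
#' activation_spec("melu", k = 8, max_input = 255)
#' activation_spec("leaky_relu")$constants$a  # 0.01
#' @export
activation_spec <- function(kind, k = NULL, max_input = 1, constants = list()) {
  reg <- act_registry()
  stop_if_not(kind %in% names(reg), sprintf("unknown activation kind '%s'", kind))
  stop_if_not(is.numeric(max_input) && length(max_input) == 1L && max_input > 0,
              "`max_input` must be a positive scalar")
  entry <- reg[[kind]]
  k <- k %||% entry$default_k
  if (!is.null(k)) {
    stop_if_not(k %in% c(2L, 4L, 8L), "`k` must be one of 2, 4, 8")
    k <- as.integer(k)
  }
  const <- utils::modifyList(entry$default_constants, constants)
  structure(list(kind = kind, k = k, max_input = max_input, constants = const),
            class = "activation_spec")
}

#' @export
print.activation_spec <- function(x, ...) {
  cat(sprintf("<activation_spec %s | k = %s | max_input = %g>\n",
              x$kind, ifelse(is.null(x$k), "-", x$k), x$max_input))
  invisible(x)
}

#' List the registered activation kinds
#'
#' @return Character vector of the 25 kind names addressable from
#'   [activation_spec()], configuration files and the command line.
#' @export
activation_kinds <- function() names(act_registry())

#' Names of the learnable parameters of a kind
#'
#' @param spec An [activation_spec()].
#' @return Character vector (empty for fixed activations such as ReLU).
#' @export
learnable_params <- function(spec) {
  stop_if_not(inherits(spec, "activation_spec"), "expected an activation_spec")
  act_registry()[[spec$kind]]$learnable
}

# Ladders used by a ladder-based spec (MeLU basis and/or derived GaLU basis).
spec_ladders <- function(spec) {
  ml <- build_melu_ladder(spec$max_input, spec$k)
  list(melu = ml, galu = derive_galu_ladder(ml))
}

#' Initialize per-channel learnable parameters
#'
#' Initialization follows the conventions under which every ladder-based
#' kind starts as ReLU: all hat coefficients, PReLU/Splash/TanELU/mixing
#' slopes and APLU slopes are zero; APLU and Splash hinge locations are
#' drawn uniformly on `(0, max_input)`; SReLU starts from its operational
#' preset (`a_l = 0.5, a_r = 0.2, t_l = -2, t_r = 1.5`) or, with
#' `constants = list(preset = "reference")`, from
#' `a_l = 0, t_l = 0, t_r = max_input, a_r = 1`; SRS starts at
#' `alpha = 3, beta = 2`; Soft Learnable and Mish/Swish learnable scalars
#' start at 1; Flexible MeLU centers start at the ladder values.
#'
#' @param spec An [activation_spec()].
#' @param n_channels Number of channels (>= 1).
#' @param seed Integer seed driving any random initialization.
#' @return An object of class `channel_params`: a named list of numeric
#'   vectors (length `n_channels`) or matrices (`n_channels x hinges` for
#'   APLU/Splash, `n_channels x (k-1)` hat coefficients,
#'   `n_channels x (k-1)^2` for 2D MeLU).
#' @export
init_params <- function(spec, n_channels, seed = 1L) {
  stop_if_not(inherits(spec, "activation_spec"), "expected an activation_spec")
  stop_if_not(n_channels >= 1L, "`n_channels` must be >= 1")
  entry <- act_registry()[[spec$kind]]
  p <- with_seed(seed, entry$init(spec, as.integer(n_channels)))
  structure(p, class = "channel_params", kind = spec$kind,
            n_channels = as.integer(n_channels))
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf("<channel_params %s | %d channels | params: %s>\n",
              attr(x, "kind"), attr(x, "n_channels"),
              if (length(x)) paste(names(x), collapse = ", ") else "(none)"))
  invisible(x)
}

# Coerce input to a channels-by-points matrix matched against params.
as_channel_matrix <- function(x, n_channels) {
  if (is.matrix(x)) {
    stop_if_not(nrow(x) == n_channels,
                sprintf("input has %d rows but params describe %d channels",
                        nrow(x), n_channels))
    return(x)
  }
  if (n_channels == 1L) return(matrix(as.numeric(x), nrow = 1L))
  stop_if_not(length(x) == n_channels,
              "vector input length must equal the channel count")
  matrix(as.numeric(x), ncol = 1L)
}

check_param_keys <- function(spec, params) {
  stop_if_not(inherits(params, "channel_params"), "expected channel_params")
  stop_if_not(attr(params, "kind") == spec$kind,
              sprintf("params were initialized for kind '%s', not '%s'",
                      attr(params, "kind"), spec$kind))
  want <- sort(act_registry()[[spec$kind]]$learnable)
  have <- sort(names(params) %||% character(0))
  stop_if_not(identical(want, have),
              sprintf("parameter keys {%s} do not match kind '%s' ({%s})",
                      paste(have, collapse = ","), spec$kind,
                      paste(want, collapse = ",")))
  invisible(TRUE)
}

#' Evaluate an activation function
#'
#' Applies the kind's formula channel-wise (or, for 2D MeLU, to cyclic
#' channel pairs) with the per-channel parameters in `params`.
#'
#' @param spec An [activation_spec()].
#' @param params A `channel_params` object from [init_params()] (possibly
#'   with updated values).
#' @param x Numeric matrix with one row per channel (columns are
#'   evaluation points), or a plain vector when `n_channels` is 1.
#' @return Numeric array of the same shape as `x`.
#' @examples
#' sp <- activation_spec("elu")
#' eval_activation(sp, init_params(sp, 1), c(-1, 0, 2))
#' @export
eval_activation <- function(spec, params, x) {
  check_param_keys(spec, params)
  xm <- as_channel_matrix(x, attr(params, "n_channels"))
  y <- act_registry()[[spec$kind]]$fwd(spec, params, xm)
  if (!is.matrix(x)) y <- as.numeric(y)
  y
}

#' Gradients of an activation function
#'
#' Returns the backpropagation bundle for an activation site: the gradient
#' of `sum(upstream * f(x))` with respect to the input (`d_input`, same
#' shape as `x`) and with respect to every learnable parameter
#' (`d_params`, shapes matching `params`). With the default upstream of
#' ones and a single evaluation point this reduces to the pointwise
#' derivatives printed for each kind. At non-differentiable points the
#' derivative of the right-hand branch is used (so the ReLU-family
#' derivative at 0 is 1).
#'
#' @inheritParams eval_activation
#' @param upstream Optional numeric array of the same shape as `x` holding
#'   the upstream gradient; defaults to all ones.
#' @return An object of class `grad_bundle` with elements `d_input` and
#'   `d_params` (a named list whose keys equal [learnable_params()]).
#' @export
grad_activation <- function(spec, params, x, upstream = NULL) {
  check_param_keys(spec, params)
  xm <- as_channel_matrix(x, attr(params, "n_channels"))
  up <- if (is.null(upstream)) matrix(1, nrow(xm), ncol(xm))
        else as_channel_matrix(upstream, attr(params, "n_channels"))
  stop_if_not(all(dim(up) == dim(xm)), "upstream shape must match input")
  g <- act_registry()[[spec$kind]]$bwd(spec, params, xm, up)
  if (!is.matrix(x)) g$d_input <- as.numeric(g$d_input)
  structure(g, class = "grad_bundle")
}

# ---------------------------------------------------------------------------
# Registry. Each entry: default_k, default_constants, learnable, init, fwd,
# bwd. `x` is always a channels-by-points matrix; per-channel parameter
# vectors recycle down columns.
# ---------------------------------------------------------------------------

prelu_fwd <- function(x, c0) x * ((x >= 0) + c0 * (x < 0))
prelu_gx  <- function(x, c0) (x >= 0) + c0 * (x < 0)

zeros <- function(n, m = NULL) if (is.null(m)) numeric(n) else matrix(0, n, m)

# Hat stack of a ladder applied with coefficient matrix cmat (ch x (k-1)).
ladder_sum <- function(x, cmat, ladder, variant) {
  y <- 0
  for (j in seq_along(ladder$centers)) {
    y <- y + cmat[, j] * hat_eval(x, ladder$centers[j], ladder$half_widths[j], variant)
  }
  y
}

ladder_sum_gx <- function(x, cmat, ladder, variant) {
  g <- 0
  for (j in seq_along(ladder$centers)) {
    g <- g + cmat[, j] * hat_grad_x(x, ladder$centers[j], ladder$half_widths[j], variant)
  }
  g
}

act_registry <- local({
  reg <- NULL
  function() {
    if (!is.null(reg)) return(reg)
    r <- list()

    r$relu <- list(
      default_k = NULL, default_constants = list(), learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) pmax(x, 0),
      bwd = function(spec, p, x, up) list(d_input = up * (x >= 0), d_params = list()))

    r$leaky_relu <- list(
      default_k = NULL, default_constants = list(a = 0.01), learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) x * ((x >= 0) + spec$constants$a * (x < 0)),
      bwd = function(spec, p, x, up)
        list(d_input = up * ((x >= 0) + spec$constants$a * (x < 0)), d_params = list()))

    r$prelu <- list(
      default_k = NULL, default_constants = list(), learnable = "c0",
      init = function(spec, n) list(c0 = zeros(n)),
      fwd = function(spec, p, x) prelu_fwd(x, p$c0),
      bwd = function(spec, p, x, up)
        list(d_input = up * prelu_gx(x, p$c0),
             d_params = list(c0 = rowSums(up * x * (x < 0)))))

    r$elu <- list(
      default_k = NULL, default_constants = list(a = 1), learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) {
        neg <- x < 0
        x * (!neg) + spec$constants$a * (exp(pmin(x, 0)) - 1) * neg
      },
      bwd = function(spec, p, x, up) {
        neg <- x < 0
        list(d_input = up * ((!neg) + spec$constants$a * exp(pmin(x, 0)) * neg),
             d_params = list())
      })

    r$selu <- list(
      default_k = NULL,
      default_constants = list(lambda = 1.0507009873554805, alpha = 1.6732632423543772),
      learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) {
        neg <- x < 0
        spec$constants$lambda *
          (x * (!neg) + spec$constants$alpha * (exp(pmin(x, 0)) - 1) * neg)
      },
      bwd = function(spec, p, x, up) {
        neg <- x < 0
        list(d_input = up * spec$constants$lambda *
               ((!neg) + spec$constants$alpha * exp(pmin(x, 0)) * neg),
             d_params = list())
      })

    # negative branch: alpha * ([1 + (1-t) x]_+ ^ (1/(1-t)) - 1); t in (0,1)
    r$pdelu <- list(
      default_k = NULL, default_constants = list(t = 0.9), learnable = "alpha",
      init = function(spec, n) list(alpha = zeros(n)),
      fwd = function(spec, p, x) {
        t <- spec$constants$t; pw <- 1 / (1 - t)
        u <- pmax(1 + (1 - t) * x, 0)
        neg <- x <= 0
        x * (!neg) + p$alpha * (u^pw - 1) * neg
      },
      bwd = function(spec, p, x, up) {
        t <- spec$constants$t; pw <- 1 / (1 - t)
        u <- pmax(1 + (1 - t) * x, 0)
        neg <- x <= 0
        list(d_input = up * ((!neg) + p$alpha * u^(pw - 1) * neg),
             d_params = list(alpha = rowSums(up * (u^pw - 1) * neg)))
      })

    swish_core <- function(x, beta) {
      s <- sigmoid(beta * x)
      list(y = x * s, gx = s + beta * x * s * (1 - s), s = s)
    }
    r$swish <- list(
      default_k = NULL, default_constants = list(beta = 1), learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) swish_core(x, spec$constants$beta)$y,
      bwd = function(spec, p, x, up)
        list(d_input = up * swish_core(x, spec$constants$beta)$gx, d_params = list()))

    r$swish_learnable <- list(
      default_k = NULL, default_constants = list(), learnable = "beta",
      init = function(spec, n) list(beta = rep(1, n)),
      fwd = function(spec, p, x) swish_core(x, p$beta)$y,
      bwd = function(spec, p, x, up) {
        cc <- swish_core(x, p$beta)
        list(d_input = up * cc$gx,
             d_params = list(beta = rowSums(up * x^2 * cc$s * (1 - cc$s))))
      })

    mish_core <- function(x, alpha) {
      sp <- softplus(alpha * x)
      th <- tanh(sp)
      list(y = x * th,
           gx = th + x * (1 - th^2) * alpha * sigmoid(alpha * x),
           galpha = x^2 * (1 - th^2) * sigmoid(alpha * x))
    }
    r$mish <- list(
      default_k = NULL, default_constants = list(alpha = 1), learnable = character(0),
      init = function(spec, n) list(),
      fwd = function(spec, p, x) mish_core(x, spec$constants$alpha)$y,
      bwd = function(spec, p, x, up)
        list(d_input = up * mish_core(x, spec$constants$alpha)$gx, d_params = list()))

    r$mish_learnable <- list(
      default_k = NULL, default_constants = list(), learnable = "alpha",
      init = function(spec, n) list(alpha = rep(1, n)),
      fwd = function(spec, p, x) mish_core(x, p$alpha)$y,
      bwd = function(spec, p, x, up) {
        cc <- mish_core(x, p$alpha)
        list(d_input = up * cc$gx,
             d_params = list(alpha = rowSums(up * cc$galpha)))
      })

    r$tanelu <- list(
      default_k = NULL, default_constants = list(), learnable = "a",
      init = function(spec, n) list(a = zeros(n)),
      fwd = function(spec, p, x) pmax(x, 0) + p$a * tanh(x),
      bwd = function(spec, p, x, up)
        list(d_input = up * ((x >= 0) + p$a * (1 - tanh(x)^2)),
             d_params = list(a = rowSums(up * tanh(x)))))

    r$srelu <- list(
      default_k = NULL, default_constants = list(preset = "operational"),
      learnable = c("a_l", "a_r", "t_l", "t_r"),
      init = function(spec, n) {
        if (identical(spec$constants$preset, "reference"))
          list(a_l = zeros(n), a_r = rep(1, n), t_l = zeros(n),
               t_r = rep(spec$max_input, n))
        else
          list(a_l = rep(0.5, n), a_r = rep(0.2, n), t_l = rep(-2, n),
               t_r = rep(1.5, n))
      },
      fwd = function(spec, p, x) {
        L <- x <= p$t_l; R <- x >= p$t_r; M <- !(L | R)
        (p$t_l + p$a_l * (x - p$t_l)) * L + x * M + (p$t_r + p$a_r * (x - p$t_r)) * R
      },
      bwd = function(spec, p, x, up) {
        L <- x <= p$t_l; R <- x >= p$t_r; M <- !(L | R)
        list(d_input = up * (p$a_l * L + M + p$a_r * R),
             d_params = list(a_l = rowSums(up * (x - p$t_l) * L),
                             a_r = rowSums(up * (x - p$t_r) * R),
                             t_l = rowSums(up * (1 - p$a_l) * L),
                             t_r = rowSums(up * (1 - p$a_r) * R)))
      })

    # ReLU(x) + sum_h a_h * max(0, b_h - x); hinge h active for x < b_h
    r$aplu <- list(
      default_k = NULL, default_constants = list(n_hinges = 5), learnable = c("a", "b"),
      init = function(spec, n) {
        nh <- spec$constants$n_hinges
        list(a = zeros(n, nh),
             b = matrix(stats::runif(n * nh, 0, spec$max_input), n, nh))
      },
      fwd = function(spec, p, x) {
        y <- pmax(x, 0)
        for (h in seq_len(ncol(p$a))) y <- y + p$a[, h] * pmax(p$b[, h] - x, 0)
        y
      },
      bwd = function(spec, p, x, up) {
        gx <- (x >= 0) * 1
        da <- p$a; db <- p$b
        for (h in seq_len(ncol(p$a))) {
          act <- x < p$b[, h]
          gx <- gx - p$a[, h] * act
          da[, h] <- rowSums(up * pmax(p$b[, h] - x, 0))
          db[, h] <- rowSums(up * p$a[, h] * act)
        }
        list(d_input = up * gx, d_params = list(a = da, b = db))
      })

    # APLU(a+, b)(x) + APLU(a-, b)(-x); hinges shared, mirrored at -b
    r$splash <- list(
      default_k = NULL, default_constants = list(n_hinges = 5),
      learnable = c("a_pos", "a_neg", "b"),
      init = function(spec, n) {
        nh <- spec$constants$n_hinges
        list(a_pos = zeros(n, nh), a_neg = zeros(n, nh),
             b = matrix(stats::runif(n * nh, 0, spec$max_input), n, nh))
      },
      fwd = function(spec, p, x) {
        y <- pmax(x, 0) + pmax(-x, 0)
        for (h in seq_len(ncol(p$b))) {
          y <- y + p$a_pos[, h] * pmax(p$b[, h] - x, 0) +
            p$a_neg[, h] * pmax(p$b[, h] + x, 0)
        }
        y
      },
      bwd = function(spec, p, x, up) {
        gx <- (x >= 0) - (-x >= 0)
        dap <- p$a_pos; dan <- p$a_neg; db <- p$b
        for (h in seq_len(ncol(p$b))) {
          actp <- x < p$b[, h]; actn <- -x < p$b[, h]
          gx <- gx - p$a_pos[, h] * actp + p$a_neg[, h] * actn
          dap[, h] <- rowSums(up * pmax(p$b[, h] - x, 0))
          dan[, h] <- rowSums(up * pmax(p$b[, h] + x, 0))
          db[, h] <- rowSums(up * (p$a_pos[, h] * actp + p$a_neg[, h] * actn))
        }
        list(d_input = up * gx, d_params = list(a_pos = dap, a_neg = dan, b = db))
      })

    # x / (x/alpha + exp(-x/beta)); alpha, beta kept >= eps by the optimizer
    r$srs <- list(
      default_k = NULL, default_constants = list(eps = 1e-6), learnable = c("alpha", "beta"),
      init = function(spec, n) list(alpha = rep(3, n), beta = rep(2, n)),
      fwd = function(spec, p, x) x / (x / p$alpha + exp(-x / p$beta)),
      bwd = function(spec, p, x, up) {
        e <- exp(-x / p$beta)
        D <- x / p$alpha + e
        list(d_input = up * e * (1 + x / p$beta) / D^2,
             d_params = list(alpha = rowSums(up * x^2 / (p$alpha^2 * D^2)),
                             beta = rowSums(-up * x^2 * e / (p$beta^2 * D^2))))
      })

    soft_fwd <- function(x, alpha, beta) {
      neg <- x <= 0
      x * (!neg) + alpha * (log1p(exp(beta * pmin(x, 0))) - log(2)) * neg
    }
    soft_bwd <- function(x, alpha, beta, up, learn_beta) {
      neg <- x <= 0
      dp <- list(alpha = rowSums(up * (log1p(exp(beta * pmin(x, 0))) - log(2)) * neg))
      if (learn_beta)
        dp$beta <- rowSums(up * alpha * x * sigmoid(beta * x) * neg)
      list(d_input = up * ((!neg) + alpha * beta * sigmoid(beta * x) * neg),
           d_params = dp)
    }
    r$soft_learnable <- list(
      default_k = NULL, default_constants = list(beta = 1), learnable = "alpha",
      init = function(spec, n) list(alpha = rep(1, n)),
      fwd = function(spec, p, x) soft_fwd(x, p$alpha, spec$constants$beta),
      bwd = function(spec, p, x, up)
        soft_bwd(x, p$alpha, spec$constants$beta, up, FALSE))

    r$soft_learnable2 <- list(
      default_k = NULL, default_constants = list(), learnable = c("alpha", "beta"),
      init = function(spec, n) list(alpha = rep(1, n), beta = rep(1, n)),
      fwd = function(spec, p, x) soft_fwd(x, p$alpha, p$beta),
      bwd = function(spec, p, x, up) soft_bwd(x, p$alpha, p$beta, up, TRUE))

    # --- MeLU/GaLU family -------------------------------------------------
    melu_like <- function(default_k, which_ladder, variant) {
      list(
        default_k = default_k, default_constants = list(), learnable = c("c0", "c"),
        init = function(spec, n) list(c0 = zeros(n), c = zeros(n, spec$k - 1L)),
        fwd = function(spec, p, x) {
          lad <- spec_ladders(spec)[[which_ladder]]
          prelu_fwd(x, p$c0) + ladder_sum(x, p$c, lad, variant)
        },
        bwd = function(spec, p, x, up) {
          lad <- spec_ladders(spec)[[which_ladder]]
          dc <- p$c
          for (j in seq_along(lad$centers))
            dc[, j] <- rowSums(up * hat_eval(x, lad$centers[j], lad$half_widths[j], variant))
          list(d_input = up * (prelu_gx(x, p$c0) + ladder_sum_gx(x, p$c, lad, variant)),
               d_params = list(c0 = rowSums(up * x * (x < 0)), c = dc))
        })
    }
    r$melu <- melu_like(8L, "melu", "mexican")
    r$galu <- melu_like(4L, "galu", "gaussian")
    r$small_galu <- melu_like(2L, "galu", "gaussian")

    # (1 - a) MeLU + a GaLU with shared c0/c_j over both hat bases
    r$melu_plus_galu <- list(
      default_k = 8L, default_constants = list(), learnable = c("a", "c0", "c"),
      init = function(spec, n)
        list(a = zeros(n), c0 = zeros(n), c = zeros(n, spec$k - 1L)),
      fwd = function(spec, p, x) {
        lads <- spec_ladders(spec)
        prelu_fwd(x, p$c0) + (1 - p$a) * ladder_sum(x, p$c, lads$melu, "mexican") +
          p$a * ladder_sum(x, p$c, lads$galu, "gaussian")
      },
      bwd = function(spec, p, x, up) {
        lads <- spec_ladders(spec)
        dc <- p$c; da <- 0
        for (j in seq_along(lads$melu$centers)) {
          phm <- hat_eval(x, lads$melu$centers[j], lads$melu$half_widths[j], "mexican")
          phg <- hat_eval(x, lads$galu$centers[j], lads$galu$half_widths[j], "gaussian")
          dc[, j] <- rowSums(up * ((1 - p$a) * phm + p$a * phg))
          da <- da + up * p$c[, j] * (phg - phm)
        }
        gx <- prelu_gx(x, p$c0) +
          (1 - p$a) * ladder_sum_gx(x, p$c, lads$melu, "mexican") +
          p$a * ladder_sum_gx(x, p$c, lads$galu, "gaussian")
        list(d_input = up * gx,
             d_params = list(a = rowSums(da), c0 = rowSums(up * x * (x < 0)), c = dc))
      })

    # f(x) + f(-x) with shared coefficients; |x| at init
    symmetric_like <- function(default_k, which_ladder, variant) {
      list(
        default_k = default_k, default_constants = list(), learnable = c("c0", "c"),
        init = function(spec, n) list(c0 = zeros(n), c = zeros(n, spec$k - 1L)),
        fwd = function(spec, p, x) {
          lad <- spec_ladders(spec)[[which_ladder]]
          prelu_fwd(x, p$c0) + prelu_fwd(-x, p$c0) +
            ladder_sum(x, p$c, lad, variant) + ladder_sum(-x, p$c, lad, variant)
        },
        bwd = function(spec, p, x, up) {
          lad <- spec_ladders(spec)[[which_ladder]]
          dc <- p$c
          for (j in seq_along(lad$centers)) {
            dc[, j] <- rowSums(up * (hat_eval(x, lad$centers[j], lad$half_widths[j], variant) +
                                     hat_eval(-x, lad$centers[j], lad$half_widths[j], variant)))
          }
          gx <- prelu_gx(x, p$c0) - prelu_gx(-x, p$c0) +
            ladder_sum_gx(x, p$c, lad, variant) - ladder_sum_gx(-x, p$c, lad, variant)
          list(d_input = up * gx,
               d_params = list(c0 = rowSums(up * (x * (x < 0) - x * (-x < 0))), c = dc))
        })
    }
    r$symmetric_melu <- symmetric_like(8L, "melu", "mexican")
    r$symmetric_galu <- symmetric_like(4L, "galu", "gaussian")

    # MeLU with learnable per-channel hat centers (half-widths fixed)
    r$flexible_melu <- list(
      default_k = 8L, default_constants = list(), learnable = c("c0", "c", "centers"),
      init = function(spec, n) {
        lad <- spec_ladders(spec)$melu
        list(c0 = zeros(n), c = zeros(n, spec$k - 1L),
             centers = matrix(lad$centers, n, spec$k - 1L, byrow = TRUE))
      },
      fwd = function(spec, p, x) {
        lad <- spec_ladders(spec)$melu
        y <- prelu_fwd(x, p$c0)
        for (j in seq_along(lad$half_widths))
          y <- y + p$c[, j] * pmax(lad$half_widths[j] - abs(x - p$centers[, j]), 0)
        y
      },
      bwd = function(spec, p, x, up) {
        lad <- spec_ladders(spec)$melu
        gx <- prelu_gx(x, p$c0)
        dc <- p$c; dA <- p$centers
        for (j in seq_along(lad$half_widths)) {
          a <- p$centers[, j]; lam <- lad$half_widths[j]
          phi <- pmax(lam - abs(x - a), 0)
          # right-derivative in x; d/da is its negative on the support
          gj <- (x >= a - lam & x < a) - (x >= a & x < a + lam)
          gx <- gx + p$c[, j] * gj
          dc[, j] <- rowSums(up * phi)
          dA[, j] <- rowSums(-up * p$c[, j] * gj)
        }
        list(d_input = up * gx,
             d_params = list(c0 = rowSums(up * x * (x < 0)), c = dc, centers = dA))
      })

    # 2D MeLU: y_i = PReLU(x_i) + PReLU(x_{i+1}) + sum_{u,v} c_uv *
    # max(lambda_{max(u,v)} - ||(x_i, x_{i+1}) - (a_u, a_v)||, 0), cyclic pairs
    r$melu_2d <- list(
      default_k = 4L, default_constants = list(), learnable = c("c0", "c"),
      init = function(spec, n) list(c0 = zeros(n), c = zeros(n, (spec$k - 1L)^2)),
      fwd = function(spec, p, x) {
        lad <- spec_ladders(spec)$melu
        nch <- nrow(x)
        nxt <- c(seq_len(nch)[-1], 1L)
        xn <- x[nxt, , drop = FALSE]
        y <- prelu_fwd(x, p$c0) + prelu_fwd(xn, p$c0)
        km1 <- spec$k - 1L
        for (u in seq_len(km1)) for (v in seq_len(km1)) {
          lam <- lad$half_widths[max(u, v)]
          d <- sqrt((x - lad$centers[u])^2 + (xn - lad$centers[v])^2)
          y <- y + p$c[, (u - 1L) * km1 + v] * pmax(lam - d, 0)
        }
        y
      },
      bwd = function(spec, p, x, up) {
        lad <- spec_ladders(spec)$melu
        nch <- nrow(x)
        nxt <- c(seq_len(nch)[-1], 1L)
        xn <- x[nxt, , drop = FALSE]
        gx <- up * prelu_gx(x, p$c0)          # direct dependence through x_i
        gn <- up * prelu_gx(xn, p$c0)         # dependence through x_{i+1}
        dc <- p$c
        km1 <- spec$k - 1L
        for (u in seq_len(km1)) for (v in seq_len(km1)) {
          lam <- lad$half_widths[max(u, v)]
          dx1 <- x - lad$centers[u]; dx2 <- xn - lad$centers[v]
          d <- sqrt(dx1^2 + dx2^2)
          supp <- d < lam & d > 0
          ds <- ifelse(d > 0, d, 1)
          cj <- p$c[, (u - 1L) * km1 + v]
          gx <- gx - up * cj * (dx1 / ds) * supp
          gn <- gn - up * cj * (dx2 / ds) * supp
          dc[, (u - 1L) * km1 + v] <- rowSums(up * pmax(lam - d, 0))
        }
        d_input <- gx
        d_input[nxt, ] <- d_input[nxt, , drop = FALSE] + gn
        list(d_input = d_input,
             d_params = list(c0 = rowSums(up * (x * (x < 0) + xn * (xn < 0))), c = dc))
      })

    reg <<- r
    reg
  }
})

#' Distance to the nearest non-differentiable point
#'
#' For every entry of `x`, the distance (in input units) to the nearest
#' kink of the activation: branch points at 0, APLU/Splash hinges, hat
#' knots, SReLU thresholds, or (for 2D MeLU) the hat support circles and
#' centers. Smooth kinds return `Inf`. Used to keep finite-difference
#' gradient checks away from subgradient points.
#'
#' @inheritParams eval_activation
#' @return Numeric array shaped like `x`.
#' @keywords internal
#' @export
kink_distance <- function(spec, params, x) {
  xm <- as_channel_matrix(x, attr(params, "n_channels"))
  nch <- nrow(xm)
  kind <- spec$kind
  smooth <- c("swish", "swish_learnable", "mish", "mish_learnable", "srs")
  if (kind %in% smooth) return(array(Inf, dim(xm)))
  if (kind == "melu_2d") {
    lad <- spec_ladders(spec)$melu
    nxt <- c(seq_len(nch)[-1], 1L)
    xn <- xm[nxt, , drop = FALSE]
    dmin <- pmin(abs(xm), abs(xn))
    km1 <- spec$k - 1L
    for (u in seq_len(km1)) for (v in seq_len(km1)) {
      lam <- lad$half_widths[max(u, v)]
      d <- sqrt((xm - lad$centers[u])^2 + (xn - lad$centers[v])^2)
      dmin <- pmin(dmin, abs(d - lam), d)
    }
    # a kink through the pair (x_i, x_{i+1}) affects both channels
    out <- pmin(dmin, dmin[c(nch, seq_len(nch)[-nch]), , drop = FALSE])
    return(out)
  }
  knots_for_channel <- function(ch) {
    ks <- 0
    if (kind %in% c("aplu")) ks <- c(ks, params$b[ch, ])
    if (kind == "splash") ks <- c(ks, params$b[ch, ], -params$b[ch, ])
    if (kind == "srelu") ks <- c(ks, params$t_l[ch], params$t_r[ch])
    lad_knots <- function(lad, variant, centers = lad$centers) {
      kk <- c(centers - lad$half_widths, centers, centers + lad$half_widths)
      if (variant == "gaussian")
        kk <- c(kk, centers + 2 * lad$half_widths, centers + 3 * lad$half_widths)
      kk
    }
    if (kind %in% c("melu", "melu_plus_galu"))
      ks <- c(ks, lad_knots(spec_ladders(spec)$melu, "mexican"))
    if (kind %in% c("galu", "small_galu", "melu_plus_galu"))
      ks <- c(ks, lad_knots(spec_ladders(spec)$galu, "gaussian"))
    if (kind == "flexible_melu") {
      lad <- spec_ladders(spec)$melu
      ks <- c(ks, lad_knots(lad, "mexican", centers = params$centers[ch, ]))
    }
    if (kind %in% c("symmetric_melu", "symmetric_galu")) {
      variant <- if (kind == "symmetric_melu") "mexican" else "gaussian"
      lad <- spec_ladders(spec)[[if (variant == "mexican") "melu" else "galu"]]
      kk <- lad_knots(lad, variant)
      ks <- c(ks, kk, -kk)
    }
    ks
  }
  out <- xm
  for (ch in seq_len(nch)) {
    ks <- knots_for_channel(ch)
    out[ch, ] <- vapply(xm[ch, ], function(v) min(abs(v - ks)), numeric(1))
  }
  out
}
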