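# Minimal CNN engine used for desk-scale experiments. Convolutions are
# 3x3, stride 1, same padding, implemented by im2col + BLAS matmul;
# pooling is 2x2 max. Activation sites dispatch to the activation
# registry, so every learnable-activation gradient flows through
# grad_activation().

# ---- convolution ----------------------------------------------------------

conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Cout <- nrow(W)
  Xp <- array(0, c(H + 2, Wd + 2, C, N))
  Xp[2:(H + 1), 2:(Wd + 1), , ] <- x
  cols <- matrix(0, 9 * C, H * Wd * N)
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    slice <- Xp[(1:H) + dy, (1:Wd) + dx, , , drop = FALSE]
    cols[o * C + seq_len(C), ] <- matrix(aperm(slice, c(3, 1, 2, 4)), nrow = C)
    o <- o + 1L
  }
  out <- W %*% cols + b
  list(y = aperm(array(out, c(Cout, H, Wd, N)), c(2, 3, 1, 4)), cols = cols)
}

conv_backward <- function(dy, cols, W, xdim) {
  H <- xdim[1]; Wd <- xdim[2]; C <- xdim[3]; N <- xdim[4]
  Cout <- nrow(W)
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = Cout)
  dW <- dym %*% t(cols)
  db <- rowSums(dym)
  dcols <- t(W) %*% dym
  dXp <- array(0, c(H + 2, Wd + 2, C, N))
  o <- 0L
  for (dx in 0:2) for (dy_ in 0:2) {
    block <- aperm(array(dcols[o * C + seq_len(C), , drop = FALSE], c(C, H, Wd, N)),
                   c(2, 3, 1, 4))
    dXp[(1:H) + dy_, (1:Wd) + dx, , ] <-
      dXp[(1:H) + dy_, (1:Wd) + dx, , , drop = FALSE] + block
    o <- o + 1L
  }
  list(dx = dXp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE], dW = dW, db = db)
}

# ---- 2x2 max pooling ------------------------------------------------------

pool_forward <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  A <- array(x, c(2, H / 2, 2, Wd / 2, C, N))
  sub <- function(i, j) array(A[i, , j, , , ], c(H / 2, Wd / 2, C, N))
  s <- list(sub(1, 1), sub(2, 1), sub(1, 2), sub(2, 2))
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  masks <- vector("list", 4)
  rem <- array(TRUE, dim(y))
  for (q in 1:4) {                        # route gradient to the first max
    masks[[q]] <- (s[[q]] == y) & rem
    rem <- rem & !masks[[q]]
  }
  list(y = y, masks = masks, xdim = d)
}

pool_backward <- function(dy, cache) {
  d <- cache$xdim; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  dA <- array(0, c(2, H / 2, 2, Wd / 2, C, N))
  ij <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (q in 1:4)
    dA[ij[[q]][1], , ij[[q]][2], , , ] <- dy * cache$masks[[q]]
  array(dA, d)
}

# ---- activation sites -----------------------------------------------------

# Reshape a feature map to a channels-by-points matrix and back.
to_channel_mat <- function(x) {
  if (length(dim(x)) == 4L) {
    d <- dim(x)
    matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
  } else x                                 # fc activations are units x N
}

from_channel_mat <- function(m, template) {
  if (length(dim(template)) == 4L) {
    d <- dim(template)
    aperm(array(m, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  } else m
}

# ---- model ----------------------------------------------------------------

#' Initialize TinyNet weights for an instantiated graph
#'
#' He-style Gaussian initialization for convolution and fully connected
#' weights, zero biases. The graph must already carry activation specs
#' and parameters (see [apply_plan()]).
#'
#' @param graph A `layer_graph` returned by [apply_plan()].
#' @param seed Integer seed.
#' @return A `tiny_model` object (graph + weights).
#' @export
init_model <- function(graph, seed = 1L) {
  d <- graph$input_shape
  H <- d[1]; Wd <- d[2]; C <- d[3]
  weights <- list()
  cur <- c(H, Wd, C)
  with_seed(seed, {
    for (l in graph$layers) {
      if (l$role == "conv") {
        fan_in <- 9 * cur[3]
        weights[[l$id]] <- list(
          W = matrix(stats::rnorm(l$out_channels * fan_in, 0, sqrt(2 / fan_in)),
                     l$out_channels, fan_in),
          b = numeric(l$out_channels))
        cur[3] <- l$out_channels
      } else if (l$role == "pooling") {
        cur[1:2] <- cur[1:2] / 2
      } else if (l$role %in% c("fully_connected", "classifier_head")) {
        fan_in <- prod(cur)
        weights[[l$id]] <- list(
          W = matrix(stats::rnorm(l$units * fan_in, 0, sqrt(2 / fan_in)),
                     l$units, fan_in),
          b = numeric(l$units))
        cur <- l$units
      }
    }
  })
  structure(list(graph = graph, weights = weights), class = "tiny_model")
}

#' @export
print.tiny_model <- function(x, ...) {
  np <- sum(vapply(x$weights, function(w) length(w$W) + length(w$b), numeric(1)))
  cat(sprintf("<tiny_model | %d weight tensors | %d weights>\n",
              length(x$weights), np))
  invisible(x)
}

# Forward pass; with cache = TRUE returns everything backward needs.
model_forward <- function(model, x, cache = FALSE) {
  caches <- list()
  a <- x
  for (l in model$graph$layers) {
    if (l$role == "conv") {
      cf <- conv_forward(a, model$weights[[l$id]]$W, model$weights[[l$id]]$b)
      if (cache) caches[[l$id]] <- list(cols = cf$cols, xdim = dim(a))
      a <- cf$y
    } else if (l$role == "pooling") {
      pf <- pool_forward(a)
      if (cache) caches[[l$id]] <- pf
      a <- pf$y
    } else if (l$role == "activation_site") {
      xm <- to_channel_mat(a)
      ym <- eval_activation(l$spec, l$params, xm)
      if (cache) caches[[l$id]] <- list(xm = xm, template = a)
      a <- from_channel_mat(ym, a)
    } else if (l$role %in% c("fully_connected", "classifier_head")) {
      flat <- if (length(dim(a)) == 4L) matrix(a, ncol = dim(a)[4]) else a
      if (cache) caches[[l$id]] <- list(flat = flat, template = a)
      a <- model$weights[[l$id]]$W %*% flat + model$weights[[l$id]]$b
    }
  }
  # softmax over classes (rows), stable
  z <- sweep(a, 2, apply(a, 2, max))
  p <- exp(z)
  p <- sweep(p, 2, colSums(p), "/")
  list(probs = p, logits = a, caches = caches)
}

# Cross-entropy + activation-regularization loss and full gradient set.
model_backward <- function(model, fw, y, reg_coeff) {
  n <- length(y)
  K <- nrow(fw$probs)
  loss <- -mean(log(pmax(fw$probs[cbind(y, seq_len(n))], 1e-12)))
  dlogits <- fw$probs
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  dlogits <- dlogits / n
  gw <- list(); gact <- list()
  da <- dlogits
  for (li in rev(seq_along(model$graph$layers))) {
    l <- model$graph$layers[[li]]
    if (l$role %in% c("fully_connected", "classifier_head")) {
      cc <- fw$caches[[l$id]]
      gw[[l$id]] <- list(W = da %*% t(cc$flat), b = rowSums(da))
      dflat <- t(model$weights[[l$id]]$W) %*% da
      da <- if (length(dim(cc$template)) == 4L) array(dflat, dim(cc$template)) else dflat
    } else if (l$role == "activation_site") {
      cc <- fw$caches[[l$id]]
      g <- grad_activation(l$spec, l$params, cc$xm, upstream = to_channel_mat(da))
      if (l$spec$kind %in% c("aplu", "splash")) {
        loss <- loss + aplu_regularization(l$params, reg_coeff)
        for (nm in intersect(names(g$d_params), c("a", "a_pos", "a_neg")))
          g$d_params[[nm]] <- g$d_params[[nm]] + 2 * reg_coeff * l$params[[nm]]
      }
      gact[[l$id]] <- g$d_params
      da <- from_channel_mat(g$d_input, cc$template)
    } else if (l$role == "pooling") {
      da <- pool_backward(da, fw$caches[[l$id]])
    } else if (l$role == "conv") {
      cc <- fw$caches[[l$id]]
      cb <- conv_backward(da, cc$cols, model$weights[[l$id]]$W, cc$xdim)
      gw[[l$id]] <- list(W = cb$dW, b = cb$db)
      da <- cb$dx
    }
  }
  list(loss = loss, gw = gw, gact = gact)
}

#' Class probabilities of a trained TinyNet
#'
#' Applies the mean-centering offset learned from the training set (if the
#' model was trained) before the forward pass.
#'
#' @param model A `tiny_model`.
#' @param x Image array `H x W x C x N`.
#' @param model_id Identifier stored on the returned matrix.
#' @return A [probability_matrix()] with one row per sample.
#' @export
predict_model <- function(model, x, model_id = "tiny_model") {
  if (!is.null(model$input_offset)) x <- x - model$input_offset
  p <- model_forward(model, x)$probs
  probability_matrix(t(p), model_id = model_id)
}
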