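#' Toy image-dataset specification
#'
#' Describes a seeded, desk-scale labeled image dataset with a
#' controllable class signal: `"blob"` places a Gaussian intensity blob at
#' a class-specific position, `"texture"` uses a class-specific sinusoid
#' frequency, `"gradient"` a class-specific intensity-gradient
#' orientation. `sigma` is the standard deviation of additive Gaussian
#' pixel noise on the unit intensity range; at `sigma = 0` classes are
#' perfectly separable by their generative parameter.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Images generated per class.
#' @param size Square image side in pixels (>= 16).
#' @param signal One of `"blob"`, `"texture"`, `"gradient"`.
#' @param sigma Nonnegative pixel-noise standard deviation.
#' @param seed Integer seed; all outputs are pure functions of spec+seed.
#' @return A `toy_spec` object.
#' @export
toy_spec <- function(n_classes = 4L, samples_per_class = 50L, size = 32L,
                     signal = c("blob", "texture", "gradient"),
                     sigma = 0.5, seed = 1L) {
  signal <- match.arg(signal)
  stop_if_not(n_classes >= 2L, "`n_classes` must be >= 2")
  stop_if_not(size >= 16L, "`size` must be >= 16 pixels")
  stop_if_not(sigma >= 0, "`sigma` must be nonnegative")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 size = as.integer(size), signal = signal,
                 sigma = sigma, seed = as.integer(seed)),
            class = "toy_spec")
}

# Noiseless class template plus per-sample nuisance draws (which use the
# active RNG stream): blob position jitter / sinusoid phase / gradient
# intensity jitter.
toy_image <- function(spec, class_idx) {
  s <- spec$size
  gx <- matrix(rep(seq_len(s), s), s, s)          # column index
  gy <- t(gx)                                     # row index
  if (spec$signal == "blob") {
    theta <- 2 * pi * (class_idx - 1) / spec$n_classes + pi / 4
    cx <- s / 2 + 0.28 * s * cos(theta) + stats::rnorm(1, 0, 1)
    cy <- s / 2 + 0.28 * s * sin(theta) + stats::rnorm(1, 0, 1)
    bw <- 0.12 * s
    img <- 0.5 + 0.5 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * bw^2))
  } else if (spec$signal == "texture") {
    freq <- 1.5 + 1.5 * class_idx                  # cycles per image
    phase <- stats::runif(1, 0, pi / 4)            # bounded nuisance jitter
    img <- 0.5 + 0.4 * sin(2 * pi * freq * gx / s + phase)
  } else {
    theta <- pi * (class_idx - 1) / spec$n_classes
    proj <- (cos(theta) * gx + sin(theta) * gy) / s
    proj <- (proj - min(proj)) / (max(proj) - min(proj))
    img <- 0.1 + 0.8 * proj * stats::runif(1, 0.9, 1.1)
  }
  img
}

#' Generate a toy image dataset
#'
#' Produces `n_classes * samples_per_class` grayscale images according to
#' the spec. When `dir` is given, writes the standard per-class PNG layout
#' `<dir>/<class_name>/<sample_id>.png` plus a `labels.csv` manifest
#' (columns `file`, `class`); identical spec+seed give byte-identical
#' trees. Pixel values are quantized to 8 bits so the in-memory data equal
#' what [load_image_dataset()] reads back.
#'
#' @param spec A [toy_spec()].
#' @param dir Optional output directory (created if needed).
#' @return (Invisibly when writing) a list with `x`
#'   (`size x size x 1 x N` array), `y` (integer labels), `classes`.
#' @export
make_toy_dataset <- function(spec, dir = NULL) {
  stop_if_not(inherits(spec, "toy_spec"), "expected a toy_spec")
  n <- spec$n_classes * spec$samples_per_class
  x <- array(0, c(spec$size, spec$size, 1L, n))
  y <- integer(n)
  classes <- sprintf("class_%02d", seq_len(spec$n_classes))
  with_seed(spec$seed, {
    i <- 0L
    for (ci in seq_len(spec$n_classes)) {
      for (si in seq_len(spec$samples_per_class)) {
        i <- i + 1L
        img <- toy_image(spec, ci)
        if (spec$sigma > 0)
          img <- img + matrix(stats::rnorm(spec$size^2, 0, spec$sigma),
                              spec$size, spec$size)
        img <- pmin(pmax(img, 0), 1)
        x[, , 1L, i] <- round(img * 255) / 255
        y[i] <- ci
      }
    }
  })
  out <- list(x = x, y = y, classes = classes)
  if (!is.null(dir)) {
    manifest <- data.frame(file = character(n), class = character(n))
    for (ci in seq_len(spec$n_classes))
      dir.create(file.path(dir, classes[ci]), recursive = TRUE, showWarnings = FALSE)
    counters <- integer(spec$n_classes)
    for (i in seq_len(n)) {
      ci <- y[i]
      counters[ci] <- counters[ci] + 1L
      rel <- file.path(classes[ci], sprintf("sample_%03d.png", counters[ci]))
      png::writePNG(x[, , 1L, i], file.path(dir, rel))
      manifest$file[i] <- rel
      manifest$class[i] <- classes[ci]
    }
    utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Synthetic probability-matrix fixtures
#'
#' Generates labeled class-probability matrices with prescribed argmax
#' accuracies, for exercising fusion and selection without any training.
#' Exactly `round(target * n_samples)` rows of each matrix have their
#' argmax at the true label, so realized accuracy matches the target to
#' rounding.
#'
#' @param n_models Number of matrices.
#' @param n_samples Rows per matrix.
#' @param n_classes Columns per matrix.
#' @param targets Numeric vector (length `n_models`) of accuracy targets
#'   in `[1/n_classes, 1]`.
#' @param seed Integer seed.
#' @return List with `probs` (list of `probability_matrix`) and `labels`
#'   (integer vector).
#' @export
make_probability_fixtures <- function(n_models, n_samples, n_classes,
                                      targets, seed = 1L) {
  stop_if_not(length(targets) == n_models, "need one target per model")
  stop_if_not(all(targets >= 1 / n_classes - 1e-12 & targets <= 1),
              "targets must lie in [1/n_classes, 1]")
  with_seed(seed, {
    labels <- sample.int(n_classes, n_samples, replace = TRUE)
    probs <- lapply(seq_len(n_models), function(mi) {
      m <- matrix(0, n_samples, n_classes)
      correct <- sample.int(n_samples, round(targets[mi] * n_samples))
      for (i in seq_len(n_samples)) {
        winner <- if (i %in% correct) labels[i]
                  else sample(setdiff(seq_len(n_classes), labels[i]), 1L)
        top <- stats::runif(1, 0.55, 0.9)
        rest <- stats::rgamma(n_classes - 1L, 1)
        m[i, -winner] <- (1 - top) * rest / sum(rest)
        m[i, winner] <- top
      }
      probability_matrix(m, model_id = sprintf("fixture_%02d", mi))
    })
    list(probs = probs, labels = labels)
  })
}
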