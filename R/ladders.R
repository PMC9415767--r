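#' Fixed Mexican-hat parameter ladders
#'
#' The MeLU/GaLU activation families are built on a fixed hierarchy of
#' triangular "Mexican hat" bumps on the input range `[0, 4 * max_input]`.
#' The ladder is constructed recursively, breadth-first by dyadic level:
#' the first hat peaks at `2 * max_input` and vanishes at `0` and
#' `4 * max_input`; the next two hats peak at `max_input` and
#' `3 * max_input` and are supported on the two halves of the range; each
#' further level halves the half-width again. `k - 1` hats are used for a
#' ladder of order `k`.
#'
#' @param max_input Positive scalar: the assumed input scale of the
#'   activation (typically 1, 255 or 256). Ladders scale linearly in it.
#' @param k Hat-count order; one of 2, 4 or 8, giving `k - 1` hats.
#' @return An object of class `parameter_ladder`: a list with numeric
#'   vectors `centers` and `half_widths` (length `k - 1`) and the
#'   `max_input` used.
#' @examples
#' build_melu_ladder(256, 8)$centers  # 512 256 768 128 384 640 896
#' @export
build_melu_ladder <- function(max_input, k = 8L) {
  stop_if_not(is.numeric(max_input) && length(max_input) == 1L && max_input > 0,
              "`max_input` must be a positive scalar")
  stop_if_not(k %in% c(2L, 4L, 8L), "`k` must be one of 2, 4, 8")
  m <- max_input
  # breadth-first dyadic construction: level l has 2^(l-1) hats of
  # half-width 4*m / 2^l, peaking at the odd multiples of that half-width
  centers <- numeric(0)
  half_widths <- numeric(0)
  level <- 1L
  while (length(centers) < k - 1L) {
    hw <- 4 * m / 2^level
    cs <- hw * seq(1, by = 2, length.out = 2^(level - 1L))
    centers <- c(centers, cs)
    half_widths <- c(half_widths, rep(hw, length(cs)))
    level <- level + 1L
  }
  new_parameter_ladder(centers[seq_len(k - 1L)], half_widths[seq_len(k - 1L)],
                       max_input)
}

new_parameter_ladder <- function(centers, half_widths, max_input) {
  stop_if_not(length(centers) == length(half_widths),
              "centers and half-widths must have equal length")
  stop_if_not(all(half_widths > 0), "all half-widths must be positive")
  structure(list(centers = as.numeric(centers),
                 half_widths = as.numeric(half_widths),
                 max_input = as.numeric(max_input)),
            class = "parameter_ladder")
}

#' Derive the GaLU ladder from a MeLU ladder
#'
#' GaLU uses Gaussian-type hats (an up-triangle followed by a zero-mean
#' down-triangle) on a ladder obtained from the MeLU ladder by halving
#' every half-width and shifting each center left by the new half-width,
#' so the up-bump of the Gaussian hat occupies the left half of the
#' original Mexican-hat support.
#'
#' @param melu_ladder A `parameter_ladder` from [build_melu_ladder()].
#' @return A `parameter_ladder` with transformed centers and half-widths.
#' @examples
#' derive_galu_ladder(build_melu_ladder(1, 8))$centers
#' @export
derive_galu_ladder <- function(melu_ladder) {
  stop_if_not(inherits(melu_ladder, "parameter_ladder"), "expected a parameter_ladder")
  stop_if_not(length(melu_ladder$centers) >= 1L, "empty ladder")
  hw <- melu_ladder$half_widths / 2
  new_parameter_ladder(melu_ladder$centers - hw, hw, melu_ladder$max_input)
}

#' Evaluate a single hat basis function
#'
#' The Mexican variant is the triangular bump
#' `max(lambda - |x - a|, 0)`; the Gaussian variant adds the mirrored
#' down-bump `min(|x - a - 2*lambda| - lambda, 0)`, giving a zero-mean
#' function supported on `[a - lambda, a + 3*lambda]`.
#'
#' @param x Numeric vector of evaluation points.
#' @param a Hat center.
#' @param lambda Positive half-width.
#' @param variant `"mexican"` or `"gaussian"`.
#' @return Numeric vector of hat values.
#' @export
hat_eval <- function(x, a, lambda, variant = c("mexican", "gaussian")) {
  variant <- match.arg(variant)
  stop_if_not(is.numeric(lambda) && all(lambda > 0), "`lambda` must be positive")
  up <- pmax(lambda - abs(x - a), 0)
  if (variant == "mexican") return(up)
  up + pmin(abs(x - a - 2 * lambda) - lambda, 0)
}

# Right-derivative of a hat w.r.t. x (convention: at every kink the
# derivative of the branch to the right is used). Vectorized over matrices.
hat_grad_x <- function(x, a, lambda, variant = c("mexican", "gaussian")) {
  variant <- match.arg(variant)
  g <- (x >= a - lambda & x < a) - (x >= a & x < a + lambda)
  if (variant == "gaussian") {
    g <- g - (x >= a + lambda & x < a + 2 * lambda) +
      (x >= a + 2 * lambda & x < a + 3 * lambda)
  }
  g
}

#' @export
print.parameter_ladder <- function(x, ...) {
  cat(sprintf("Hat parameter ladder (max_input = %g, %d hats)\n",
              x$max_input, length(x$centers)))
  print(data.frame(j = seq_along(x$centers), a_j = x$centers,
                   lambda_j = x$half_widths), row.names = FALSE)
  invisible(x)
}

#' Read/write a parameter ladder as CSV
#'
#' The CSV layout has columns `j`, `a_j`, `lambda_j`, one row per hat.
#'
#' @param ladder A `parameter_ladder`.
#' @param path File path.
#' @param max_input Input scale recorded in the reconstructed ladder
#'   (defaults to 1 on read; the CSV stores only the hat parameters).
#' @return `write_ladder_csv` returns `path` invisibly; `read_ladder_csv`
#'   returns a `parameter_ladder`.
#' @export
write_ladder_csv <- function(ladder, path) {
  stop_if_not(inherits(ladder, "parameter_ladder"), "expected a parameter_ladder")
  utils::write.csv(data.frame(j = seq_along(ladder$centers),
                              a_j = ladder$centers,
                              lambda_j = ladder$half_widths),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ladder_csv
#' @export
read_ladder_csv <- function(path, max_input = 1) {
  df <- utils::read.csv(path)
  stop_if_not(all(c("j", "a_j", "lambda_j") %in% names(df)),
              "ladder CSV needs columns j, a_j, lambda_j")
  df <- df[order(df$j), ]
  new_parameter_ladder(df$a_j, df$lambda_j, max_input)
}
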