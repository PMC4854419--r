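#' Neuronal gain (frequency-input) function
#'
#' The circuit's gain function is zero at or below threshold (chosen as zero)
#' and monotonically increasing and concave above it. The `"hard"` variant is
#' the square root of the positive part, `f(x) = sqrt(max(x, 0))`, used for
#' all simulations. The `"smoothed"` variant,
#' `f(x) = sqrt(x + eps) - sqrt(eps)` for `x > 0` and zero otherwise,
#' replaces the infinite slope at threshold by the finite slope
#' `1 / (2 sqrt(eps))` while remaining non-decreasing, concave for positive
#' argument, and converging pointwise to the hard variant as
#' `smoothing_scale -> 0`. The smoothed variant is convenient for bifurcation
#' scans where branches must be continued through the threshold.
#'
#' @param variant `"hard"` or `"smoothed"`.
#' @param smoothing_scale positive smoothing scale `eps` (smoothed variant
#'   only).
#' @return An object of class `gain_function`.
#' @examples
#' g <- gain_function("hard")
#' gain_eval(g, c(-1, 0, 4)) # 0 0 2
#' @export
gain_function <- function(variant = c("hard", "smoothed"),
                          smoothing_scale = NULL) {
  variant <- match.arg(variant)
  if (variant == "smoothed") {
    if (is.null(smoothing_scale) || !is.numeric(smoothing_scale) ||
        length(smoothing_scale) != 1L || smoothing_scale <= 0)
      stop("smoothed gain requires a positive 'smoothing_scale'")
  } else {
    smoothing_scale <- 0
  }
  structure(list(variant = variant,
                 smoothing_scale = as.numeric(smoothing_scale)),
            class = "gain_function")
}

#' Evaluate a gain function
#'
#' @param g a [gain_function()].
#' @param x numeric vector of gain arguments.
#' @return Non-negative firing rates, same length as `x`. Total function: any
#'   finite argument is accepted.
#' @export
gain_eval <- function(g, x) {
  stopifnot(inherits(g, "gain_function"))
  pos <- x > 0
  out <- numeric(length(x))
  if (g$variant == "hard") {
    out[pos] <- sqrt(x[pos])
  } else {
    eps <- g$smoothing_scale
    out[pos] <- sqrt(x[pos] + eps) - sqrt(eps)
  }
  out
}

# derivative on the active side (one-sided at the threshold kink)
gain_deriv <- function(g, x) {
  pos <- x > 0
  out <- numeric(length(x))
  if (g$variant == "hard") {
    out[pos] <- 0.5 / sqrt(x[pos])
  } else {
    out[pos] <- 0.5 / sqrt(x[pos] + g$smoothing_scale)
  }
  out
}

#' @export
print.gain_function <- function(x, ...) {
  if (x$variant == "hard") {
    cat("gain: hard threshold, f(x) = sqrt(max(x, 0))\n")
  } else {
    cat(sprintf(
      "gain: smoothed threshold (scale %g), f(x) = sqrt(x + %g) - sqrt(%g) for x > 0\n",
      x$smoothing_scale, x$smoothing_scale, x$smoothing_scale))
  }
  invisible(x)
}
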