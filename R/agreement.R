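# Tumor-volume arithmetic and Bland-Altman method agreement.

#' Tumor volume from caliper length and width
#'
#' The standard ellipsoid approximation for caliper measurements:
#' `V = L * W^2 * 0.5` in mm3, with length the larger axis.
#'
#' @param length Tumor length, mm (the larger axis; > 0, vectorized).
#' @param width Tumor width, mm (> 0, must not exceed `length`).
#' @return Volume(s) in mm3.
#' @export
#' @examples
#' tumor_volume(20, 10) # 1000 mm3
tumor_volume <- function(length, width) {
  check_number(length, "length", min = 0, strict = TRUE, len = NULL)
  check_number(width, "width", min = 0, strict = TRUE, len = NULL)
  if (any(width > length)) {
    stop_invalid("`width` exceeds `length`: axes appear swapped")
  }
  length * width^2 * 0.5
}

#' Bland-Altman agreement between two measurement methods
#'
#' Computes the bias (mean paired difference `a - b`) and the 95% limits of
#' agreement `bias +/- 1.96 * SD(a - b)` (sample SD, normal-quantile
#' multiplier), the standard summary of agreement between two methods
#' measuring the same quantity — here tumor volumes by ultrasound versus
#' vernier caliper.
#'
#' @param method_a,method_b Equal-length numeric vectors of paired
#'   measurements, n >= 2.
#' @return A `bland_altman_result` with `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `loa_half_width`, `n`, plus the per-pair `means` and
#'   `differences` for plotting.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))
bland_altman <- function(method_a, method_b) {
  if (!is.numeric(method_a) || !is.numeric(method_b)) {
    stop_invalid("inputs must be numeric vectors")
  }
  if (length(method_a) != length(method_b)) {
    stop_invalid("methods must have equal-length paired samples")
  }
  if (length(method_a) < 2L) stop_invalid("need at least 2 pairs")
  if (any(!is.finite(method_a)) || any(!is.finite(method_b))) {
    stop_invalid("inputs must be finite")
  }
  d <- method_a - method_b
  bias <- mean(d)
  sd_diff <- sd(d)
  half <- 1.96 * sd_diff
  structure(
    list(bias = bias, sd_diff = sd_diff, loa_lower = bias - half,
         loa_upper = bias + half, loa_half_width = half,
         n = length(d), means = (method_a + method_b) / 2, differences = d),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  bias: %.4f\n", x$bias))
  cat(sprintf("  SD of differences: %.4f\n", x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.4f, %.4f] (half-width %.4f)\n",
              x$loa_lower, x$loa_upper, x$loa_half_width))
  invisible(x)
}
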