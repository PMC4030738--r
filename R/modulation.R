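#' Reflex modulation curve over the gait cycle
#'
#' A periodic, continuous map from gait-cycle position (% of cycle) to a
#' modulation factor in `[0, 1]`, built from binned reflex amplitudes by
#' periodic cubic-spline interpolation through the bin values, with the
#' evaluated curve clipped to `[0, 1]`. The curve interpolates the bin values
#' exactly at the bin centers.
#'
#' @param bin_values modulation values in `[0, 1]`, one per bin.
#' @param bin_centers gait-cycle positions of the bins in `[0, 100)`;
#'   defaults to the centers of `length(bin_values)` equal bins.
#' @return an object of class `modulation_curve`.
#' @examples
#' mc <- modulation_curve(c(0.9, 1, 0.8, 0.1))
#' predict(mc, c(0, 25, 50, 75, 100))
#' @export
modulation_curve <- function(bin_values,
                             bin_centers = NULL) {
  stop_not_finite(bin_values, "bin_values")
  if (any(bin_values < 0 | bin_values > 1)) {
    abort("bin_values must lie in [0, 1]")
  }
  n <- length(bin_values)
  if (n < 2L) abort("need at least 2 bins")
  if (is.null(bin_centers)) {
    w <- 100 / n
    bin_centers <- w / 2 + w * (seq_len(n) - 1L)
  }
  stop_not_finite(bin_centers, "bin_centers")
  if (any(bin_centers < 0 | bin_centers >= 100) || is.unsorted(bin_centers, strictly = TRUE)) {
    abort("bin_centers must be strictly increasing in [0, 100)")
  }
  x <- c(bin_centers, bin_centers[1L] + 100)
  y <- c(bin_values, bin_values[1L])
  fun <- stats::splinefun(x, y, method = "periodic")
  structure(list(bin_centers = bin_centers, bin_values = bin_values,
                 fun = fun),
            class = "modulation_curve")
}

#' @describeIn modulation_curve evaluate the curve at gait-cycle positions
#'   (any real number; the curve is periodic with period 100) with output
#'   clipped to `[0, 1]`.
#' @param object a `modulation_curve`.
#' @param pct gait-cycle positions (% of cycle).
#' @param ... unused.
#' @export
predict.modulation_curve <- function(object, pct, ...) {
  x0 <- object$bin_centers[1L]
  pmin(1, pmax(0, object$fun(x0 + (pct - x0) %% 100)))
}

#' @export
print.modulation_curve <- function(x, ...) {
  cat(sprintf("<modulation_curve> %d bins, range [%.3f, %.3f]\n",
              length(x$bin_values), min(x$bin_values), max(x$bin_values)))
  invisible(x)
}

#' Constant modulation curve
#'
#' Convenience constructor for a flat modulation factor (e.g. `k = 1`,
#' feedback fully on throughout the cycle).
#'
#' @param value modulation factor in `[0, 1]`.
#' @export
constant_modulation <- function(value = 1) {
  modulation_curve(rep(value, 16))
}

#' @rdname modulation_curve
#' @method tidy modulation_curve
#' @export
tidy.modulation_curve <- function(x, ...) {
  tibble(bin = seq_along(x$bin_values),
         bin_center_pct = x$bin_centers,
         value = x$bin_values)
}

#' @param object a `modulation_curve`.
#' @param n number of points at which to sample the curve.
#' @rdname modulation_curve
#' @method autoplot modulation_curve
#' @export
autoplot.modulation_curve <- function(object, n = 400, ...) {
  pct <- seq(0, 100, length.out = n)
  df <- tibble(pct = pct, k = predict(object, pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tidy(object),
                        ggplot2::aes(x = .data$bin_center_pct, y = .data$value)) +
    ggplot2::labs(x = "gait cycle (%)", y = "reflex modulation factor k") +
    ggplot2::ylim(0, 1)
}
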