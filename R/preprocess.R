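#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design forward and backward so that the net
#' phase response is zero. The `order` argument is the *effective* order
#' after the two passes: the default interpretation designs an
#' `order/2`-order filter and applies it twice (the usual reading of a
#' "fourth-order zero-phase" specification); `literal_order = TRUE` instead
#' designs the stated order and accepts the doubled effective roll-off.
#' Ends are protected with odd-reflection padding of length `3 * order`.
#'
#' @param x Numeric series.
#' @param rate Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz); must lie below the Nyquist frequency.
#' @param order Effective filter order (even; default 4).
#' @param literal_order Design the stated order per pass instead of halving.
#' @return Filtered series, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / 240))
#' y <- butter_zero_phase(x, rate = 240, cutoff = 10)
#' @export
butter_zero_phase <- function(x, rate, cutoff, order = 4,
                              literal_order = FALSE) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  if (length(x) <= 3 * order)
    stop("series too short for padding: need length > ", 3 * order)
  n_design <- if (literal_order) order else order / 2
  if (n_design != round(n_design) || n_design < 1)
    stop("order must be an even positive integer (or use literal_order)")
  bf <- signal::butter(n_design, W = cutoff / (rate / 2), type = "low")
  filtfilt_padded(bf, x, padlen = 3 * order)
}

# Forward-backward pass of an ARMA filter with odd-reflection end padding.
# Each pass starts from the filter's steady state for the first padded
# sample, so constants pass through exactly and edge transients do not leak
# into the retained window.
filtfilt_padded <- function(bf, x, padlen) {
  b <- bf$b
  a <- bf$a
  n <- length(x)
  padlen <- min(padlen, n - 1)
  head_pad <- 2 * x[1] - x[(padlen + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xp <- c(head_pad, x, tail_pad)
  dc_gain <- sum(b) / sum(a)
  run <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z0, length(b) - 1),
                              init.y = rep(z0 * dc_gain, length(a) - 1)))
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# Zero-phase band-pass used by the synthetic generator's sway model.
bandpass_zero_phase <- function(x, rate, band, order = 2) {
  bf <- signal::butter(order, W = band / (rate / 2), type = "pass")
  filtfilt_padded(bf, x, padlen = 3 * 2 * order)
}

#' Remove the mean of a series
#'
#' Gravity and sensor offsets appear as per-axis constants during static
#' postures; subtracting the trial mean removes them.
#'
#' @param x Nonempty numeric series.
#' @return `x - mean(x)`.
#' @export
detrend_mean <- function(x) {
  if (length(x) == 0) stop("empty series")
  x - mean(x)
}

#' Derive directional series from a tri-axial recording
#'
#' Splits a 3-axis acceleration matrix into the anterior-posterior (AP),
#' medial-lateral (ML) and inferior-superior (IS) components and computes the
#' planar (2DR) and spatial (3DR) resultant magnitude series samplewise.
#'
#' @param acc Numeric matrix with columns AP, ML, IS (equal lengths).
#' @param rate Sampling rate (Hz).
#' @param detrend_axes Subtract each axis mean first (default `TRUE`)?
#'   Resultants are always computed from the axes as returned.
#' @return An object of class `directional_signals`: list with elements
#'   `ap`, `ml`, `is_`, `r2d`, `r3d`, `rate`.
#' @export
derive_directions <- function(acc, rate, detrend_axes = TRUE) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acc must have exactly 3 columns (AP, ML, IS)")
  if (any(!is.finite(acc))) stop("acc contains non-finite values")
  ap <- acc[, 1]; ml <- acc[, 2]; is_ <- acc[, 3]
  if (detrend_axes) {
    ap <- ap - mean(ap); ml <- ml - mean(ml); is_ <- is_ - mean(is_)
  }
  structure(list(
    ap = ap, ml = ml, is_ = is_,
    r2d = sqrt(ap^2 + ml^2),
    r3d = sqrt(ap^2 + ml^2 + is_^2),
    rate = rate
  ), class = "directional_signals")
}
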