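#' Names of the 43 acceleration-based sway measures
#'
#' The registry spans twelve families: average (AVG) and root-mean-square
#' (RMS) amplitude, range (RNG), sway areas (ARE_SW, ARE_CC, ARE_CE), fractal
#' dimensions (FD_CC, FD_CE), trajectory length (LEN), mean distance (MD),
#' mean frequency (MF), mean velocity (MV), planar deviation (PD_P, PD_V),
#' the phase-plane parameter (PP) and root-mean-square distance (RMSD),
#' expanded over the applicable directions (AP, ML, IS, 2DR, 3DR).
#'
#' @return Character vector of length 43 in canonical order.
#' @export
measure_names <- function() {
  c(paste0("AVG_",  c("AP", "ML", "IS", "2DR", "3DR")),
    paste0("RNG_",  c("AP", "ML", "IS", "2DR", "3DR")),
    paste0("RMS_",  c("AP", "ML", "IS", "2DR", "3DR")),
    "ARE_SW", "ARE_CC", "ARE_CE",
    "FD_CC", "FD_CE",
    paste0("LEN_",  c("AP", "ML", "2DR", "3DR")),
    paste0("MD_",   c("AP", "ML", "2DR", "3DR")),
    paste0("MF_",   c("AP", "ML", "2DR", "3DR")),
    paste0("MV_",   c("AP", "ML", "2DR", "3DR")),
    "PD_P", "PD_V", "PP",
    paste0("RMSD_", c("AP", "ML", "2DR", "3DR")))
}

#' Options for the sway-measure computations
#'
#' @param cutoff Low-pass cutoff (Hz) applied to each axis before measure
#'   computation (default 10).
#' @param filter_order Effective Butterworth order (default 4).
#' @param apply_filter Filter the raw axes first (default `TRUE`)?
#' @param avg_raw Use the literal raw mean for the axis AVG measures instead
#'   of the mean absolute deviation (default `FALSE`; the raw mean of a
#'   gravity-removed axis is ~0 and uninformative).
#' @param per_time Divide the three area measures by the trial duration
#'   ("per unit of time", default `TRUE`); lengths are reported per trial.
#' @param confidence Coverage of the confidence circle/ellipse (default 0.95).
#' @return A list of class `measure_opts`.
#' @export
measure_opts <- function(cutoff = 10, filter_order = 4, apply_filter = TRUE,
                         avg_raw = FALSE, per_time = TRUE, confidence = 0.95) {
  structure(list(cutoff = cutoff, filter_order = filter_order,
                 apply_filter = apply_filter, avg_raw = avg_raw,
                 per_time = per_time, confidence = confidence),
            class = "measure_opts")
}

#' Amplitude statistics: AVG, RNG, RMS, MD, RMSD
#'
#' Average, range, root-mean-square, mean distance from center and RMS
#' distance from center, per direction. Axis statistics use the series as
#' given (assumed centered by preprocessing); distance statistics for the
#' resultant directions use the samplewise resultant magnitudes.
#'
#' @param d A `directional_signals` object (see [derive_directions()]).
#' @param avg_raw Use the literal raw mean for axis AVG entries.
#' @return Named numeric vector of 18 statistics.
#' @export
basic_stats <- function(d, avg_raw = FALSE) {
  if (length(d$ap) < 2) stop("series too short (need length >= 2)")
  axis_avg <- function(x) if (avg_raw) mean(x) else mean(abs(x))
  rng <- function(x) max(x) - min(x)
  rms <- function(x) sqrt(mean(x^2))
  c(AVG_AP = axis_avg(d$ap), AVG_ML = axis_avg(d$ml), AVG_IS = axis_avg(d$is_),
    AVG_2DR = mean(d$r2d), AVG_3DR = mean(d$r3d),
    RNG_AP = rng(d$ap), RNG_ML = rng(d$ml), RNG_IS = rng(d$is_),
    RNG_2DR = rng(d$r2d), RNG_3DR = rng(d$r3d),
    RMS_AP = rms(d$ap), RMS_ML = rms(d$ml), RMS_IS = rms(d$is_),
    RMS_2DR = rms(d$r2d), RMS_3DR = rms(d$r3d),
    MD_AP = mean(abs(d$ap)), MD_ML = mean(abs(d$ml)),
    MD_2DR = mean(d$r2d), MD_3DR = mean(d$r3d),
    RMSD_AP = rms(d$ap), RMSD_ML = rms(d$ml),
    RMSD_2DR = rms(d$r2d), RMSD_3DR = rms(d$r3d))
}

#' Trajectory length: LEN
#'
#' Total length of the acceleration trajectory: per axis the sum of absolute
#' first differences; for the resultant directions the sum of Euclidean
#' increment norms in the plane (2DR) or in space (3DR).
#'
#' @param d A `directional_signals` object.
#' @param per_second Divide lengths by the trial duration (default `FALSE`:
#'   lengths are reported per trial).
#' @return Named numeric vector `LEN_AP`, `LEN_ML`, `LEN_2DR`, `LEN_3DR`.
#' @export
trajectory_length <- function(d, per_second = FALSE) {
  if (length(d$ap) < 2) stop("series too short (need length >= 2)")
  dap <- diff(d$ap); dml <- diff(d$ml); dis <- diff(d$is_)
  denom <- if (per_second) length(d$ap) / d$rate else 1
  c(LEN_AP = sum(abs(dap)), LEN_ML = sum(abs(dml)),
    LEN_2DR = sum(sqrt(dap^2 + dml^2)),
    LEN_3DR = sum(sqrt(dap^2 + dml^2 + dis^2))) / denom
}

#' Sway areas: ARE_SW, ARE_CC, ARE_CE
#'
#' Triangle-sweep sway area about the trajectory center, the 95% confidence
#' circle area \eqn{\pi (MD_{2DR} + z_{.05} s_{RD})^2} and the 95% confidence
#' ellipse area \eqn{2\pi F_{.05}[2, n-2] \sqrt{s_{AP}^2 s_{ML}^2 -
#' s_{APML}^2}} computed from the planar (AP, ML) trajectory, each divided by
#' the trial duration when `per_time` is set. Second moments are population
#' moments (divide by n) about the sample mean.
#'
#' @param d A `directional_signals` object.
#' @param per_time Divide by the trial duration (default `TRUE`).
#' @param confidence Coverage probability (default 0.95).
#' @return Named numeric vector `ARE_SW`, `ARE_CC`, `ARE_CE`.
#' @export
area_measures <- function(d, per_time = TRUE, confidence = 0.95) {
  n <- length(d$ap)
  if (n < 3) stop("series too short (need length >= 3)")
  ap <- d$ap - mean(d$ap); ml <- d$ml - mean(d$ml)
  dur <- if (per_time) n / d$rate else 1
  i <- seq_len(n - 1)
  are_sw <- sum(0.5 * abs(ap[i] * ml[i + 1] - ap[i + 1] * ml[i])) / dur
  rd <- sqrt(ap^2 + ml^2)
  md <- mean(rd)
  s_rd2 <- mean(rd^2) - md^2
  s_rd <- sqrt(max(s_rd2, 0))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  are_cc <- pi * (md + z * s_rd)^2 / dur
  s_ap2 <- mean(ap^2); s_ml2 <- mean(ml^2); s_apml <- mean(ap * ml)
  det2 <- s_ap2 * s_ml2 - s_apml^2
  f <- stats::qf(confidence, 2, n - 2)
  are_ce <- 2 * pi * f * sqrt(max(det2, 0)) / dur
  c(ARE_SW = are_sw, ARE_CC = are_cc, ARE_CE = are_ce)
}

#' Fractal dimensions: FD_CC, FD_CE
#'
#' Prieto-style fractal dimension \eqn{\ln(N) / \ln(N d / LEN_{2DR})} of the
#' N-point planar trajectory, with the characteristic diameter d taken as the
#' 95% confidence circle diameter (FD_CC) or the diameter of the circle whose
#' area equals the 95% confidence ellipse (FD_CE). Degenerate trajectories
#' (zero path length or non-positive log argument) yield `NA`.
#'
#' @param d A `directional_signals` object.
#' @param confidence Coverage probability (default 0.95).
#' @return Named numeric vector `FD_CC`, `FD_CE` (dimensionless).
#' @export
fractal_dimension <- function(d, confidence = 0.95) {
  n <- length(d$ap)
  if (n < 3) stop("series too short (need length >= 3)")
  ap <- d$ap - mean(d$ap); ml <- d$ml - mean(d$ml)
  dap <- diff(ap); dml <- diff(ml)
  len2 <- sum(sqrt(dap^2 + dml^2))
  rd <- sqrt(ap^2 + ml^2)
  md <- mean(rd)
  s_rd <- sqrt(max(mean(rd^2) - md^2, 0))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  d_cc <- 2 * (md + z * s_rd)
  area_ce <- area_measures(d, per_time = FALSE, confidence = confidence)[["ARE_CE"]]
  d_ce <- sqrt(8 * area_ce / pi)
  fd_of <- function(diam) {
    if (len2 <= 0 || diam <= 0) return(NA_real_)
    ratio <- n * diam / len2
    if (ratio <= 0 || abs(log(ratio)) < .Machine$double.eps) return(NA_real_)
    log(n) / log(ratio)
  }
  c(FD_CC = fd_of(d_cc), FD_CE = fd_of(d_ce))
}

#' Spectral mean frequency: MF
#'
#' Power-weighted mean frequency of the one-sided periodogram (DC bin
#' excluded) per direction. Resultant directions use the spectrum of the
#' mean-centered resultant magnitude series. Zero total power yields `NA`.
#'
#' @param d A `directional_signals` object.
#' @return Named numeric vector `MF_AP`, `MF_ML`, `MF_2DR`, `MF_3DR` (Hz).
#' @export
mean_frequency <- function(d) {
  n <- length(d$ap)
  if (n < 16) stop("series too short for spectral estimation (need >= 16)")
  mf1 <- function(x) {
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2
    k <- 2:(floor(n / 2) + 1)
    freq <- (k - 1) * d$rate / n
    pw <- p[k]
    tot <- sum(pw)
    if (tot <= 0) return(NA_real_)
    sum(freq * pw) / tot
  }
  c(MF_AP = mf1(d$ap), MF_ML = mf1(d$ml),
    MF_2DR = mf1(d$r2d), MF_3DR = mf1(d$r3d))
}

# Linear detrend (remove least-squares line), used to suppress integration
# drift of the velocity and displacement series.
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::.lm.fit(cbind(1, t), x)$residuals
}

#' Integral measures: MV, PD, PP
#'
#' Velocity is the cumulative trapezoidal integral of each (centered) axis
#' acceleration, linearly detrended; displacement integrates velocity the
#' same way. Mean velocity (MV) is the mean absolute velocity per axis and
#' the mean resultant speed for 2DR/3DR. Planar deviation pools AP and ML
#' variances of displacement (PD_P) and velocity (PD_V); the phase-plane
#' parameter (PP) pools displacement and velocity variance of the sagittal
#' (AP) direction. Variances are population variances.
#'
#' @param d A `directional_signals` object.
#' @return Named numeric vector `MV_AP`, `MV_ML`, `MV_2DR`, `MV_3DR`,
#'   `PD_P`, `PD_V`, `PP`.
#' @export
integrate_measures <- function(d) {
  n <- length(d$ap)
  if (n < 3) stop("series too short (need length >= 3)")
  t <- seq(0, by = 1 / d$rate, length.out = n)
  integ <- function(x) detrend_linear(drop(pracma::cumtrapz(t, x)))
  v_ap <- integ(d$ap); v_ml <- integ(d$ml); v_is <- integ(d$is_)
  p_ap <- integ(v_ap); p_ml <- integ(v_ml)
  pvar <- function(x) mean((x - mean(x))^2)
  c(MV_AP = mean(abs(v_ap)), MV_ML = mean(abs(v_ml)),
    MV_2DR = mean(sqrt(v_ap^2 + v_ml^2)),
    MV_3DR = mean(sqrt(v_ap^2 + v_ml^2 + v_is^2)),
    PD_P = sqrt(pvar(p_ap) + pvar(p_ml)),
    PD_V = sqrt(pvar(v_ap) + pvar(v_ml)),
    PP = sqrt(pvar(p_ap) + pvar(v_ap)))
}

#' Compute the 43 sway measures from directional signals
#'
#' Assembles all measure families into the canonical 43-entry vector for one
#' sensor and trial. The input is expected to be filtered and centered; use
#' [compute_all_measures()] to go from a raw trial recording.
#'
#' @param d A `directional_signals` object.
#' @param opts A [measure_opts()] object (filtering fields ignored here).
#' @return Named numeric vector of length 43 in [measure_names()] order.
#' @export
compute_measures <- function(d, opts = measure_opts()) {
  out <- c(basic_stats(d, avg_raw = opts$avg_raw),
           trajectory_length(d),
           area_measures(d, per_time = opts$per_time,
                         confidence = opts$confidence),
           fractal_dimension(d, confidence = opts$confidence),
           mean_frequency(d),
           integrate_measures(d))
  out[measure_names()]
}

#' Compute the 43 sway measures for one sensor of a trial recording
#'
#' Applies the preprocessing chain (zero-phase Butterworth low-pass, per-axis
#' mean removal) to the requested sensor's tri-axial acceleration, then
#' evaluates every measure family.
#'
#' @param recording A `trial_recording` (see [simulate_trial()]) or any list
#'   with an `acc` element mapping sensor names to n x 3 matrices.
#' @param sensor Placement name present in the recording.
#' @param opts A [measure_opts()] object.
#' @param rate Sampling rate (Hz); taken from the recording if present.
#' @return Named numeric vector of length 43.
#' @export
compute_all_measures <- function(recording, sensor, opts = measure_opts(),
                                 rate = NULL) {
  if (!sensor %in% names(recording$acc))
    stop("sensor '", sensor, "' not present in recording")
  if (is.null(rate)) rate <- recording$acc_rate
  acc <- recording$acc[[sensor]]
  if (isTRUE(opts$apply_filter)) {
    acc <- apply(acc, 2, butter_zero_phase, rate = rate,
                 cutoff = opts$cutoff, order = opts$filter_order)
  }
  d <- derive_directions(acc, rate, detrend_axes = TRUE)
  compute_measures(d, opts)
}

#' Rotational mean frequency
#'
#' The classical rotational alternative to the spectral mean frequency:
#' the number of full loops per second a point traversing the trajectory's
#' path length at radius equal to the mean distance would complete:
#' `(LEN / duration) / (2 * pi * MD)` in the plane, with the `4 * sqrt(2)`
#' one-dimensional analog on single axes. Not part of the 43-measure
#' registry (which uses the spectral definition).
#'
#' @param d A `directional_signals` object.
#' @return Named numeric vector `MFREQ_AP`, `MFREQ_ML`, `MFREQ_2DR` (Hz).
#' @export
mfreq_rotational <- function(d) {
  len <- trajectory_length(d, per_second = TRUE)
  bs <- basic_stats(d)
  c(MFREQ_AP = len[["LEN_AP"]] / (4 * sqrt(2) * bs[["MD_AP"]]),
    MFREQ_ML = len[["LEN_ML"]] / (4 * sqrt(2) * bs[["MD_ML"]]),
    MFREQ_2DR = len[["LEN_2DR"]] / (2 * pi * bs[["MD_2DR"]]))
}

#' Mean anterior-posterior COP velocity (COPV_AP)
#'
#' Total anterior-posterior path length of the (optionally filtered) COP
#' trajectory divided by the trial duration.
#'
#' @param cop Numeric matrix with columns AP, ML (mm).
#' @param rate Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz) of the zero-phase filter; `NULL` skips
#'   filtering.
#' @param order Effective filter order (default 4).
#' @return Mean AP velocity (mm/s), nonnegative.
#' @examples
#' ramp <- cbind(seq(0, 30, length.out = 400), 0)
#' copv_ap(ramp, rate = 40, cutoff = NULL) # 3 mm/s
#' @export
copv_ap <- function(cop, rate, cutoff = 10, order = 4) {
  cop <- as.matrix(cop)
  if (nrow(cop) < 2) stop("COP series too short (need length >= 2)")
  ap <- cop[, 1]
  if (!is.null(cutoff)) ap <- butter_zero_phase(ap, rate, cutoff, order)
  duration <- nrow(cop) / rate
  sum(abs(diff(ap))) / duration
}
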