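#' Effect parameters of the synthetic-study generator
#'
#' The generator produces, for each trial, a strictly positive latent
#' instability \eqn{I = \exp(\eta)} from a linear predictor on the log scale:
#' \deqn{\eta = \mu + \beta_{WP}[p] + \beta_{SS} 1\{inclined\} +
#'   \beta_{LC} 1\{10kg\} + interactions + b_{subject} + \epsilon_{trial}.}
#' The latent drives (i) the amplitude of every accelerometer channel through
#' per-placement gains, (ii) the upper edge of the simulated sway passband
#' (through `freq_coupling`, so that frequency-domain and scale-invariant
#' measures also respond to the factors), (iii) the center-of-pressure
#' amplitude, and (iv) the subjective stability rating.
#'
#' Defaults make the load-carriage effect large (`beta_lc = 0.6`) and the
#' surface-slope effect small (`beta_ss = 0.1`), with posture offsets spread
#' over 0--0.8, so that posture and load effects are detected with high power
#' while surface effects are only marginally detectable.
#'
#' @param baseline_log_sway Baseline log instability; `exp()` of it is the
#'   reference acceleration scale (m/s^2) at the pelvis.
#' @param beta_wp Numeric length 6, posture offsets (log scale) for P1--P6.
#' @param beta_ss Surface-slope offset (log scale) applied when inclined.
#' @param beta_lc Load-carriage offset (log scale) applied at 10 kg.
#' @param gamma_wp_lc,gamma_wp_ss Numeric length 6, posture-specific
#'   modulation added when the load (resp. incline) indicator is on.
#' @param gamma_ss_lc Scalar added when both incline and load are on.
#' @param gamma_wp_ss_lc Numeric length 6, three-way modulation.
#' @param subject_sd SD of the between-subject random effect (log scale).
#' @param subject_wp_sd,subject_ss_sd,subject_lc_sd SDs of the
#'   factor-specific subject susceptibilities (log scale): each subject
#'   draws a private offset per posture, per surface and per load level,
#'   stable across repetitions. These are the error terms of the
#'   corresponding within-subject F tests, so they control detection
#'   power factor by factor. Defaults are sized so that at the default
#'   30-subject design the posture and load effects are detected by
#'   essentially every measure while the small surface-slope effect is
#'   only marginally detectable, per-measure power roughly 0.2-0.3.
#' @param subject_cond_sd SD of the unstructured subject-by-condition
#'   random effect (log scale), stable across repetitions; the error term
#'   of the interaction F tests.
#' @param trial_sd SD of the residual trial-to-trial noise (log scale).
#' @param sensor_gains Named positive multipliers per placement; the pelvis
#'   carries the strongest coupling by default.
#' @param sway_band Length-2 passband (Hz) of the simulated sway at baseline.
#' @param freq_coupling Exponent coupling the passband upper edge to the
#'   latent: `high_eff = high * exp(freq_coupling * (log(I) - baseline))`.
#' @param cop_gain COP amplitude (mm) per unit latent instability.
#' @param pps_intercept,pps_slope,pps_noise_sd Mapping from log latent to the
#'   0--10 perceived-stability rating: `pps = clip(intercept +
#'   slope * log(I) + noise, 0, 10)`.
#' @return An object of class `effect_params` (a validated list).
#' @export
effect_params <- function(baseline_log_sway = -2.5,
                          beta_wp = c(0, 0.16, 0.32, 0.48, 0.64, 0.8),
                          beta_ss = 0.1,
                          beta_lc = 0.6,
                          gamma_wp_lc = seq(0, 0.25, length.out = 6),
                          gamma_wp_ss = seq(0, 0.03, length.out = 6),
                          gamma_ss_lc = 0.02,
                          gamma_wp_ss_lc = rep(0, 6),
                          subject_sd = 0.2,
                          subject_wp_sd = 0.25,
                          subject_ss_sd = 0.3,
                          subject_lc_sd = 0.3,
                          subject_cond_sd = 0.25,
                          trial_sd = 0.25,
                          sensor_gains = c(pelvis = 1, T8 = 0.8,
                                           shoulder_L = 0.7, shoulder_R = 0.7,
                                           upper_leg_L = 0.6, upper_leg_R = 0.6,
                                           lower_leg_L = 0.75, lower_leg_R = 0.75),
                          sway_band = c(0.1, 3),
                          freq_coupling = 0.4,
                          cop_gain = 60,
                          pps_intercept = 10.25,
                          pps_slope = 3,
                          pps_noise_sd = 0.8) {
  stopifnot(length(beta_wp) == 6, length(gamma_wp_lc) == 6,
            length(gamma_wp_ss) == 6, length(gamma_wp_ss_lc) == 6,
            length(sway_band) == 2, sway_band[1] > 0,
            sway_band[2] > sway_band[1],
            subject_sd >= 0, subject_wp_sd >= 0, subject_ss_sd >= 0,
            subject_lc_sd >= 0, subject_cond_sd >= 0, trial_sd >= 0,
            pps_noise_sd >= 0,
            all(sensor_gains >= 0), cop_gain >= 0)
  structure(list(
    baseline_log_sway = baseline_log_sway,
    beta_wp = beta_wp, beta_ss = beta_ss, beta_lc = beta_lc,
    gamma_wp_lc = gamma_wp_lc, gamma_wp_ss = gamma_wp_ss,
    gamma_ss_lc = gamma_ss_lc, gamma_wp_ss_lc = gamma_wp_ss_lc,
    subject_sd = subject_sd, subject_wp_sd = subject_wp_sd,
    subject_ss_sd = subject_ss_sd, subject_lc_sd = subject_lc_sd,
    subject_cond_sd = subject_cond_sd, trial_sd = trial_sd,
    sensor_gains = sensor_gains, sway_band = sway_band,
    freq_coupling = freq_coupling, cop_gain = cop_gain,
    pps_intercept = pps_intercept, pps_slope = pps_slope,
    pps_noise_sd = pps_noise_sd
  ), class = "effect_params")
}

#' Null effect parameters
#'
#' Convenience constructor with all factor effects set to zero (subject and
#' trial variability retained unless overridden). Used for type-I error
#' calibration of the ANOVA stage.
#'
#' @param ... Overrides passed on to [effect_params()].
#' @return An `effect_params` object with all betas/gammas zero.
#' @export
null_effect_params <- function(...) {
  args <- list(beta_wp = rep(0, 6), beta_ss = 0, beta_lc = 0,
               gamma_wp_lc = rep(0, 6), gamma_wp_ss = rep(0, 6),
               gamma_ss_lc = 0, gamma_wp_ss_lc = rep(0, 6))
  args <- utils::modifyList(args, list(...))
  do.call(effect_params, args)
}

#' Study configuration for the synthetic generator
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_repetitions Repetitions of each of the 24 tasks (default 2).
#' @param trial_duration Trial length in seconds (default 10).
#' @param acc_rate Accelerometer sampling rate in Hz (default 240).
#' @param cop_rate Center-of-pressure sampling rate in Hz (default 40).
#' @param sensor_set Character vector of placements, a subset of
#'   [default_sensors()].
#' @param effect_params An [effect_params()] object.
#' @param seed Integer seed; every trial derives its own substream from it.
#' @param pps_round Round the stability rating to the 11-point integer scale?
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 30, n_repetitions = 2,
                         trial_duration = 10, acc_rate = 240, cop_rate = 40,
                         sensor_set = default_sensors(),
                         effect_params = swaylab::effect_params(),
                         seed = 1, pps_round = FALSE) {
  if (n_subjects < 1 || n_repetitions < 1)
    stop("n_subjects and n_repetitions must be >= 1")
  if (trial_duration <= 0 || acc_rate <= 0 || cop_rate <= 0)
    stop("trial_duration and sampling rates must be positive")
  if (!all(sensor_set %in% default_sensors()))
    stop("unknown sensor placement(s): ",
         paste(setdiff(sensor_set, default_sensors()), collapse = ", "))
  if (length(sensor_set) == 0)
    stop("sensor_set must contain at least one placement")
  if (!inherits(effect_params, "effect_params"))
    stop("effect_params must be created by effect_params()")
  if (effect_params$sway_band[2] >= min(acc_rate, cop_rate) / 2)
    stop("sway_band must lie below the Nyquist frequency of both streams")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_repetitions = as.integer(n_repetitions),
    trial_duration = trial_duration, acc_rate = acc_rate, cop_rate = cop_rate,
    sensor_set = sensor_set, effect_params = effect_params,
    seed = as.integer(seed), pps_round = isTRUE(pps_round)
  ), class = "study_config")
}
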