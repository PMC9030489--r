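# Deterministic per-trial substream: fold (seed, subject, condition,
# repetition) into one 31-bit seed. Stepwise modular arithmetic keeps every
# intermediate below 2^53 so the derivation is exact in doubles.
trial_seed <- function(seed, subject, cond_index, repetition) {
  m <- 2147483629
  s <- seed %% m
  for (k in c(subject, cond_index, repetition)) {
    s <- (s * 1000003 + k) %% m
  }
  as.integer(s)
}

cond_index <- function(cond) {
  p <- match(as.character(cond$posture), wp_levels())
  s <- match(as.character(cond$surface), ss_levels())
  l <- match(as.character(cond$load), lc_levels())
  if (any(is.na(c(p, s, l)))) stop("invalid condition")
  (p - 1L) * 4L + (s - 1L) * 2L + l
}

#' Latent instability of a trial
#'
#' Evaluates the generator's log-linear model and returns the strictly
#' positive latent instability \eqn{\exp(\eta)} for one condition.
#'
#' @param cond A condition (one row of [enumerate_conditions()] or a list
#'   with `posture`, `surface`, `load`).
#' @param subject_effect Subject random effect on the log scale.
#' @param params An [effect_params()] object.
#' @param trial_noise Residual log-scale noise; drawn from
#'   `N(0, params$trial_sd)` when `NULL`.
#' @return Positive scalar latent instability.
#' @export
latent_instability <- function(cond, subject_effect = 0,
                               params = effect_params(), trial_noise = NULL) {
  p <- match(as.character(cond$posture), wp_levels())
  inc <- as.numeric(as.character(cond$surface) == "inclined")
  ld <- as.numeric(as.character(cond$load) == "10kg")
  if (is.null(trial_noise))
    trial_noise <- stats::rnorm(1, 0, params$trial_sd)
  eta <- params$baseline_log_sway + params$beta_wp[p] +
    params$beta_ss * inc + params$beta_lc * ld +
    params$gamma_wp_lc[p] * ld + params$gamma_wp_ss[p] * inc +
    params$gamma_ss_lc * inc * ld + params$gamma_wp_ss_lc[p] * inc * ld +
    subject_effect + trial_noise
  exp(eta)
}

# One band-limited, centered noise channel with sample SD exactly `scale`.
sway_channel <- function(n, rate, band, scale) {
  x <- stats::rnorm(n)
  x <- bandpass_zero_phase(x, rate, band)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * scale
}

#' Simulate one trial recording
#'
#' Generates the coupled outputs of one task execution: per-sensor tri-axial
#' acceleration (band-limited Gaussian sway with channel SD equal to
#' `sensor_gain * instability`), a center-of-pressure trajectory sharing the
#' same latent, and the 0--10 perceived-stability rating. All randomness is
#' drawn from a substream seeded deterministically from
#' `(config$seed, subject, condition, repetition)`, so identical arguments
#' reproduce identical recordings.
#'
#' @param subject_id Integer subject index.
#' @param cond A condition (see [latent_instability()]).
#' @param repetition Repetition index (1-based).
#' @param config A [study_config()] object.
#' @param subject_effect Log-scale subject random effect (drawn centrally by
#'   [simulate_study()]).
#' @param signals Generate waveforms (`TRUE`) or only the latent and rating
#'   (`FALSE`, used for large statistical calibrations)?
#' @return A `trial_recording`: list with `subject_id`, `posture`, `surface`,
#'   `load`, `repetition`, `latent`, `pps`, `acc` (named list of n x 3
#'   matrices, m/s^2), `cop` (n x 2 matrix, mm), `acc_rate`, `cop_rate`.
#' @export
simulate_trial <- function(subject_id, cond, repetition, config,
                           subject_effect = 0, signals = TRUE) {
  with_local_seed(
    trial_seed(config$seed, subject_id, cond_index(cond), repetition),
    simulate_trial_impl(subject_id, cond, repetition, config,
                        subject_effect, signals))
}

simulate_trial_impl <- function(subject_id, cond, repetition, config,
                                subject_effect, signals) {
  params <- config$effect_params
  noise <- stats::rnorm(1, 0, params$trial_sd)
  inst <- latent_instability(cond, subject_effect, params, trial_noise = noise)

  pps <- params$pps_intercept + params$pps_slope * log(inst) +
    stats::rnorm(1, 0, params$pps_noise_sd)
  pps <- min(max(pps, 0), 10)
  if (config$pps_round) pps <- round(pps)

  rec <- list(subject_id = subject_id,
              posture = as.character(cond$posture),
              surface = as.character(cond$surface),
              load = as.character(cond$load),
              repetition = repetition,
              latent = inst, pps = pps,
              acc = NULL, cop = NULL,
              acc_rate = config$acc_rate, cop_rate = config$cop_rate)

  if (signals) {
    eta_excess <- log(inst) - params$baseline_log_sway
    freq_scale <- exp(params$freq_coupling * eta_excess)
    band_for <- function(rate) {
      lo <- params$sway_band[1]
      hi <- min(params$sway_band[2] * freq_scale, 0.45 * rate)
      c(lo, max(hi, lo * 1.5))
    }
    n_acc <- round(config$trial_duration * config$acc_rate)
    band_acc <- band_for(config$acc_rate)
    acc <- lapply(config$sensor_set, function(sensor) {
      gain <- params$sensor_gains[[sensor]]
      m <- vapply(1:3, function(axis)
        sway_channel(n_acc, config$acc_rate, band_acc, gain * inst),
        numeric(n_acc))
      colnames(m) <- c("AP", "ML", "IS")
      m
    })
    names(acc) <- config$sensor_set
    n_cop <- round(config$trial_duration * config$cop_rate)
    band_cop <- band_for(config$cop_rate)
    cop <- cbind(
      AP = sway_channel(n_cop, config$cop_rate, band_cop,
                        params$cop_gain * inst),
      ML = sway_channel(n_cop, config$cop_rate, band_cop,
                        params$cop_gain * inst))
    rec$acc <- acc
    rec$cop <- cop
  }
  structure(rec, class = "trial_recording")
}

#' Simulate a complete factorial study
#'
#' Generates every (subject, condition, repetition) cell of the 6 x 2 x 2
#' within-subject design: `n_subjects * 24 * n_repetitions` trials, in
#' subject-major order. Deterministic given `config$seed`.
#'
#' @param config A [study_config()] object.
#' @param signals Generate waveforms per trial (default `TRUE`); `FALSE`
#'   produces latent-and-rating-only trials for fast statistical simulation.
#' @return A `study_dataset`: list with `trials` (list of
#'   `trial_recording`) and `config`.
#' @examples
#' cfg <- study_config(n_subjects = 1, n_repetitions = 1, seed = 7)
#' ds <- simulate_study(cfg, signals = FALSE)
#' length(ds$trials) # 24
#' @export
simulate_study <- function(config, signals = TRUE) {
  params <- config$effect_params
  subj_eff <- with_local_seed(config$seed,
    stats::rnorm(config$n_subjects, 0, params$subject_sd))
  conds <- enumerate_conditions()
  trials <- vector("list", config$n_subjects * 24 * config$n_repetitions)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    # factor-specific susceptibilities plus an unstructured cell effect,
    # all stable across repetitions of a task
    cell_eff <- with_local_seed(trial_seed(config$seed, s, 0L, 0L), {
      u_wp <- stats::rnorm(6, 0, params$subject_wp_sd)
      u_ss <- stats::rnorm(2, 0, params$subject_ss_sd)
      u_lc <- stats::rnorm(2, 0, params$subject_lc_sd)
      u_cell <- stats::rnorm(24, 0, params$subject_cond_sd)
      u_wp[as.integer(conds$posture)] + u_ss[as.integer(conds$surface)] +
        u_lc[as.integer(conds$load)] + u_cell
    })
    for (ci in seq_len(24)) {
      for (r in seq_len(config$n_repetitions)) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(s, conds[ci, ], r, config,
                                      subject_effect = subj_eff[s] +
                                        cell_eff[ci],
                                      signals = signals)
      }
    }
  }
  structure(list(trials = trials, config = config), class = "study_dataset")
}

#' Trial metadata of a study dataset
#'
#' @param dataset A `study_dataset`.
#' @return Data frame with one row per trial: `subject`, `posture`,
#'   `surface`, `load`, `repetition`, `pps`, `latent`.
#' @export
study_metadata <- function(dataset) {
  do.call(rbind, lapply(dataset$trials, function(tr)
    data.frame(subject = tr$subject_id, posture = tr$posture,
               surface = tr$surface, load = tr$load,
               repetition = tr$repetition, pps = tr$pps,
               latent = tr$latent)))
}

#' @export
print.study_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic working-posture study:", length(x$trials), "trials\n")
  cat("  ", cfg$n_subjects, "subjects x 24 conditions x",
      cfg$n_repetitions, "repetition(s)\n")
  cat("  sensors:", paste(cfg$sensor_set, collapse = ", "), "\n")
  invisible(x)
}
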