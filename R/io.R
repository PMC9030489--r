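fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

trial_dirname <- function(tr) {
  sprintf("S%02d_%s_%s_%s_r%d", tr$subject_id, tr$posture, tr$surface,
          tr$load, tr$repetition)
}

#' Write a study dataset to a directory
#'
#' Layout: `metadata.csv` (subject, posture, surface, load, repetition,
#' pps, latent), `config.yaml` (the study configuration), and one directory
#' per trial under `trials/` holding a `time,AP,ML,IS` CSV per sensor plus
#' `cop.csv` (`time,AP,ML`). Floats are serialized at 17 significant digits
#' so a read round-trips to full precision.
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- study_metadata(dataset)
  meta$pps <- fmt(meta$pps)
  meta$latent <- fmt(meta$latent)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  write_study_config(dataset$config, file.path(dir, "config.yaml"))
  for (tr in dataset$trials) {
    if (is.null(tr$acc)) next
    tdir <- file.path(dir, "trials", trial_dirname(tr))
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    n <- nrow(tr$acc[[1]])
    t_acc <- fmt(seq(0, by = 1 / tr$acc_rate, length.out = n))
    for (sen in names(tr$acc)) {
      m <- tr$acc[[sen]]
      df <- data.frame(time = t_acc, AP = fmt(m[, 1]), ML = fmt(m[, 2]),
                       IS = fmt(m[, 3]))
      utils::write.csv(df, file.path(tdir, paste0(sen, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    nc <- nrow(tr$cop)
    df <- data.frame(time = fmt(seq(0, by = 1 / tr$cop_rate,
                                    length.out = nc)),
                     AP = fmt(tr$cop[, 1]), ML = fmt(tr$cop[, 2]))
    utils::write.csv(df, file.path(tdir, "cop.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(dir)
}

#' Read a study dataset written by [write_study()]
#'
#' @param dir Directory containing `metadata.csv`, `config.yaml` and
#'   `trials/`.
#' @return A `study_dataset`.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "metadata.csv")
  if (!file.exists(mf)) stop("missing metadata file: ", mf)
  cf <- file.path(dir, "config.yaml")
  if (!file.exists(cf)) stop("missing config file: ", cf)
  meta <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("subject", "posture", "surface", "load", "repetition", "pps")
  if (!all(need %in% names(meta)))
    stop("metadata.csv lacks required columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  extra <- setdiff(names(meta), c(need, "latent"))
  if (length(extra))
    warning("metadata.csv has extra columns (preserved): ",
            paste(extra, collapse = ", "))
  config <- read_study_config(cf)
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    tr <- list(subject_id = meta$subject[i], posture = meta$posture[i],
               surface = meta$surface[i], load = meta$load[i],
               repetition = meta$repetition[i], pps = meta$pps[i],
               latent = if ("latent" %in% names(meta)) meta$latent[i] else NA,
               acc = NULL, cop = NULL,
               acc_rate = config$acc_rate, cop_rate = config$cop_rate)
    tdir <- file.path(dir, "trials", trial_dirname(tr))
    if (dir.exists(tdir)) {
      acc <- lapply(config$sensor_set, function(sen) {
        f <- file.path(tdir, paste0(sen, ".csv"))
        if (!file.exists(f)) stop("missing signal file: ", f)
        m <- as.matrix(utils::read.csv(f)[, c("AP", "ML", "IS")])
        m
      })
      names(acc) <- config$sensor_set
      tr$acc <- acc
      tr$cop <- as.matrix(utils::read.csv(
        file.path(tdir, "cop.csv"))[, c("AP", "ML")])
    }
    structure(tr, class = "trial_recording")
  })
  structure(list(trials = trials, config = config), class = "study_dataset")
}

#' Serialize / restore a study configuration as YAML
#'
#' @param config A [study_config()] object.
#' @param path YAML file path.
#' @return `write_study_config`: `path`, invisibly. `read_study_config`:
#'   a `study_config` object.
#' @export
write_study_config <- function(config, path) {
  ep <- config$effect_params
  lst <- list(
    n_subjects = config$n_subjects, n_repetitions = config$n_repetitions,
    trial_duration = config$trial_duration, acc_rate = config$acc_rate,
    cop_rate = config$cop_rate, sensor_set = as.list(config$sensor_set),
    seed = config$seed, pps_round = config$pps_round,
    effect_params = lapply(unclass(ep), function(x)
      if (is.null(names(x))) unname(x) else as.list(x)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  epl <- lst$effect_params
  num <- function(x) unlist(x, use.names = TRUE)
  ep <- effect_params(
    baseline_log_sway = epl$baseline_log_sway,
    beta_wp = num(epl$beta_wp), beta_ss = epl$beta_ss,
    beta_lc = epl$beta_lc, gamma_wp_lc = num(epl$gamma_wp_lc),
    gamma_wp_ss = num(epl$gamma_wp_ss), gamma_ss_lc = epl$gamma_ss_lc,
    gamma_wp_ss_lc = num(epl$gamma_wp_ss_lc),
    subject_sd = epl$subject_sd, subject_wp_sd = epl$subject_wp_sd,
    subject_ss_sd = epl$subject_ss_sd, subject_lc_sd = epl$subject_lc_sd,
    subject_cond_sd = epl$subject_cond_sd, trial_sd = epl$trial_sd,
    sensor_gains = num(epl$sensor_gains), sway_band = num(epl$sway_band),
    freq_coupling = epl$freq_coupling, cop_gain = epl$cop_gain,
    pps_intercept = epl$pps_intercept, pps_slope = epl$pps_slope,
    pps_noise_sd = epl$pps_noise_sd)
  study_config(n_subjects = lst$n_subjects,
               n_repetitions = lst$n_repetitions,
               trial_duration = lst$trial_duration,
               acc_rate = lst$acc_rate, cop_rate = lst$cop_rate,
               sensor_set = unlist(lst$sensor_set),
               effect_params = ep, seed = lst$seed,
               pps_round = isTRUE(lst$pps_round))
}
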