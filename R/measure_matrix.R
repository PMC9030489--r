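#' Compute the sway-measure matrix for a study
#'
#' Evaluates the 43 measures for every trial x sensor combination.
#'
#' @param dataset A `study_dataset` (or equivalent list of recordings).
#' @param sensors Placements to process (default: the study's sensor set).
#' @param opts A [measure_opts()] object.
#' @return Wide data frame: metadata columns (`subject`, `posture`,
#'   `surface`, `load`, `repetition`, `sensor`) followed by the 43 measure
#'   columns.
#' @export
compute_study_measures <- function(dataset,
                                   sensors = dataset$config$sensor_set,
                                   opts = measure_opts()) {
  rows <- lapply(dataset$trials, function(tr) {
    meta <- data.frame(subject = tr$subject_id, posture = tr$posture,
                       surface = tr$surface, load = tr$load,
                       repetition = tr$repetition)
    vals <- lapply(sensors, function(s)
      as.data.frame(as.list(compute_all_measures(tr, s, opts))))
    out <- do.call(rbind, vals)
    out <- cbind(meta[rep(1, length(sensors)), , drop = FALSE],
                 sensor = sensors, out)
    rownames(out) <- NULL
    out
  })
  res <- do.call(rbind, rows)
  names(res)[-(1:6)] <- measure_names()
  res
}

#' Reshape a wide measure matrix to tidy long format
#'
#' @param wide Output of [compute_study_measures()].
#' @return Long data frame with columns (`subject`, `posture`, `surface`,
#'   `load`, `repetition`, `sensor`, `measure`, `value`).
#' @export
measures_long <- function(wide) {
  meta_cols <- c("subject", "posture", "surface", "load", "repetition",
                 "sensor")
  mcols <- setdiff(names(wide), meta_cols)
  long <- stats::reshape(wide, direction = "long", varying = mcols,
                         v.names = "value", timevar = "measure",
                         times = mcols, idvar = "row_id",
                         ids = seq_len(nrow(wide)))
  rownames(long) <- NULL
  long$row_id <- NULL
  long[order(match(long$measure, mcols)), c(meta_cols, "measure", "value")]
}

#' Per-trial COPV_AP for a study
#'
#' @param dataset A `study_dataset` containing COP signals.
#' @param cutoff Low-pass cutoff (Hz), `NULL` to skip filtering.
#' @return Numeric vector, one mean AP COP velocity (mm/s) per trial.
#' @export
compute_study_copv <- function(dataset, cutoff = 10) {
  vapply(dataset$trials, function(tr) {
    if (is.null(tr$cop)) stop("dataset was simulated without signals")
    copv_ap(tr$cop, tr$cop_rate, cutoff = cutoff)
  }, numeric(1))
}
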