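#' Feature-set and sensor-configuration registries
#'
#' Feature sets: `FS1` = seven time-domain moments (mean, range, variance,
#' standard deviation, root mean squared, skewness, kurtosis); `FS2` = the
#' magnitudes of the first five nonzero-frequency FFT coefficients; `FS3` =
#' their union (twelve features per sensor axis). Sensor configurations:
#' `SC1` = all eight placements, `SC2` = pelvis, T8 and shoulders, `SC3` =
#' pelvis and T8; `pelvis` = pelvis only.
#'
#' @return `feature_names()`: character vector for one feature set.
#'   `sensor_configs()`: named list of placement vectors.
#' @export
feature_names <- function(feature_set = c("FS3", "FS1", "FS2")) {
  feature_set <- match.arg(feature_set)
  fs1 <- c("mean", "range", "variance", "sd", "rms", "skewness", "kurtosis")
  fs2 <- paste0("fft", 1:5)
  switch(feature_set, FS1 = fs1, FS2 = fs2, FS3 = c(fs1, fs2))
}

#' @rdname feature_names
#' @param feature_set One of `"FS1"`, `"FS2"`, `"FS3"`.
#' @export
sensor_configs <- function() {
  list(SC1 = default_sensors(),
       SC2 = c("pelvis", "T8", "shoulder_L", "shoulder_R"),
       SC3 = c("pelvis", "T8"),
       pelvis = "pelvis")
}

axis_features <- function(x, feature_set) {
  out <- numeric(0)
  if (feature_set %in% c("FS1", "FS3")) {
    v <- mean((x - mean(x))^2) * length(x) / (length(x) - 1)
    s <- sqrt(v)
    sk <- if (s == 0) 0 else e1071::skewness(x)
    ku <- if (s == 0) 0 else e1071::kurtosis(x)
    out <- c(mean = mean(x), range = max(x) - min(x), variance = v,
             sd = s, rms = sqrt(mean(x^2)), skewness = sk, kurtosis = ku)
  }
  if (feature_set %in% c("FS2", "FS3")) {
    co <- Mod(stats::fft(x))[2:6]
    names(co) <- paste0("fft", 1:5)
    out <- c(out, co)
  }
  out
}

#' Extract the classification feature matrix
#'
#' Computes the selected feature set per sensor and axis on the raw
#' (unfiltered) acceleration of every trial. The five FFT features are the
#' magnitudes of the lowest five nonzero-frequency coefficients of the
#' unwindowed transform (DC excluded, since it duplicates the mean).
#' Skewness and kurtosis of zero-variance signals are imputed as 0.
#'
#' @param dataset A `study_dataset` with signals.
#' @param sensors A sensor-configuration name (`"SC1"`, `"SC2"`, `"SC3"`,
#'   `"pelvis"`) or an explicit vector of placements.
#' @param feature_set `"FS1"`, `"FS2"` or `"FS3"`.
#' @param filter Low-pass filter axes before extraction (default `FALSE`:
#'   features are defined on raw acceleration).
#' @param cutoff Cutoff (Hz) when `filter = TRUE`.
#' @return Numeric matrix, rows = trials, columns named
#'   `<sensor>.<axis>.<feature>`; attributes `feature_set` and `sensors`.
#' @export
extract_features <- function(dataset, sensors = "SC1", feature_set = "FS3",
                             filter = FALSE, cutoff = 10) {
  if (is.character(sensors) && length(sensors) == 1 &&
      sensors %in% names(sensor_configs()))
    sensors <- sensor_configs()[[sensors]]
  if (!all(sensors %in% default_sensors()))
    stop("unknown sensor placement(s): ",
         paste(setdiff(sensors, default_sensors()), collapse = ", "))
  feature_set <- match.arg(feature_set, c("FS1", "FS2", "FS3"))
  axes <- c("AP", "ML", "IS")
  feats <- feature_names(feature_set)
  cn <- as.vector(outer(feats, as.vector(outer(axes, sensors,
        function(a, s) paste(s, a, sep = "."))),
        function(f, sa) paste(sa, f, sep = ".")))
  rows <- lapply(dataset$trials, function(tr) {
    if (is.null(tr$acc)) stop("dataset was simulated without signals")
    unlist(lapply(sensors, function(sen) {
      m <- tr$acc[[sen]]
      if (is.null(m)) stop("sensor '", sen, "' missing from a trial")
      unlist(lapply(seq_along(axes), function(a) {
        x <- m[, a]
        if (filter) x <- butter_zero_phase(x, tr$acc_rate, cutoff)
        axis_features(x, feature_set)
      }))
    }))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- cn
  structure(mat, feature_set = feature_set, sensors = sensors,
            standardized = FALSE)
}

#' Label trials as stable or unstable
#'
#' `pps` criterion: stable for ratings in `[0, 5)`, unstable for `[5, 10]`.
#' `copv_ap` criterion: stable below the median COPV_AP, unstable at or
#' above it (the boundary trial is unstable).
#'
#' @param dataset A `study_dataset`.
#' @param criterion `"pps"` or `"copv_ap"`.
#' @param copv Optional precomputed per-trial COPV_AP vector (otherwise
#'   computed from the dataset's COP signals).
#' @return Factor with levels `stable`, `unstable`; attribute `criterion`.
#' @export
label_trials <- function(dataset, criterion = c("pps", "copv_ap"),
                         copv = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "pps") {
    v <- vapply(dataset$trials, function(tr) tr$pps, numeric(1))
    if (anyNA(v)) stop("missing PPS ratings for trials: ",
                       paste(which(is.na(v)), collapse = ", "))
    lab <- ifelse(v < 5, "stable", "unstable")
  } else {
    if (is.null(copv)) copv <- compute_study_copv(dataset)
    med <- stats::median(copv)
    lab <- ifelse(copv < med, "stable", "unstable")
  }
  structure(factor(lab, levels = c("stable", "unstable")),
            criterion = criterion)
}

#' Column-wise z-score standardization
#'
#' Centers and scales every column to mean 0 and (population) SD 1.
#' Zero-variance columns are mapped to zeros and recorded in the
#' `constant_columns` attribute. Idempotent.
#'
#' @param features Numeric matrix (rows = trials).
#' @return Standardized matrix with attribute `standardized = TRUE`.
#' @export
zscore_features <- function(features) {
  if (nrow(features) < 2) stop("need at least 2 rows to standardize")
  mu <- colMeans(features)
  sdp <- sqrt(colMeans(sweep(features, 2, mu)^2))
  const <- sdp == 0
  sdp[const] <- 1
  out <- sweep(sweep(features, 2, mu), 2, sdp, "/")
  out[, const] <- 0
  structure(out, feature_set = attr(features, "feature_set"),
            sensors = attr(features, "sensors"), standardized = TRUE,
            constant_columns = colnames(features)[const])
}
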