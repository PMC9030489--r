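# Independent brute-force transcription of the sway-measure definitions.
# Deliberately naive (explicit loops, literal formulas, stats::spec.pgram for
# the periodogram) and kept separate from the package's computation path.

oracle_cumtrapz <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  for (i in 2:n) v[i] <- v[i - 1] + (x[i] + x[i - 1]) / 2 * dt
  v
}

oracle_detrend_line <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm(x ~ t))
}

oracle_mf <- function(x, rate) {
  sp <- stats::spec.pgram(x - mean(x), taper = 0, detrend = FALSE,
                          fast = FALSE, plot = FALSE)
  sum(sp$freq * rate * sp$spec) / sum(sp$spec)
}

# ap/ml/is_ are centered, filtered series; returns all 43 measures.
oracle_measures <- function(ap, ml, is_, rate, per_time = TRUE) {
  n <- length(ap)
  dur <- n / rate
  r2d <- numeric(n); r3d <- numeric(n)
  for (i in 1:n) {
    r2d[i] <- sqrt(ap[i]^2 + ml[i]^2)
    r3d[i] <- sqrt(ap[i]^2 + ml[i]^2 + is_[i]^2)
  }
  out <- c(
    AVG_AP = sum(abs(ap)) / n, AVG_ML = sum(abs(ml)) / n,
    AVG_IS = sum(abs(is_)) / n, AVG_2DR = sum(r2d) / n,
    AVG_3DR = sum(r3d) / n,
    RNG_AP = max(ap) - min(ap), RNG_ML = max(ml) - min(ml),
    RNG_IS = max(is_) - min(is_), RNG_2DR = max(r2d) - min(r2d),
    RNG_3DR = max(r3d) - min(r3d),
    RMS_AP = sqrt(sum(ap^2) / n), RMS_ML = sqrt(sum(ml^2) / n),
    RMS_IS = sqrt(sum(is_^2) / n), RMS_2DR = sqrt(sum(r2d^2) / n),
    RMS_3DR = sqrt(sum(r3d^2) / n))

  # areas about the mean point of the planar trajectory
  apc <- ap - mean(ap); mlc <- ml - mean(ml)
  sw <- 0
  for (i in 1:(n - 1))
    sw <- sw + 0.5 * abs(apc[i] * mlc[i + 1] - apc[i + 1] * mlc[i])
  rd <- sqrt(apc^2 + mlc^2)
  md2 <- mean(rd)
  s_rd <- sqrt(mean(rd^2) - md2^2)
  z <- stats::qnorm(0.975)
  cc <- pi * (md2 + z * s_rd)^2
  covm <- c(mean(apc^2), mean(mlc^2), mean(apc * mlc))
  ce <- 2 * pi * stats::qf(0.95, 2, n - 2) *
    sqrt(covm[1] * covm[2] - covm[3]^2)
  denom <- if (per_time) dur else 1
  out <- c(out, ARE_SW = sw / denom, ARE_CC = cc / denom,
           ARE_CE = ce / denom)

  len2 <- 0
  for (i in 1:(n - 1))
    len2 <- len2 + sqrt((apc[i + 1] - apc[i])^2 + (mlc[i + 1] - mlc[i])^2)
  d_cc <- 2 * (md2 + z * s_rd)
  d_ce <- sqrt(8 * ce / pi)
  out <- c(out,
           FD_CC = log(n) / log(n * d_cc / len2),
           FD_CE = log(n) / log(n * d_ce / len2))

  len_ap <- 0; len_ml <- 0; len3 <- 0
  for (i in 1:(n - 1)) {
    len_ap <- len_ap + abs(ap[i + 1] - ap[i])
    len_ml <- len_ml + abs(ml[i + 1] - ml[i])
    len3 <- len3 + sqrt((ap[i + 1] - ap[i])^2 + (ml[i + 1] - ml[i])^2 +
                          (is_[i + 1] - is_[i])^2)
  }
  out <- c(out, LEN_AP = len_ap, LEN_ML = len_ml,
           LEN_2DR = len2, LEN_3DR = len3,
           MD_AP = sum(abs(ap)) / n, MD_ML = sum(abs(ml)) / n,
           MD_2DR = md2, MD_3DR = sum(r3d) / n,
           MF_AP = oracle_mf(ap, rate), MF_ML = oracle_mf(ml, rate),
           MF_2DR = oracle_mf(r2d, rate), MF_3DR = oracle_mf(r3d, rate))

  dt <- 1 / rate
  v_ap <- oracle_detrend_line(oracle_cumtrapz(ap, dt))
  v_ml <- oracle_detrend_line(oracle_cumtrapz(ml, dt))
  v_is <- oracle_detrend_line(oracle_cumtrapz(is_, dt))
  p_ap <- oracle_detrend_line(oracle_cumtrapz(v_ap, dt))
  p_ml <- oracle_detrend_line(oracle_cumtrapz(v_ml, dt))
  pv <- function(x) mean((x - mean(x))^2)
  out <- c(out,
           MV_AP = mean(abs(v_ap)), MV_ML = mean(abs(v_ml)),
           MV_2DR = mean(sqrt(v_ap^2 + v_ml^2)),
           MV_3DR = mean(sqrt(v_ap^2 + v_ml^2 + v_is^2)),
           PD_P = sqrt(pv(p_ap) + pv(p_ml)),
           PD_V = sqrt(pv(v_ap) + pv(v_ml)),
           PP = sqrt(pv(p_ap) + pv(v_ap)),
           RMSD_AP = sqrt(sum(ap^2) / n), RMSD_ML = sqrt(sum(ml^2) / n),
           RMSD_2DR = sqrt(sum(r2d^2) / n), RMSD_3DR = sqrt(sum(r3d^2) / n))
  out
}
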