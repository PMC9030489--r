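# Orthonormal within-subject contrast matrix for one effect of the
# WP(6) x SS(2) x LC(2) design. Columns of the subject x cell matrix are
# assumed in enumerate_conditions() order (posture slowest, load fastest).
effect_contrasts <- function(effect) {
  orth <- function(k) {
    h <- stats::contr.helmert(k)
    sweep(h, 2, sqrt(colSums(h^2)), "/")
  }
  ones <- function(k) matrix(1 / sqrt(k), k, 1)
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  a_wp <- if ("WP" %in% parts) orth(6) else ones(6)
  a_ss <- if ("SS" %in% parts) orth(2) else ones(2)
  a_lc <- if ("LC" %in% parts) orth(2) else ones(2)
  t(a_wp %x% a_ss %x% a_lc)
}

# Subject x 24 cell-mean matrix from long data (repetitions averaged).
cell_matrix <- function(df) {
  df$posture <- factor(df$posture, levels = wp_levels())
  df$surface <- factor(df$surface, levels = ss_levels())
  df$load <- factor(df$load, levels = lc_levels())
  agg <- stats::aggregate(value ~ subject + posture + surface + load,
                          data = df, FUN = mean)
  subjects <- sort(unique(agg$subject))
  conds <- enumerate_conditions()
  key <- paste(agg$posture, agg$surface, agg$load)
  ckey <- paste(conds$posture, conds$surface, conds$load)
  y <- matrix(NA_real_, length(subjects), 24,
              dimnames = list(subjects, ckey))
  y[cbind(match(agg$subject, subjects), match(key, ckey))] <- agg$value
  if (anyNA(y)) stop("unbalanced design: every subject needs all 24 cells")
  y
}

sphericity_stats <- function(scores) {
  n <- nrow(scores)
  d <- ncol(scores)
  s <- stats::cov(scores)
  tr <- sum(diag(s))
  eps <- tr^2 / (d * sum(s^2))
  eps <- min(max(eps, 1 / d), 1)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || n - 1 < d) {
    w <- NA_real_; chisq <- NA_real_; p <- NA_real_
  } else {
    w <- exp(sum(log(ev)) - d * log(tr / d))
    f <- (2 * d^2 + d + 2) / (6 * d)
    chisq <- -((n - 1) - f) * log(w)
    p <- stats::pchisq(chisq, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  }
  list(W = w, chisq = chisq, df = d * (d + 1) / 2 - 1, p = p,
       epsilon = eps, d = d)
}

#' Mauchly's test of sphericity for a within-subject factor
#'
#' Tests equality of variances of the orthonormal within-subject contrasts
#' of one factor (marginalizing over the others) using the standard
#' chi-square approximation. Two-level factors carry a single contrast, so
#' sphericity holds trivially (`W = 1`, `p = 1`).
#'
#' @param df Long data frame with columns `subject`, `posture`, `surface`,
#'   `load`, `value`.
#' @param factor_name One of `"WP"`, `"SS"`, `"LC"`.
#' @return List with `W`, `chisq`, `df`, `p`.
#' @export
mauchly_test <- function(df, factor_name = "WP") {
  k <- c(WP = 6, SS = 2, LC = 2)[[factor_name]]
  if (k == 2) return(list(W = 1, chisq = 0, df = 0, p = 1))
  y <- cell_matrix(df)
  scores <- y %*% t(effect_contrasts(factor_name))
  s <- sphericity_stats(scores)
  s[c("W", "chisq", "df", "p")]
}

#' Greenhouse-Geisser epsilon for a within-subject factor
#'
#' Epsilon from the sample covariance of orthonormal within-subject
#' contrasts, clamped to `[1/(k-1), 1]` for a k-level factor.
#'
#' @inheritParams mauchly_test
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(df, factor_name = "WP") {
  k <- c(WP = 6, SS = 2, LC = 2)[[factor_name]]
  if (k == 2) return(1)
  y <- cell_matrix(df)
  scores <- y %*% t(effect_contrasts(factor_name))
  sphericity_stats(scores)$epsilon
}

#' Three-way repeated-measures ANOVA with sphericity handling
#'
#' Classical fully-within-subject decomposition of the 6 x 2 x 2 design:
#' each effect is tested against its effect-by-subject interaction.
#' Repetitions are averaged within subject and condition first. For effects
#' involving the six-level posture factor, Mauchly's test is evaluated on
#' the effect's contrast covariance and, when violated at `alpha_sphericity`,
#' the Greenhouse-Geisser epsilon multiplies both degrees of freedom.
#' Two-level effects (single contrast) are exempt.
#'
#' @param df Long data frame with columns `subject`, `posture`, `surface`,
#'   `load`, `value` (and optionally `repetition`, averaged out).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param alpha_sphericity Level of the Mauchly gate (default 0.05).
#' @return Data frame with one row per effect (`SS`, `LC`, `WP`, `SS:LC`,
#'   `SS:WP`, `LC:WP`, `SS:LC:WP`): `F`, `df1`, `df2`, `epsilon`,
#'   `mauchly_W`, `mauchly_p`, `gg_applied`, `p_uncorrected`, `p`,
#'   `significant`.
#' @export
rm_anova_3way <- function(df, alpha = 0.05, alpha_sphericity = 0.05) {
  y <- cell_matrix(df)
  n <- nrow(y)
  if (n < 2) stop("need at least 2 subjects")
  effects <- c("SS", "LC", "WP", "SS:LC", "SS:WP", "LC:WP", "SS:LC:WP")
  out <- lapply(effects, function(eff) {
    cm <- effect_contrasts(eff)
    scores <- y %*% t(cm)
    d <- nrow(cm)
    # univariate within-subject F: effect MS vs effect-by-subject MS
    ss_eff <- n * sum(colMeans(scores)^2)
    resid <- sweep(scores, 2, colMeans(scores))
    ss_err <- sum(resid^2)
    df1 <- d
    df2 <- d * (n - 1)
    f_stat <- (ss_eff / df1) / (ss_err / df2)
    p_unc <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    has_wp <- grepl("WP", eff)
    if (has_wp) {
      sph <- sphericity_stats(scores)
      eps <- sph$epsilon
      mw <- sph$W
      mp <- sph$p
      gg <- is.finite(mp) && mp < alpha_sphericity
    } else {
      eps <- 1; mw <- 1; mp <- 1; gg <- FALSE
    }
    p_adj <- if (gg)
      stats::pf(f_stat, df1 * eps, df2 * eps, lower.tail = FALSE)
    else p_unc
    data.frame(effect = eff, F = f_stat,
               df1 = if (gg) df1 * eps else df1,
               df2 = if (gg) df2 * eps else df2,
               epsilon = eps, mauchly_W = mw, mauchly_p = mp,
               gg_applied = gg, p_uncorrected = p_unc, p = p_adj,
               significant = is.finite(p_adj) && p_adj < alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All pairwise paired t-tests for one factor
#'
#' Compares subject-level marginal means between every pair of factor
#' levels with two-sided paired t-tests.
#'
#' @inheritParams mauchly_test
#' @param correction `"none"` (default) or `"holm"`.
#' @return Data frame with `level1`, `level2`, `t`, `df`, `p`, `p_adj`.
#' @export
paired_ttests <- function(df, factor_name = "WP", correction = "none") {
  correction <- match.arg(correction, c("none", "holm"))
  col <- c(WP = "posture", SS = "surface", LC = "load")[[factor_name]]
  agg <- stats::aggregate(df$value,
                          by = list(subject = df$subject, level = df[[col]]),
                          FUN = mean)
  levs <- levels(factor(agg$level,
                        levels = switch(factor_name, WP = wp_levels(),
                                        SS = ss_levels(), LC = lc_levels())))
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- agg$x[agg$level == pr[1]][order(agg$subject[agg$level == pr[1]])]
    y <- agg$x[agg$level == pr[2]][order(agg$subject[agg$level == pr[2]])]
    d <- x - y
    if (stats::sd(d) == 0) {
      data.frame(level1 = pr[1], level2 = pr[2], t = if (all(d == 0)) 0 else NA,
                 df = length(d) - 1, p = if (all(d == 0)) 1 else NA)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(level1 = pr[1], level2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  res <- do.call(rbind, res)
  res$p_adj <- if (correction == "holm") stats::p.adjust(res$p, "holm") else res$p
  res
}

#' Per-cell Shapiro-Wilk normality diagnostics
#'
#' Normality of the subject distribution is screened per design cell and
#' reported as a diagnostic only; it never switches the analysis path.
#'
#' @param df Long data frame (`subject`, `posture`, `surface`, `load`,
#'   `value`).
#' @return Data frame with one row per cell: `posture`, `surface`, `load`,
#'   `W`, `p`.
#' @export
shapiro_by_cell <- function(df) {
  agg <- stats::aggregate(value ~ subject + posture + surface + load,
                          data = df, FUN = mean)
  cells <- unique(agg[c("posture", "surface", "load")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- agg$posture == cells$posture[i] & agg$surface == cells$surface[i] &
      agg$load == cells$load[i]
    v <- agg$value[sel]
    sw <- if (length(v) >= 3 && stats::sd(v) > 0)
      stats::shapiro.test(v) else list(statistic = NA, p.value = NA)
    cbind(cells[i, ], W = unname(sw$statistic), p = sw$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the factor-effect scan over measures and sensors
#'
#' Applies [rm_anova_3way()] to every measure x sensor slice of a wide
#' measure matrix.
#'
#' @param measures Wide matrix from [compute_study_measures()].
#' @param measure_cols Measure columns to scan (default [measure_names()]).
#' @param sensors Sensors to scan (default: those present).
#' @param alpha Significance level (default 0.05).
#' @return Long data frame: `sensor`, `measure`, then the [rm_anova_3way()]
#'   columns. Measures with missing values for a sensor yield `NA` rows.
#' @export
run_effects_scan <- function(measures, measure_cols = NULL, sensors = NULL,
                             alpha = 0.05) {
  if (is.null(measure_cols))
    measure_cols <- intersect(measure_names(), names(measures))
  if (is.null(sensors)) sensors <- unique(measures$sensor)
  out <- list()
  for (sen in sensors) {
    sl <- measures[measures$sensor == sen, ]
    for (mc in measure_cols) {
      df <- data.frame(subject = sl$subject, posture = sl$posture,
                       surface = sl$surface, load = sl$load,
                       value = sl[[mc]])
      if (anyNA(df$value)) {
        tab <- data.frame(effect = c("SS", "LC", "WP", "SS:LC", "SS:WP",
                                     "LC:WP", "SS:LC:WP"),
                          F = NA, df1 = NA, df2 = NA, epsilon = NA,
                          mauchly_W = NA, mauchly_p = NA, gg_applied = NA,
                          p_uncorrected = NA, p = NA, significant = NA)
      } else {
        tab <- rm_anova_3way(df, alpha = alpha)
      }
      out[[length(out) + 1L]] <- cbind(sensor = sen, measure = mc, tab)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detection-count summary across measures
#'
#' Counts, per sensor and effect, how many measures detected the effect
#' (`p < alpha`), with main-effect and interaction-effect row sums --
#' the layout used to compare sensor placements.
#'
#' @param scan Output of [run_effects_scan()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per sensor: counts for `SS`, `LC`, `WP`,
#'   `main_sum`, `SS:LC`, `SS:WP`, `LC:WP`, `SS:LC:WP`, `interaction_sum`,
#'   and `n_excluded` (measures with undefined values).
#' @export
detection_summary <- function(scan, alpha = 0.05) {
  effs <- c("SS", "LC", "WP", "SS:LC", "SS:WP", "LC:WP", "SS:LC:WP")
  sensors <- unique(scan$sensor)
  rows <- lapply(sensors, function(sen) {
    sl <- scan[scan$sensor == sen, ]
    cnt <- vapply(effs, function(e) {
      p <- sl$p[sl$effect == e]
      sum(p < alpha, na.rm = TRUE)
    }, numeric(1))
    excl <- length(unique(sl$measure[is.na(sl$p)]))
    data.frame(sensor = sen, SS = cnt[["SS"]], LC = cnt[["LC"]],
               WP = cnt[["WP"]],
               main_sum = cnt[["SS"]] + cnt[["LC"]] + cnt[["WP"]],
               `SS:LC` = cnt[["SS:LC"]], `SS:WP` = cnt[["SS:WP"]],
               `LC:WP` = cnt[["LC:WP"]], `SS:LC:WP` = cnt[["SS:LC:WP"]],
               interaction_sum = sum(cnt[4:7]),
               n_excluded = excl, check.names = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
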