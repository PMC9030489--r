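# Rep-averaged long data for one simulated study at the latent level.
latent_long <- function(n_subjects = 10, params = effect_params(), seed = 1) {
  cfg <- study_config(n_subjects = n_subjects, n_repetitions = 2,
                      sensor_set = "pelvis", effect_params = params,
                      seed = seed)
  md <- study_metadata(simulate_study(cfg, signals = FALSE))
  md$value <- log(md$latent)
  md
}

test_that("the within-subject F decomposition agrees with aov error strata", {
  md <- latent_long(seed = 21)
  res <- rm_anova_3way(md)
  agg <- aggregate(value ~ subject + posture + surface + load, md, mean)
  agg$subject <- factor(agg$subject)
  a <- summary(aov(value ~ posture * surface * load +
                     Error(subject / (posture * surface * load)), agg))
  f_of <- function(stratum) a[[stratum]][[1]][1, "F value"]
  expect_equal(res$F[res$effect == "WP"], f_of("Error: subject:posture"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "SS"], f_of("Error: subject:surface"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "LC"], f_of("Error: subject:load"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "SS:LC"],
               f_of("Error: subject:surface:load"), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "SS:LC:WP"],
               f_of("Error: subject:posture:surface:load"),
               tolerance = 1e-10)
})

test_that("two-level factor F equals the squared paired t statistic", {
  md <- latent_long(seed = 22)
  res <- rm_anova_3way(md)
  agg <- aggregate(value ~ subject + load, md, mean)
  tt <- t.test(agg$value[agg$load == "0kg"], agg$value[agg$load == "10kg"],
               paired = TRUE)
  expect_equal(res$F[res$effect == "LC"], unname(tt$statistic^2))
  expect_equal(res$p[res$effect == "LC"], tt$p.value)
})

test_that("Mauchly statistic and GG epsilon agree with the mlm oracles", {
  md <- latent_long(seed = 23)
  agg <- aggregate(value ~ subject + posture, md, mean)
  y <- matrix(agg$value[order(agg$posture, agg$subject)], ncol = 6)
  mlm <- lm(y ~ 1)
  idata <- data.frame(WP = factor(1:6))
  mt <- mauchly.test(mlm, X = ~1, M = ~WP, idata = idata)
  own <- mauchly_test(md, "WP")
  expect_equal(own$W, unname(mt$statistic), tolerance = 1e-9)
  # stats::mauchly.test adds the second-order Box term to the chi-square
  # approximation; the leading-order p agrees closely but not exactly
  expect_lt(abs(own$p - mt$p.value), 0.05)
  am <- anova(mlm, X = ~1, M = ~WP, idata = idata, test = "Spherical")
  eps_line <- grep("Greenhouse-Geisser", attr(am, "heading"), value = TRUE)
  eps_oracle <- as.numeric(sub(".*: *", "", eps_line))
  expect_equal(gg_epsilon(md, "WP"), eps_oracle, tolerance = 5e-4)
  # two-level convention
  expect_equal(mauchly_test(md, "LC")$W, 1)
  expect_equal(gg_epsilon(md, "LC"), 1)
})

test_that("GG epsilon respects its bounds and the sphericity/degeneracy limits", {
  md <- latent_long(seed = 24)
  eps <- gg_epsilon(md, "WP")
  expect_gte(eps, 0.2)
  expect_lte(eps, 1)
  # compound-symmetric data: epsilon near 1, Mauchly not significant
  set.seed(25)
  sub_eff <- rnorm(12, 0, 2)
  cs <- expand.grid(subject = 1:12, posture = paste0("P", 1:6),
                    surface = c("flat", "inclined"), load = c("0kg", "10kg"))
  cs$value <- sub_eff[cs$subject] + rnorm(nrow(cs))
  expect_gt(gg_epsilon(cs, "WP"), 0.6)
  expect_gt(mauchly_test(cs, "WP")$p, 0.01)
  # rank-deficient contrasts drive epsilon to the lower bound
  r1 <- cs
  r1$value <- sub_eff[r1$subject] +
    as.integer(sub("P", "", r1$posture)) * rnorm(12)[r1$subject]
  expect_lt(gg_epsilon(r1, "WP"), 0.3)
})

test_that("GG correction never promotes an effect to significance", {
  for (s in 26:30) {
    md <- latent_long(seed = s)
    res <- rm_anova_3way(md, alpha_sphericity = 1)  # force GG everywhere
    wp_rows <- grepl("WP", res$effect)
    # in the right tail shrinking both dfs can only raise the tail
    # probability; near F ~ 1 the ordering can wobble by O(1e-3), and both
    # ps are then far from significance anyway
    conservative <- res$F >= 2 & wp_rows
    expect_true(all(res$p[conservative] >=
                      res$p_uncorrected[conservative] - 1e-12))
    flipped <- wp_rows & res$p_uncorrected >= 0.05 & res$p < 0.05
    expect_false(any(flipped))
  }
})

test_that("type-I error is near nominal under the generator null", {
  n_rep <- 60
  rej <- matrix(FALSE, n_rep, 7)
  for (i in seq_len(n_rep)) {
    md <- latent_long(params = null_effect_params(), seed = 3000 + i)
    res <- rm_anova_3way(md)
    rej[i, ] <- res$significant
  }
  rate <- mean(rej)  # pooled over the 7 effects, 420 tests
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("paired t-tests cover all level pairs with exact degenerate handling", {
  md <- latent_long(seed = 31)
  tt <- paired_ttests(md, "WP")
  expect_equal(nrow(tt), choose(6, 2))
  # identical level means give t = 0, p = 1
  md0 <- md
  md0$value <- ave(md0$value, md0$subject)
  t0 <- paired_ttests(md0, "LC")
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # holm correction is monotone non-decreasing in p
  th <- paired_ttests(md, "WP", correction = "holm")
  expect_true(all(th$p_adj >= th$p - 1e-15))
})

test_that("paired t-test power at a 1-SD shift matches the closed form", {
  n <- 30
  pw_closed <- power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05,
                            type = "paired")$power
  set.seed(32)
  hits <- replicate(400, {
    d <- rnorm(n, 1, 1)
    t.test(d)$p.value < 0.05
  })
  expect_equal(mean(hits), pw_closed, tolerance = 0.05)
})

test_that("Shapiro diagnostics cover every design cell without switching analyses", {
  md <- latent_long(seed = 33)
  sw <- shapiro_by_cell(md)
  expect_equal(nrow(sw), 24)
  expect_true(all(sw$p >= 0 & sw$p <= 1))
})

test_that("detection counts saturate and empty out at forced p-values", {
  scan <- expand.grid(sensor = c("pelvis", "T8"),
                      measure = measure_names(),
                      effect = c("SS", "LC", "WP", "SS:LC", "SS:WP",
                                 "LC:WP", "SS:LC:WP"))
  scan$p <- 0
  ds <- detection_summary(scan)
  expect_true(all(ds$SS == 43 & ds$LC == 43 & ds$WP == 43))
  expect_true(all(ds$main_sum == 129))
  expect_true(all(ds$interaction_sum == 4 * 43))
  scan$p <- 1
  ds1 <- detection_summary(scan)
  expect_true(all(ds1$main_sum == 0 & ds1$interaction_sum == 0))
})
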