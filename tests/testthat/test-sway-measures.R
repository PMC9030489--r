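test_that("the registry names exactly 43 measures with the family counts", {
  nm <- measure_names()
  expect_length(nm, 43)
  expect_equal(anyDuplicated(nm), 0L)
  fam <- table(sub("_.*", "", nm))
  expect_equal(fam[["AVG"]], 5)
  expect_equal(fam[["RNG"]], 5)
  expect_equal(fam[["RMS"]], 5)
  expect_equal(fam[["ARE"]], 3)
  expect_equal(fam[["FD"]], 2)
  expect_equal(fam[["LEN"]], 4)
  expect_equal(fam[["MD"]], 4)
  expect_equal(fam[["MF"]], 4)
  expect_equal(fam[["MV"]], 4)
  expect_equal(fam[["PD"]], 2)
  expect_equal(fam[["PP"]], 1)
  expect_equal(fam[["RMSD"]], 4)
})

test_that("amplitude statistics match closed forms on a unit sinusoid", {
  fs <- 240
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  d <- derive_directions(cbind(sin(2 * pi * 1.5 * t), 0, 0), fs,
                         detrend_axes = TRUE)
  bs <- basic_stats(d)
  expect_equal(bs[["RMS_AP"]], 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(bs[["RNG_AP"]], 2, tolerance = 1e-6)
  expect_equal(bs[["AVG_AP"]], 2 / pi, tolerance = 1e-3)
  zero <- derive_directions(matrix(0, 100, 3), fs)
  expect_true(all(basic_stats(zero) == 0))
})

test_that("planar distance statistics approach Rayleigh moments for Gaussian sway", {
  sig <- 0.25
  set.seed(10)
  reps <- replicate(40, {
    d <- derive_directions(cbind(rnorm(2400, 0, sig), rnorm(2400, 0, sig), 0),
                           240)
    bs <- basic_stats(d)
    c(bs[["MD_2DR"]], bs[["RMSD_2DR"]])
  })
  expect_equal(mean(reps[1, ]), sig * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(mean(reps[2, ]), sig * sqrt(2), tolerance = 0.01)
})

test_that("trajectory length telescopes, vanishes on constants and is homogeneous", {
  n <- 100
  ramp <- derive_directions(cbind(seq(0, 1, length.out = n), 0, 0), 240,
                            detrend_axes = FALSE)
  expect_equal(trajectory_length(ramp)[["LEN_AP"]], 1)
  flat <- derive_directions(matrix(2, n, 3), 240, detrend_axes = FALSE)
  expect_true(all(trajectory_length(flat) == 0))
  d <- gaussian_directions(n = 500, seed = 11)
  dk <- derive_directions(cbind(d$ap, d$ml, d$is_) * 3.5, 240,
                          detrend_axes = FALSE)
  expect_equal(trajectory_length(dk), 3.5 * trajectory_length(d))
})

test_that("confidence-ellipse area approaches 6*pi*sigma^2 and areas scale quadratically", {
  sig <- 0.3
  set.seed(12)
  ce <- replicate(30, {
    d <- derive_directions(cbind(rnorm(2400, 0, sig), rnorm(2400, 0, sig), 0),
                           240)
    area_measures(d, per_time = FALSE)[["ARE_CE"]]
  })
  expect_equal(mean(ce), 6 * pi * sig^2, tolerance = 0.02)
  d <- gaussian_directions(n = 600, seed = 13)
  a1 <- area_measures(d)
  dk <- derive_directions(cbind(d$ap, d$ml, d$is_) * 2, d$rate,
                          detrend_axes = FALSE)
  expect_equal(area_measures(dk), 4 * a1, tolerance = 1e-9)
  zero <- derive_directions(matrix(0, 100, 3), 240)
  expect_true(all(area_measures(zero) == 0))
})

test_that("fractal dimension is scale invariant and near 1 for a jittered line", {
  d <- gaussian_directions(n = 800, seed = 14)
  fd <- fractal_dimension(d)
  dk <- derive_directions(cbind(d$ap, d$ml, d$is_) * 9.7, d$rate,
                          detrend_axes = FALSE)
  expect_equal(fractal_dimension(dk), fd, tolerance = 1e-9)
  # monotone near-straight planar segment
  set.seed(15)
  n <- 500
  line <- derive_directions(
    cbind(seq(0, 1, length.out = n) + rnorm(n, 0, 1e-5),
          seq(0, 0.5, length.out = n) + rnorm(n, 0, 1e-5), 0),
    240, detrend_axes = FALSE)
  expect_equal(fractal_dimension(line)[["FD_CC"]], 1, tolerance = 0.1)
  # degenerate trajectory is flagged undefined
  zero <- derive_directions(matrix(0, 100, 3), 240)
  expect_true(all(is.na(fractal_dimension(zero))))
})

test_that("mean frequency matches spectral closed forms", {
  fs <- 240
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone <- derive_directions(cbind(sin(2 * pi * 1.5 * t), 0, 0), fs)
  expect_equal(mean_frequency(tone)[["MF_AP"]], 1.5, tolerance = 0.1)
  two <- derive_directions(
    cbind(sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t), 0, 0), fs)
  expect_equal(mean_frequency(two)[["MF_AP"]], 2, tolerance = 0.1)
  set.seed(16)
  white <- replicate(20, {
    d <- derive_directions(cbind(rnorm(2400), 0, 0), fs)
    mean_frequency(d)[["MF_AP"]]
  })
  expect_equal(mean(white), fs / 4, tolerance = 0.02)
  zero <- derive_directions(matrix(0, 100, 3), fs)
  expect_true(all(is.na(mean_frequency(zero))))
})

test_that("integral measures obey linearity and the sinusoid closed form", {
  fs <- 240
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  d <- derive_directions(cbind(sin(2 * pi * t), 0, 0), fs)
  im <- integrate_measures(d)
  expect_equal(im[["MV_AP"]], (2 / pi) / (2 * pi), tolerance = 1e-3)
  zero <- derive_directions(matrix(0, 100, 3), fs)
  expect_true(all(integrate_measures(zero) == 0))
  g <- gaussian_directions(n = 600, seed = 17)
  gk <- derive_directions(cbind(g$ap, g$ml, g$is_) * 4, g$rate,
                          detrend_axes = FALSE)
  expect_equal(integrate_measures(gk), 4 * integrate_measures(g),
               tolerance = 1e-9)
})

test_that("every measure matches the independent brute-force transcription", {
  set.seed(18)
  for (i in 1:10) {
    n <- sample(c(600, 1200, 2400), 1)
    sd <- runif(1, 0.05, 0.5)
    acc <- matrix(rnorm(3 * n, 0, sd), n, 3)
    d <- derive_directions(acc, 240, detrend_axes = TRUE)
    mine <- compute_measures(d)
    orc <- oracle_measures(d$ap, d$ml, d$is_, 240)[measure_names()]
    spectral <- grepl("^MF", names(mine))
    expect_equal(mine[!spectral], orc[!spectral], tolerance = 1e-9)
    expect_equal(mine[spectral], orc[spectral], tolerance = 1e-6)
  }
})

test_that("measure vector properties: count, determinism, RMSD >= MD, homogeneity", {
  ds <- fixture_small_study()
  tr <- ds$trials[[1]]
  v1 <- compute_all_measures(tr, "pelvis")
  v2 <- compute_all_measures(tr, "pelvis")
  expect_identical(v1, v2)
  expect_length(v1, 43)
  expect_named(v1, measure_names())
  for (dir in c("AP", "ML", "2DR", "3DR"))
    expect_gte(v1[[paste0("RMSD_", dir)]], v1[[paste0("MD_", dir)]])
  expect_equal(v1[["RMS_2DR"]]^2, v1[["RMS_AP"]]^2 + v1[["RMS_ML"]]^2,
               tolerance = 1e-9)
  expect_error(compute_all_measures(tr, "nonexistent"), "not present")
  # homogeneity of the full vector under signal scaling
  d <- gaussian_directions(n = 600, seed = 19)
  dk <- derive_directions(cbind(d$ap, d$ml, d$is_) * 2, d$rate,
                          detrend_axes = FALSE)
  m1 <- compute_measures(d)
  m2 <- compute_measures(dk)
  lin <- grep("^(AVG|RNG|RMS|MD|RMSD|LEN|MV|PD)|^PP$", measure_names(),
              value = TRUE)
  expect_equal(m2[lin], 2 * m1[lin], tolerance = 1e-9)
  expect_equal(m2[c("ARE_SW", "ARE_CC", "ARE_CE")],
               4 * m1[c("ARE_SW", "ARE_CC", "ARE_CE")], tolerance = 1e-9)
  inv <- c("FD_CC", "FD_CE", "MF_AP", "MF_ML", "MF_2DR", "MF_3DR")
  expect_equal(m2[inv], m1[inv], tolerance = 1e-9)
})

test_that("measures rise monotonically with the generator's latent instability", {
  set.seed(20)
  ladder <- exp(seq(log(0.05), log(0.5), length.out = 10))
  vals <- sapply(ladder, function(inst) {
    acc <- sapply(1:3, function(a) {
      x <- rnorm(2400)
      x <- swaylab:::bandpass_zero_phase(x, 240, c(0.1, 3))
      x <- x - mean(x)
      x / sd(x) * inst
    })
    compute_measures(derive_directions(acc, 240))[["RMS_2DR"]]
  })
  expect_gt(cor(vals, ladder, method = "spearman"), 0.9)
})

test_that("length per-second variant and rotational mean frequency follow closed forms", {
  fs <- 240
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  d <- derive_directions(cbind(seq(0, 5, length.out = length(t)), 0, 0), fs,
                         detrend_axes = FALSE)
  expect_equal(trajectory_length(d)[["LEN_AP"]], 5)
  expect_equal(trajectory_length(d, per_second = TRUE)[["LEN_AP"]], 0.5)
  # circular sway at f Hz has rotational mean frequency f
  f0 <- 1.25
  circ <- derive_directions(cbind(sin(2 * pi * f0 * t),
                                  cos(2 * pi * f0 * t), 0), fs)
  expect_equal(mfreq_rotational(circ)[["MFREQ_2DR"]], f0, tolerance = 0.01)
})

test_that("COPV_AP follows path-over-duration arithmetic", {
  ramp <- cbind(seq(0, 30, length.out = 400), 0)
  expect_equal(copv_ap(ramp, 40, cutoff = NULL), 3)
  expect_equal(copv_ap(ramp, 40, cutoff = 10), 3, tolerance = 1e-3)
  expect_equal(copv_ap(cbind(rep(5, 400), 0), 40, cutoff = NULL), 0)
  tri <- cbind(c(seq(0, 10, length.out = 101)[-101],
                 seq(10, 0, length.out = 101)[-101],
                 seq(0, 10, length.out = 101)[-101],
                 seq(10, 0, length.out = 101)[-101]), 0)
  expect_equal(copv_ap(tri, 40, cutoff = NULL), 4, tolerance = 0.01)
  expect_error(copv_ap(cbind(1, 1), 40), "short")
})
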