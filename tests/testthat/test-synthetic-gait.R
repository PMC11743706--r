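# Synthetic cohort generator: sample counts, ground-truth structure,
# determinism, calibration and raw-series/trace closure.

test_that("default cohort has the study design's 300 samples", {
  cohort <- generate_cohort(cohort_config(seed = 11))
  expect_equal(nrow(cohort), 300L)
  expect_equal(length(unique(cohort$subject_id)), 30L)
  expect_setequal(unique(cohort$foot), c("left", "right"))
  expect_true(all(cohort[paste0("region_", 1:10)] >= 0))
  expect_true(all(cohort$stiffness >= 70 & cohort$stiffness <= 1900))
})

test_that("degenerate generator settings collapse to the intercept", {
  cfg <- cohort_config(n_subjects = 4, noise_sd = 0, nonlinearity_scale = 0,
                       effect_magnitudes = rep(0, 10), seed = 5)
  cohort <- generate_cohort(cfg)
  expect_equal(cohort$stiffness, rep(cfg$stiffness_intercept, nrow(cohort)))
  expect_false(any(cohort$clipped))
})

test_that("single-region linear ground truth matches direct formula evaluation", {
  mags <- c(1, rep(0, 9))
  cfg <- cohort_config(n_subjects = 4, noise_sd = 0, nonlinearity_scale = 0,
                       effect_magnitudes = mags,
                       effect_signs = c(1, rep(-1, 4), rep(1, 5)), seed = 8)
  cohort <- generate_cohort(cfg)
  # stiffness differences between any two samples equal their region-1
  # pressure differences (hand evaluation of the linear generator)
  d_k <- diff(cohort$stiffness)
  d_p <- diff(cohort$region_1)
  expect_equal(d_k, d_p, tolerance = 1e-12)
  # and absolute values match the generator formula evaluated by hand
  expect_equal(cohort$stiffness,
               cfg$stiffness_intercept +
                 (cohort$region_1 - cfg$region_mean_profile[1]),
               tolerance = 1e-12)
})

test_that("identical seeds give byte-identical cohorts; config is validated", {
  a <- generate_cohort(cohort_config(n_subjects = 3, seed = 77))
  b <- generate_cohort(cohort_config(n_subjects = 3, seed = 77))
  expect_identical(a, b)
  expect_error(cohort_config(subject_sd = rep(-1, 10)), "deviations")
  expect_error(cohort_config(effect_magnitudes = rep(-0.1, 10)), "magnitudes")
  expect_error(cohort_config(effect_signs = rep(0, 10)), "signs")
})

test_that("default configuration is calibrated to the reported cohort stiffness", {
  draws <- do.call(rbind, lapply(1:4, function(s) {
    as.data.frame(generate_cohort(cohort_config(seed = 1000 + s)))
  }))
  expect_gte(nrow(draws), 1000L)
  expect_gt(mean(draws$stiffness), 470)
  expect_lt(mean(draws$stiffness), 485)
  expect_gt(sd(draws$stiffness), 10)
  expect_lt(sd(draws$stiffness), 25)
})

test_that("effect signs are recoverable by least squares on a noise-free linear cohort", {
  cfg <- cohort_config(noise_sd = 0, nonlinearity_scale = 0, seed = 21)
  cohort <- generate_cohort(cfg)
  X <- as.matrix(cohort[paste0("region_", 1:10)])
  fit <- lm.fit(cbind(1, X), cohort$stiffness)
  expect_identical(unname(sign(fit$coefficients[-1])), cfg$effect_signs)
})

test_that("stance series reproduce tabular means and frame arithmetic", {
  p <- c(80, 30, 90, 120, 130, 110, 60, 70, 150, 130)
  ss <- generate_stance_series(p, fs = 120, duration = 0.75, seed = 4)
  expect_equal(nrow(ss$frames), 90L)
  expect_equal(unname(mean_regional_pressure(ss)), p, tolerance = 1e-9)
  ss2 <- generate_stance_series(p, fs = 120, duration = 0.75, seed = 4)
  expect_identical(ss$frames, ss2$frames)
  expect_true(all(ss$frames >= 0))
})

test_that("oscillation traces close the stiffness formula within 1%", {
  for (k in c(200, 500, 1200)) {
    tr <- generate_oscillation(k, probe_mass = 0.018, seed = 2)
    khat <- compute_stiffness(extract_oscillation_features(tr, 0.018))
    expect_lt(abs(khat - k) / k, 0.01)
  }
  tr1 <- generate_oscillation(500, noise_sd = 1, seed = 10)
  tr2 <- generate_oscillation(500, noise_sd = 1, seed = 10)
  expect_identical(tr1$acceleration, tr2$acceleration)
  expect_error(generate_oscillation(-5), "stiffness")
})

test_that("zero damping and unit mass oscillate at sqrt(k)", {
  k <- 400
  tr <- generate_oscillation(k, probe_mass = 1, damping_ratio = 0,
                             n_cycles = 6)
  # angular frequency from zero crossings of displacement
  sgn <- sign(tr$displacement)
  crossings <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  period <- 2 * mean(diff(tr$time[crossings]))
  expect_equal(2 * pi / period, sqrt(k), tolerance = 1e-2)
})

test_that("cohort CSV round-trips with its configuration sidecar", {
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 9))
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back)[names(as.data.frame(cohort))],
               as.data.frame(cohort), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "config")$seed, 9L)
})
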