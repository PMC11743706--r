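# Synthetic gait cohort generator: seeded regional-pressure features with a
# known pressure->stiffness ground truth, plus raw stance-phase series and
# damped-oscillation traces so the measurement formulas can be exercised
# end to end without laboratory data.

#' Configuration of a synthetic gait cohort
#'
#' Defines the statistical structure of a simulated walking study: a cohort
#' of subjects, each walking several trials on both feet, with mean regional
#' plantar pressures drawn around a cohort-level loading profile and a
#' ground-truth stiffness that responds linearly (plus an optional smooth
#' interaction) to regional pressure deviations.
#'
#' The ground truth for a sample with pressures \eqn{F} is
#' \deqn{k = k_0 + \sum_i s_i m_i (F_i - \mu_i) + \lambda\, g(F)}
#' where \eqn{k_0} is `stiffness_intercept`, \eqn{s_i} the `effect_signs`,
#' \eqn{m_i} the `effect_magnitudes`, \eqn{\mu_i} the `region_mean_profile`
#' and \eqn{g(F) = z_5 z_9} with \eqn{z_i = (F_i-\mu_i)/\mu_i} a smooth
#' forefoot-by-heel interaction (metatarsal 3 x medial heel relative loads)
#' scaled by `nonlinearity_scale` (N/m).  Observed stiffness adds Gaussian
#' measurement noise and is clipped to the device range 70--1900 N/m
#' (clipped rows are flagged, never dropped, so sample counts stay exact).
#'
#' Defaults describe a heel- and metatarsal-dominant walking load with
#' between-subject variation of 10% and trial-to-trial variation of 5% of
#' the regional mean, and are calibrated so the simulated cohort stiffness
#' is about 477 +/- 15 N/m.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_trials Walking trials per subject (default 5).
#' @param feet Character subset of `c("left", "right")`; both by default.
#' @param region_mean_profile Cohort-level mean pressure per region (N),
#'   length 10, region order as [plantar_regions()].
#' @param subject_sd Between-subject SD per region (N), length 10.
#' @param trial_sd Within-subject trial SD per region (N), length 10.
#' @param effect_signs Ground-truth direction (+1/-1) of each region's
#'   effect on stiffness, length 10.
#' @param effect_magnitudes Nonnegative effect sizes (N/m per N), length 10.
#' @param stiffness_intercept Baseline stiffness (N/m).
#' @param noise_sd Measurement noise SD of observed stiffness (N/m).
#' @param nonlinearity_scale Scale (N/m) of the smooth interaction term;
#'   0 gives a purely linear ground truth.
#' @param stiffness_pairing `"per_trial"` pairs every walking trial with one
#'   noisy stiffness measurement; `"mean_of_repeats"` pairs it with the mean
#'   of `n_stiffness_repeats` simulated repeats (noise SD shrinks by
#'   `sqrt(n_stiffness_repeats)`).
#' @param n_stiffness_repeats Repeats averaged in `"mean_of_repeats"` mode.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 30,
                          n_trials = 5,
                          feet = c("left", "right"),
                          region_mean_profile = c(80, 30, 90, 120, 130,
                                                  110, 60, 70, 150, 130),
                          subject_sd = 0.10 * region_mean_profile,
                          trial_sd = 0.05 * region_mean_profile,
                          effect_signs = c(-1, -1, -1, 1, 1, 1, 1, -1, 1, 1),
                          effect_magnitudes = rep(0.4, 10),
                          stiffness_intercept = 477,
                          noise_sd = 4,
                          nonlinearity_scale = 0,
                          stiffness_pairing = c("per_trial", "mean_of_repeats"),
                          n_stiffness_repeats = 5,
                          seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_trials <- check_count(n_trials, "n_trials")
  feet <- match.arg(feet, c("left", "right"), several.ok = TRUE)
  stiffness_pairing <- match.arg(stiffness_pairing)
  for (v in c("region_mean_profile", "subject_sd", "trial_sd",
              "effect_signs", "effect_magnitudes")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != N_REGIONS || anyNA(val)) {
      stopf("'%s' must be a numeric vector of length %d", v, N_REGIONS)
    }
  }
  if (any(region_mean_profile < 0)) stopf("'region_mean_profile' must be >= 0")
  if (any(subject_sd < 0) || any(trial_sd < 0)) {
    stopf("standard deviations must be >= 0")
  }
  if (any(effect_magnitudes < 0)) stopf("'effect_magnitudes' must be >= 0")
  if (!all(effect_signs %in% c(-1, 1))) {
    stopf("'effect_signs' must be +1 or -1")
  }
  check_number(stiffness_intercept, "stiffness_intercept", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(nonlinearity_scale, "nonlinearity_scale", lower = 0)
  n_stiffness_repeats <- check_count(n_stiffness_repeats,
                                     "n_stiffness_repeats")
  cfg <- list(
    n_subjects = n_subjects, n_trials = n_trials, feet = feet,
    region_mean_profile = region_mean_profile,
    subject_sd = subject_sd, trial_sd = trial_sd,
    effect_signs = effect_signs, effect_magnitudes = effect_magnitudes,
    stiffness_intercept = stiffness_intercept, noise_sd = noise_sd,
    nonlinearity_scale = nonlinearity_scale,
    stiffness_pairing = stiffness_pairing,
    n_stiffness_repeats = n_stiffness_repeats,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

# Myoton device operating range (N/m); draws outside it are clipped+flagged.
STIFFNESS_RANGE <- c(70, 1900)

# Ground-truth stiffness for a matrix of pressures (rows = samples).
true_stiffness <- function(P, config) {
  mu <- config$region_mean_profile
  dev <- sweep(P, 2L, mu)
  lin <- drop(dev %*% (config$effect_signs * config$effect_magnitudes))
  k <- config$stiffness_intercept + lin
  if (config$nonlinearity_scale > 0) {
    z <- sweep(dev, 2L, pmax(mu, .Machine$double.eps), `/`)
    k <- k + config$nonlinearity_scale * z[, 5L] * z[, 9L]
  }
  k
}

#' Generate a synthetic gait cohort
#'
#' Draws `n_subjects * n_trials * length(feet)` samples.  Each subject gets
#' a persistent regional loading shift (shared by both feet); each trial
#' adds independent within-subject variation.  Pressures are truncated at
#' zero; ground-truth stiffness follows the documented linear(-plus-
#' interaction) model and observed stiffness adds Gaussian noise, clipped to
#' the 70--1900 N/m device range with a `clipped` flag.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `gait_cohort` with one row per trial/foot:
#'   `subject_id`, `foot`, `trial`, `region_1` .. `region_10`,
#'   `stiffness_true`, `stiffness` (observed) and `clipped`.  The generating
#'   configuration is attached as attribute `"config"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 7))
#' nrow(cohort)  # 3 subjects x 5 trials x 2 feet = 30
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stopf("'config' must be a cohort_config object")
  }
  ns <- config$n_subjects
  nt <- config$n_trials
  feet <- config$feet
  n <- ns * nt * length(feet)
  with_seed(stage_seed(config$seed, "cohort"), {
    P <- matrix(NA_real_, n, N_REGIONS)
    subject_id <- character(n)
    foot <- character(n)
    trial <- integer(n)
    row <- 0L
    for (s in seq_len(ns)) {
      shift <- stats::rnorm(N_REGIONS, 0, config$subject_sd)
      for (f in feet) {
        for (t in seq_len(nt)) {
          row <- row + 1L
          P[row, ] <- pmax(0, config$region_mean_profile + shift +
                             stats::rnorm(N_REGIONS, 0, config$trial_sd))
          subject_id[row] <- sprintf("S%02d", s)
          foot[row] <- f
          trial[row] <- t
        }
      }
    }
    k_true <- true_stiffness(P, config)
    eff_sd <- if (config$stiffness_pairing == "mean_of_repeats") {
      config$noise_sd / sqrt(config$n_stiffness_repeats)
    } else {
      config$noise_sd
    }
    k_obs <- k_true + stats::rnorm(n, 0, eff_sd)
    clipped <- k_obs < STIFFNESS_RANGE[1] | k_obs > STIFFNESS_RANGE[2]
    k_obs <- pmin(pmax(k_obs, STIFFNESS_RANGE[1]), STIFFNESS_RANGE[2])
    out <- data.frame(subject_id = subject_id, foot = foot, trial = trial,
                      P, stiffness_true = k_true, stiffness = k_obs,
                      clipped = clipped, stringsAsFactors = FALSE)
    names(out)[3L + seq_len(N_REGIONS)] <- paste0("region_", seq_len(N_REGIONS))
    attr(out, "config") <- config
    class(out) <- c("gait_cohort", "data.frame")
    out
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic gait cohort: %d samples (%d subjects x %d trials x %d feet)\n",
              nrow(x), cfg$n_subjects, cfg$n_trials, length(cfg$feet)))
  cat(sprintf("Observed stiffness: %.2f +/- %.2f N/m (%d clipped)\n",
              mean(x$stiffness), stats::sd(x$stiffness), sum(x$clipped)))
  invisible(x)
}

#' Write / read a cohort as CSV with a JSON configuration sidecar
#'
#' The CSV holds one row per trial/foot with the `region_1..region_10`
#' pressure columns and the observed stiffness; the sidecar
#' (`<path>.config.json`) records the full generator configuration and seed
#' so a cohort file is exactly reproducible.
#'
#' @param cohort A `gait_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_cohort`); a `gait_cohort`
#'   (`read_cohort`).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "foot", "trial",
              paste0("region_", seq_len(N_REGIONS)), "stiffness")
  missing <- setdiff(needed, names(out))
  if (length(missing)) stopf("cohort CSV lacks columns: %s",
                             paste(missing, collapse = ", "))
  side <- paste0(path, ".config.json")
  if (file.exists(side)) {
    cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg$feet <- as.character(cfg$feet)
    attr(out, "config") <- structure(cfg, class = "cohort_config")
  }
  class(out) <- c("gait_cohort", "data.frame")
  out
}

#' Generate a stance-phase pressure time series for one sample
#'
#' Builds a per-region time series shaped like a walking stance phase (a
#' smooth double-peaked loading curve with a small seeded frame-to-frame
#' jitter) and rescales each region so its temporal mean reproduces the
#' sample's tabular mean pressure exactly, making the series a faithful raw
#' counterpart of the feature vector.
#'
#' @param pressures Numeric vector of 10 regional mean pressures (N), or a
#'   single-row `gait_cohort` slice.
#' @param fs Sampling frequency (Hz), default 120.
#' @param duration Stance duration (s), default 0.75.
#' @param seed Integer seed for the jitter, or `NULL`.
#' @param jitter_sd Relative SD of the multiplicative frame jitter.
#' @return A [stance_series()] with `round(fs * duration)` frames.
#' @export
generate_stance_series <- function(pressures, fs = 120, duration = 0.75,
                                   seed = NULL, jitter_sd = 0.02) {
  if (is.data.frame(pressures)) {
    if (nrow(pressures) != 1L) stopf("give a single cohort row")
    pressures <- as.numeric(pressures[paste0("region_", seq_len(N_REGIONS))])
  }
  check_number(fs, "fs", lower = 0, strict = TRUE)
  check_number(duration, "duration", lower = 0, strict = TRUE)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  if (length(pressures) != N_REGIONS || any(pressures < 0)) {
    stopf("'pressures' must be 10 nonnegative values")
  }
  n <- max(1L, as.integer(round(fs * duration)))
  u <- (seq_len(n) - 0.5) / n
  # Double-peaked stance template: loading + propulsion peaks, positive floor.
  template <- sin(pi * u)^2 * (1 + 0.25 * sin(2 * pi * u)) + 0.05
  with_seed(seed, {
    frames <- sapply(seq_len(N_REGIONS), function(i) {
      col <- pressures[i] * template
      if (jitter_sd > 0) col <- col * exp(stats::rnorm(n, 0, jitter_sd))
      m <- mean(col)
      if (m > 0) col * (pressures[i] / m) else col
    })
    frames <- matrix(frames, nrow = n)
    stance_series(frames, sampling_rate = fs)
  })
}

#' Generate a damped-oscillation trace for a known stiffness
#'
#' Synthesizes the probe response of a handheld stiffness meter as the
#' closed-form underdamped oscillation of a mass on the tissue spring:
#' displacement \eqn{s(t) = (v_0/\omega_d) e^{-\zeta\omega_0 t}
#' \sin(\omega_d t)} with \eqn{\omega_0 = \sqrt{k/m}}, plus analytic
#' velocity and acceleration, and optional additive measurement noise.
#' With light damping the extracted peak acceleration and first-cycle
#' deformation recover \eqn{k = a_{max} m / \Delta l} to well within 1%.
#'
#' @param stiffness Tissue stiffness k (N/m), > 0.
#' @param probe_mass Probe mass m (kg), > 0; default 0.018.
#' @param damping_ratio Dimensionless damping ratio in (0, 1); default 0.05.
#' @param impact_velocity Initial probe velocity (m/s).
#' @param fs Sampling rate of the trace (Hz); default resolves ~75 samples
#'   per oscillation period.
#' @param n_cycles Number of oscillation periods synthesized.
#' @param noise_sd Additive acceleration noise SD (m/s^2).
#' @param seed Integer seed for the noise, or `NULL`.
#' @return An [oscillation_trace()].
#' @export
#' @examples
#' tr <- generate_oscillation(500, probe_mass = 0.018)
#' compute_stiffness(extract_oscillation_features(tr, probe_mass = 0.018))
generate_oscillation <- function(stiffness, probe_mass = 0.018,
                                 damping_ratio = 0.05,
                                 impact_velocity = 0.05,
                                 fs = NULL, n_cycles = 4,
                                 noise_sd = 0, seed = NULL) {
  check_number(stiffness, "stiffness", lower = 0, strict = TRUE)
  check_number(probe_mass, "probe_mass", lower = 0, strict = TRUE)
  check_number(damping_ratio, "damping_ratio", lower = 0)
  if (damping_ratio >= 1) stopf("'damping_ratio' must be < 1 (underdamped)")
  check_number(impact_velocity, "impact_velocity", lower = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  w0 <- sqrt(stiffness / probe_mass)
  wd <- w0 * sqrt(1 - damping_ratio^2)
  if (is.null(fs)) fs <- 75 * wd / (2 * pi)
  check_number(fs, "fs", lower = 0, strict = TRUE)
  duration <- n_cycles * 2 * pi / wd
  t <- seq(0, duration, by = 1 / fs)
  zw <- damping_ratio * w0
  env <- exp(-zw * t)
  A <- impact_velocity / wd
  s <- A * env * sin(wd * t)
  v <- A * env * (wd * cos(wd * t) - zw * sin(wd * t))
  a <- A * env * ((zw^2 - wd^2) * sin(wd * t) - 2 * zw * wd * cos(wd * t))
  if (noise_sd > 0) {
    a <- with_seed(seed, a + stats::rnorm(length(a), 0, noise_sd))
  }
  oscillation_trace(time = t, displacement = s, velocity = v, acceleration = a)
}
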