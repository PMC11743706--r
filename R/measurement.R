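# Measurement formulas: regional mean pressure over the stance phase and
# probe-oscillation stiffness (a_max * m_probe / delta_l).

#' Stance-phase pressure series
#'
#' Per-region pressure samples recorded over one stance phase.  Exactly ten
#' regions in the order of [plantar_regions()].
#'
#' @param frames Numeric matrix, frames x 10 regions, all values >= 0.
#' @param sampling_rate Sampling frequency (Hz), > 0.
#' @param region_labels Region labels; defaults to [plantar_regions()].
#' @return An object of class `stance_series`.
#' @export
stance_series <- function(frames, sampling_rate = 120,
                          region_labels = plantar_regions()) {
  frames <- as.matrix(frames)
  if (ncol(frames) != N_REGIONS) {
    stopf("'frames' must have exactly %d region columns", N_REGIONS)
  }
  if (nrow(frames) < 1L) stopf("'frames' must contain at least one frame")
  if (anyNA(frames) || any(frames < 0)) {
    stopf("pressures must be nonnegative and non-missing")
  }
  check_number(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  if (length(region_labels) != N_REGIONS) {
    stopf("'region_labels' must have length %d", N_REGIONS)
  }
  colnames(frames) <- region_labels
  structure(list(frames = frames, sampling_rate = sampling_rate,
                 region_labels = region_labels),
            class = "stance_series")
}

#' Mean regional pressure over a stance phase
#'
#' For each region, the arithmetic mean of the pressure samples,
#' \eqn{F_{mean} = \sum_i F_i / n}, over all provided frames.  Windowing to
#' a sub-phase (e.g. heel-strike to toe-off) is the data producer's
#' responsibility.
#'
#' @param series A [stance_series()], or a bare numeric matrix whose columns
#'   are regions (any region count, for small worked examples).
#' @return Named numeric vector of per-region means (N).
#' @export
#' @examples
#' mean_regional_pressure(matrix(c(10, 20, 30), ncol = 1))  # 20
mean_regional_pressure <- function(series) {
  frames <- if (inherits(series, "stance_series")) series$frames
            else as.matrix(series)
  if (nrow(frames) < 1L) stopf("series has zero frames")
  colMeans(frames)
}

#' Probe oscillation measurement
#'
#' The three quantities the stiffness formula consumes: peak acceleration,
#' probe mass and tissue deformation.
#'
#' @param a_max Peak acceleration magnitude (m/s^2), > 0.
#' @param probe_mass Probe mass (kg), > 0.
#' @param delta_l Tissue deformation (m), > 0.
#' @return An object of class `oscillation_measurement`.
#' @export
oscillation_measurement <- function(a_max, probe_mass, delta_l) {
  check_number(a_max, "a_max", lower = 0, strict = TRUE)
  check_number(probe_mass, "probe_mass", lower = 0, strict = TRUE)
  check_number(delta_l, "delta_l", lower = 0, strict = TRUE)
  structure(list(a_max = a_max, probe_mass = probe_mass, delta_l = delta_l),
            class = "oscillation_measurement")
}

#' Probe oscillation trace
#'
#' Displacement, velocity and acceleration of the probe over time.
#'
#' @param time Strictly increasing sample times (s).
#' @param displacement,velocity,acceleration Numeric vectors matching `time`.
#' @return An object of class `oscillation_trace`.
#' @export
oscillation_trace <- function(time, displacement, velocity, acceleration) {
  n <- length(time)
  if (n < 2L) stopf("trace needs at least two samples")
  if (length(displacement) != n || length(velocity) != n ||
      length(acceleration) != n) {
    stopf("trace channels must have equal length")
  }
  if (any(diff(time) <= 0)) stopf("'time' must be strictly increasing")
  structure(list(time = time, displacement = displacement,
                 velocity = velocity, acceleration = acceleration),
            class = "oscillation_trace")
}

#' Extract stiffness features from an oscillation trace
#'
#' Reads the two trace features the stiffness formula needs:
#' `a_max`, the maximum absolute acceleration over the whole trace, and
#' `delta_l`, the deformation, taken as the displacement excursion from the
#' trace start to the first local extremum of |s(t) - s(0)| (the peak of the
#' first compression half-cycle).  This deformation convention is fixed and
#' documented; it is exact for traces started at probe contact.
#'
#' @param trace An [oscillation_trace()].
#' @param probe_mass Probe mass (kg), > 0.
#' @return An [oscillation_measurement()].
#' @export
extract_oscillation_features <- function(trace, probe_mass) {
  if (!inherits(trace, "oscillation_trace")) {
    stopf("'trace' must be an oscillation_trace")
  }
  check_number(probe_mass, "probe_mass", lower = 0, strict = TRUE)
  a_max <- max(abs(trace$acceleration))
  d <- abs(trace$displacement - trace$displacement[1L])
  if (max(d) <= 0 || a_max <= 0) {
    stopf("flat trace: no oscillation to extract features from")
  }
  # First interior local maximum of the excursion; fall back to the global
  # peak for traces shorter than one half-cycle.
  n <- length(d)
  peak <- NULL
  if (n >= 3L) {
    interior <- which(d[2:(n - 1L)] >= d[1:(n - 2L)] &
                      d[2:(n - 1L)] >= d[3:n] &
                      d[2:(n - 1L)] > 0) + 1L
    if (length(interior)) peak <- interior[1L]
  }
  if (is.null(peak)) peak <- which.max(d)
  oscillation_measurement(a_max = a_max, probe_mass = probe_mass,
                          delta_l = d[peak])
}

#' Soft-tissue stiffness from an oscillation measurement
#'
#' Computes \eqn{S = a_{max} \, m_{probe} / \Delta l} in N/m.
#'
#' @param m An [oscillation_measurement()].
#' @return Stiffness (N/m).
#' @export
#' @examples
#' compute_stiffness(oscillation_measurement(10, 0.5, 0.01))  # 500
compute_stiffness <- function(m) {
  if (!inherits(m, "oscillation_measurement")) {
    stopf("'m' must be an oscillation_measurement")
  }
  m$a_max * m$probe_mass / m$delta_l
}

#' Read / write raw measurement CSV files
#'
#' Stance series are stored as frame rows by 10 region columns (header =
#' region labels); oscillation traces as columns `time`, `s`, `v`, `a`.
#'
#' @param path CSV path.
#' @param sampling_rate Sampling rate (Hz) for stance series.
#' @param series,trace Objects to write.
#' @return The parsed object, or `path` invisibly for writers.
#' @export
read_stance_series <- function(path, sampling_rate = 120) {
  df <- utils::read.csv(path, check.names = FALSE)
  stance_series(as.matrix(df), sampling_rate = sampling_rate,
                region_labels = names(df))
}

#' @rdname read_stance_series
#' @export
write_stance_series <- function(series, path) {
  utils::write.csv(as.data.frame(series$frames), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_stance_series
#' @export
read_oscillation_trace <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("time", "s", "v", "a")
  if (!all(needed %in% names(df))) {
    stopf("trace CSV must have columns: %s", paste(needed, collapse = ", "))
  }
  oscillation_trace(df$time, df$s, df$v, df$a)
}

#' @rdname read_stance_series
#' @export
write_oscillation_trace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, s = trace$displacement,
                              v = trace$velocity, a = trace$acceleration),
                   path, row.names = FALSE)
  invisible(path)
}
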