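# Time-of-flight extraction from correlation peaks and conversion to
# Bragg-peak range or detector distance.

#' Reflection template
#'
#' The entrance-window echo of the Bragg-peak wave is a time-reversed and
#' sign-inverted (180 degree phase flip at the pressure-release window) copy
#' of the direct signal. This helper builds the matching template: reversed
#' samples, negated, same time base.
#'
#' @param template A [pressure_trace()].
#' @return A `pressure_trace` matching the reflected arrival.
#' @export
reflect_template <- function(template) {
  pressure_trace(template$t0, template$dt, -rev(template$samples),
                 kind = template$kind, meta = template$meta)
}

#' Time of flight between the direct signal and its window reflection
#'
#' Correlates the measurement with the direct template and with the reflected
#' template ([reflect_template()]); the reflection peak is searched at lags
#' later than the direct peak by at least the template duration (to avoid
#' self-matching), and must exceed `threshold` times the correlation noise
#' floor (standard deviation of the correlation before the direct peak). The
#' time of flight is the lag difference, which approximates twice the proton
#' range over the sound speed. Peaks are refined by three-point parabolic
#' interpolation.
#'
#' @param measurement A [pressure_trace()] containing direct and reflected
#'   arrivals.
#' @param template The direct-signal template.
#' @param threshold Reflection detection threshold in correlation noise-floor
#'   units (default 3).
#' @return List with `tof` (s), `direct_lag`, `reflection_lag` (s, parabolic)
#'   and the two peak correlation values.
#' @export
tof_direct_reflection <- function(measurement, template, threshold = 3) {
  cc_d <- normalized_crosscorr(measurement, template)
  direct_lag <- cc_d$peak_lag_interp
  tdur <- (length(template$samples) - 1L) * template$dt
  cc_r <- normalized_crosscorr(measurement, reflect_template(template))
  search <- cc_r$lags > cc_d$peak_lag + tdur
  if (!any(search)) stop("no lags available after the direct peak")
  # correlation noise floor: the largest excursion at lags well before the
  # direct arrival, where only noise can correlate with the template
  pre <- cc_r$lags < cc_d$peak_lag - tdur
  floor_amp <- if (sum(pre) > 10) max(abs(cc_r$values[pre])) else 0
  vals <- cc_r$values[search]
  ipk <- which.max(vals)
  if (floor_amp > 0 && vals[ipk] < threshold * floor_amp) {
    stop("reflection not found: peak correlation below ", threshold,
         "x the noise floor")
  }
  idx <- which(search)[ipk]
  reflection_lag <- .parabolic_peak(cc_r$lags, cc_r$values, idx)
  list(tof = reflection_lag - direct_lag,
       direct_lag = direct_lag, reflection_lag = reflection_lag,
       direct_peak = cc_d$peak_value, reflection_peak = vals[ipk])
}

#' Range from a direct-reflection time of flight
#'
#' The reflected wave travels from the Bragg peak back to the entrance window
#' and out again, so its delay relative to the direct signal is twice the
#' range over the sound speed: `R = v_s * ToF / 2`.
#'
#' @param tof Time of flight in seconds (non-negative).
#' @param medium A [water_properties()] object, or `NULL` when `sound_speed`
#'   is given directly.
#' @param sound_speed Optional sound speed override in m/s.
#' @param direct_lag,reflection_lag Optional provenance, stored in the result.
#' @return An object of class `range_estimate`: list with `tof` (s), `range`
#'   (mm), `sound_speed_used` (m/s), `method = "direct_reflection"`.
#' @export
range_from_tof <- function(tof, medium = NULL, sound_speed = NULL,
                           direct_lag = NA_real_, reflection_lag = NA_real_) {
  if (tof < 0) stop("negative time of flight")
  vs <- if (!is.null(sound_speed)) sound_speed else {
    stopifnot(inherits(medium, "medium_properties"))
    medium$sound_speed
  }
  structure(list(tof = tof, range = vs * tof / 2 * 1e3,
                 sound_speed_used = vs, method = "direct_reflection",
                 direct_peak_lag = direct_lag,
                 reflection_peak_lag = reflection_lag),
            class = "range_estimate")
}

#' Bragg-peak range from a measurement and a template
#'
#' Convenience wrapper: [tof_direct_reflection()] followed by
#' [range_from_tof()].
#'
#' @inheritParams tof_direct_reflection
#' @inheritParams range_from_tof
#' @return A `range_estimate`.
#' @export
estimate_range <- function(measurement, template, medium = NULL,
                           sound_speed = NULL, threshold = 3) {
  tf <- tof_direct_reflection(measurement, template, threshold = threshold)
  range_from_tof(tf$tof, medium = medium, sound_speed = sound_speed,
                 direct_lag = tf$direct_lag,
                 reflection_lag = tf$reflection_lag)
}

#' Bragg-peak-to-detector distance from a trigger
#'
#' One-way time-of-flight conversion for triggered acquisitions (beam pickup
#' or prompt-gamma trigger marking the emission time): distance = v_s *
#' (arrival - trigger). This is the distance from the Bragg peak to the
#' detector, not the proton range.
#'
#' @param arrival_time Acoustic arrival time in seconds.
#' @param trigger_time Trigger (emission) time in seconds; must precede the
#'   arrival.
#' @param medium A [water_properties()] object, or `NULL` with `sound_speed`.
#' @param sound_speed Optional sound speed in m/s.
#' @return A `range_estimate` with `method = "trigger"`; `range` holds the
#'   distance in mm.
#' @export
distance_from_trigger <- function(arrival_time, trigger_time, medium = NULL,
                                  sound_speed = NULL) {
  if (arrival_time <= trigger_time) stop("arrival must be after the trigger")
  vs <- if (!is.null(sound_speed)) sound_speed else {
    stopifnot(inherits(medium, "medium_properties"))
    medium$sound_speed
  }
  tof <- arrival_time - trigger_time
  structure(list(tof = tof, range = vs * tof * 1e3,
                 sound_speed_used = vs, method = "trigger",
                 direct_peak_lag = NA_real_, reflection_peak_lag = NA_real_),
            class = "range_estimate")
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf("%s: ToF %.4g us -> %.4g mm (v_s = %.1f m/s)\n",
              x$method, x$tof * 1e6, x$range, x$sound_speed_used))
  invisible(x)
}

#' Summary statistics over repeated range estimates
#'
#' @param estimates List of `range_estimate` objects (or a numeric vector of
#'   ranges in mm); at least two.
#' @return List with `n`, `mean` (mm), `sd` (sample, n-1), `sem` (sd/sqrt(n)),
#'   `relative_sd` and `relative_sem` (fractions of the mean).
#' @export
range_statistics <- function(estimates) {
  r <- if (is.numeric(estimates)) estimates
       else vapply(estimates, function(e) e$range, numeric(1))
  if (length(r) < 2L) stop("need at least 2 estimates")
  m <- mean(r); s <- stats::sd(r)
  list(n = length(r), mean = m, sd = s, sem = s / sqrt(length(r)),
       relative_sd = s / m, relative_sem = s / sqrt(length(r)) / m)
}
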