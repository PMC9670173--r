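# Synthetic-measurement generator: composes the direct Bragg-peak signal, its
# entrance-window reflection (time-mirrored, phase-inverted), an optional
# entrance-window signal and seeded noise into scenes with known ground truth,
# so every downstream stage can be tested without experimental data.

#' Seeded noise trace
#'
#' White or band-limited Gaussian noise. The band-limited variant is filtered
#' with a causal first-order Butterworth band-pass and re-scaled to the
#' requested RMS.
#'
#' @param n_samples Number of samples.
#' @param dt Sampling interval in seconds.
#' @param rms Target root-mean-square amplitude (0 gives a zero trace).
#' @param kind `"white"` or `"bandlimited"`.
#' @param band Length-2 band in Hz (required for `"bandlimited"`).
#' @param seed Optional integer seed.
#' @param t0 Start time in seconds.
#' @return A [pressure_trace()] of kind `"measurement"`.
#' @export
make_noise <- function(n_samples, dt, rms, kind = c("white", "bandlimited"),
                       band = NULL, seed = NULL, t0 = 0) {
  kind <- match.arg(kind)
  stopifnot(rms >= 0, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (rms == 0) {
    return(pressure_trace(t0, dt, numeric(n_samples), kind = "measurement"))
  }
  y <- stats::rnorm(n_samples)
  if (kind == "bandlimited") {
    if (is.null(band)) stop("band required for bandlimited noise")
    if (band[2] >= 1 / dt / 2) stop("band outside Nyquist")
    bf <- signal::butter(1, band / (1 / dt / 2), type = "pass")
    y <- as.numeric(signal::filter(bf, y))
  }
  y <- y * rms / sqrt(mean(y^2))
  pressure_trace(t0, dt, y, kind = "measurement",
                 meta = list(noise_kind = kind, rms = rms, seed = seed))
}

#' Synthetic measurement scene
#'
#' Describes a measurement to synthesize: which template plays the direct
#' signal, the axial geometry (detector distance to the Bragg peak and the
#' ground-truth range), which secondary arrivals to include and the noise and
#' averaging model.
#'
#' @param template A [pressure_trace()] holding the direct-signal waveform,
#'   time-referenced so that the waveform start corresponds to emission at the
#'   Bragg peak (its `t0` is added to the geometric arrival delay).
#' @param detector_distance_to_peak Bragg-peak-to-detector distance in mm.
#' @param range Ground-truth proton range in mm.
#' @param include_reflection Include the entrance-window echo (time-reversed,
#'   sign-inverted, scaled by `-reflection_coefficient`).
#' @param reflection_coefficient Pressure reflection coefficient of the
#'   entrance window, in \[-1, 0\] (default -1: pressure-release, full
#'   inversion).
#' @param include_window_signal Include the entrance-window signal, a scaled
#'   copy of the direct waveform arriving from the beam entry point.
#' @param window_amplitude_ratio Amplitude of the window signal relative to
#'   the direct signal (default 0.5).
#' @param noise_rms Per-shot noise RMS in the template's amplitude units.
#' @param n_shots Number of shots averaged (noise power scales as 1/n).
#' @param seed Optional integer seed for the noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(template, detector_distance_to_peak, range,
                       include_reflection = TRUE,
                       reflection_coefficient = -1,
                       include_window_signal = FALSE,
                       window_amplitude_ratio = 0.5,
                       noise_rms = 0, n_shots = 1L, seed = NULL) {
  stopifnot(inherits(template, "pressure_trace"),
            detector_distance_to_peak > 0, range > 0,
            reflection_coefficient <= 0, reflection_coefficient >= -1,
            noise_rms >= 0, n_shots >= 1)
  structure(list(template = template,
                 detector_distance_to_peak = detector_distance_to_peak,
                 range = range,
                 include_reflection = include_reflection,
                 reflection_coefficient = reflection_coefficient,
                 include_window_signal = include_window_signal,
                 window_amplitude_ratio = window_amplitude_ratio,
                 noise_rms = noise_rms, n_shots = as.integer(n_shots),
                 seed = seed),
            class = "scene_spec")
}

#' Synthesize a measurement with ground truth
#'
#' Composes, on a common time axis starting at zero (the beam pulse / trigger
#' time):
#' * the direct signal, waveform start at `d / v_s`,
#' * the window signal (optional), a scaled copy at `(d + R) / v_s`,
#' * the reflection (optional), the time-reversed and sign-inverted waveform
#'   starting at `(d + 2R) / v_s`,
#' * white Gaussian noise of RMS `noise_rms / sqrt(n_shots)` (shot averaging).
#'
#' @param scene A [scene_spec()].
#' @param medium A [water_properties()] object (provides the sound speed).
#' @param pad Extra trace padding after the last arrival in seconds.
#' @return List with `measurement` (a [pressure_trace()]) and `truth` (range,
#'   sound speed and all arrival times).
#' @export
synthesize_measurement <- function(scene, medium, pad = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(medium, "medium_properties"))
  vs <- medium$sound_speed
  w <- scene$template$samples
  dt <- scene$template$dt
  nw <- length(w)
  tdur <- (nw - 1L) * dt
  if (is.null(pad)) pad <- 2 * tdur
  d <- scene$detector_distance_to_peak * 1e-3
  R <- scene$range * 1e-3
  t_direct <- d / vs + scene$template$t0
  t_window <- (d + R) / vs + scene$template$t0
  t_echo <- (d + 2 * R) / vs + scene$template$t0
  if (2 * R / vs < tdur && scene$include_reflection) {
    warning("reflection overlaps the direct signal: range too small for ",
            "the template duration")
  }
  t_end <- t_echo + tdur + pad
  n <- ceiling(t_end / dt) + 1L
  y <- numeric(n)
  # arrivals are quantized to the sample grid; the truth record reports the
  # placed times so estimators can be validated to sub-sample precision
  place <- function(y, start_time, wave) {
    i0 <- round(start_time / dt) + 1L
    idx <- i0:(i0 + length(wave) - 1L)
    ok <- idx >= 1L & idx <= n
    y[idx[ok]] <- y[idx[ok]] + wave[ok]
    y
  }
  placed <- function(start_time) (round(start_time / dt)) * dt
  y <- place(y, t_direct, w)
  if (scene$include_window_signal) {
    y <- place(y, t_window, scene$window_amplitude_ratio * w)
  }
  if (scene$include_reflection) {
    y <- place(y, t_echo, scene$reflection_coefficient * rev(w))
  }
  t_direct <- placed(t_direct)
  t_window <- placed(t_window)
  t_echo <- placed(t_echo)
  if (scene$noise_rms > 0) {
    nz <- make_noise(n, dt, scene$noise_rms / sqrt(scene$n_shots),
                     seed = scene$seed)
    y <- y + nz$samples
  }
  measurement <- pressure_trace(0, dt, y, kind = "measurement",
                                meta = list(scene = scene[setdiff(names(scene),
                                                                  "template")]))
  list(measurement = measurement,
       truth = list(range = scene$range, sound_speed = vs,
                    t_direct = t_direct, t_window = t_window,
                    t_echo = t_echo))
}
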