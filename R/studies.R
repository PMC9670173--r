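# Optimization studies: dose-limited SNR versus pulse duration, beam-current
# scaling at a fixed dose budget, single long pulse versus a chopped-and-
# averaged train, and the ideal duration / central frequency across clinical
# beam energies.
#
# Conventions shared by all sweeps: the raw-signal noise power is constant
# across pulse durations (the detector noise floor does not depend on the
# beam), so it cancels in any argmax over durations; the correlation noise
# power is obtained by correlating each template against one fixed seeded
# noise realization, which makes it proportional to the template energy as in
# a physical matched-filter output. Dose per pulse is proportional to
# duration times current.

.make_pulse <- function(shape, duration, dt, current, rise_time = 0) {
  if (shape == "rectangular") {
    rectangular_pulse(duration, rise_time = rise_time, dt = dt,
                      current = current)
  } else {
    gaussian_pulse(duration, dt = dt, current = current)
  }
}

# log-axis parabolic interpolation of the argmax of v over x (tie: earliest)
.log_argmax <- function(x, v) {
  i <- which.max(v)
  lx <- log(x)
  exp(.parabolic_peak(lx, v, i))
}

# band where v >= fraction * max(v), linear interpolation on the log axis
.plateau_band <- function(x, v, fraction) {
  thr <- fraction * max(v)
  lx <- log(x)
  above <- v >= thr
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  lo <- if (i1 == 1L) x[1] else {
    f <- (thr - v[i1 - 1]) / (v[i1] - v[i1 - 1])
    exp(lx[i1 - 1] + f * (lx[i1] - lx[i1 - 1]))
  }
  hi <- if (i2 == length(x)) x[length(x)] else {
    f <- (v[i2] - thr) / (v[i2] - v[i2 + 1])
    exp(lx[i2] + f * (lx[i2 + 1] - lx[i2]))
  }
  c(lo, hi)
}

#' Dose-limited SNR versus pulse duration
#'
#' For each duration, simulates the detector-filtered template, computes the
#' raw-signal power (maximum moving-average power over the window derived from
#' the template's 20% amplitude thresholds) and the correlation signal power
#' (peak moving-average power of the template autocorrelation over the window
#' between the autocorrelation zero-crossings), divides each SNR by the peak
#' dose of the pulse, and reports both dose-limited SNR curves with their
#' interpolated argmax positions and the band within `fraction` of the
#' maximum.
#'
#' In `mode = "averaged"` the instantaneous current is held fixed for all
#' durations (dose grows linearly with duration). In `mode = "single_shot"`
#' the current is rescaled per duration so each single pulse deposits
#' `dose_limit`, emulating the chopped-versus-single comparison geometry.
#'
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()] (band may be `NULL`).
#' @param durations Pulse durations in seconds (rectangular: FWHM; Gaussian:
#'   FWHM). At least 8 values spanning at least a decade.
#' @param shape `"rectangular"` or `"gaussian"`.
#' @param medium A [water_properties()] object.
#' @param current Instantaneous beam current in amperes (fixed-current mode).
#' @param noise_rms Raw noise RMS in Pa; sets absolute SNR values but cancels
#'   in the argmax.
#' @param dose_limit Dose in Gy met by each single pulse in
#'   `mode = "single_shot"`.
#' @param mode `"averaged"` (fixed current) or `"single_shot"`.
#' @param fraction Plateau threshold as a fraction of the maximum (default
#'   0.9).
#' @param seed Seed for the fixed correlation-noise realization.
#' @param dt Sampling interval; default 1/156 MHz below 30 MeV, 1/15.6 MHz
#'   above.
#' @param grid Optional precomputed `dose_grid`.
#' @param pdelta_trace Optional precomputed delta kernel.
#' @param n_noise Length of the correlation-noise realization in samples.
#' @param ... Passed to [pdelta()].
#' @return An object of class `sweep_result`: list with `durations`,
#'   `snr_d_raw`, `snr_d_corr` (1/Gy), `argmax_raw`, `argmax_corr` (s),
#'   `plateau_raw`, `plateau_corr`, `dose` (Gy per pulse), `templates`
#'   metadata and the sweep parameters.
#' @export
sweep_pulse_duration <- function(beam, detector, durations,
                                 shape = c("rectangular", "gaussian"),
                                 medium = water_properties(20.1),
                                 current = 4.5e-6, noise_rms = 0.01,
                                 dose_limit = 1, mode = c("averaged",
                                                          "single_shot"),
                                 fraction = 0.9, seed = 1L, dt = NULL,
                                 grid = NULL, pdelta_trace = NULL,
                                 n_noise = 2^14, ...) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (length(durations) < 8L) stop("need at least 8 durations")
  if (max(durations) / min(durations) < 10) {
    stop("durations must span at least one decade")
  }
  durations <- sort(durations)
  if (is.null(dt)) dt <- if (beam$energy <= 30) 1 / 156e6 else 1 / 15.6e6
  if (is.null(grid)) grid <- default_dose_grid(beam)
  peak_dose_pp <- max(grid$values)
  if (peak_dose_pp == 0) stop("degenerate dose grid: all zero")
  if (is.null(pdelta_trace)) {
    pdelta_trace <- pdelta(grid, detector, medium,
                           pad = 1.5 * max(durations), ...)
  }
  noise <- make_noise(n_noise, dt, noise_rms, seed = seed)
  n_dur <- length(durations)
  snr_raw <- snr_corr <- dose <- numeric(n_dur)
  for (i in seq_len(n_dur)) {
    tau <- durations[i]
    scale <- 1
    if (mode == "single_shot") {
      # current rescaled so this single pulse meets the dose limit
      dose_ref <- peak_dose_pp * protons_per_pulse(current, tau)
      scale <- dose_limit / dose_ref
    }
    pulse <- .make_pulse(shape, tau, dt, current * scale)
    tmpl <- simulate_template(beam, pulse, detector, medium,
                              pdelta_trace = pdelta_trace)
    tmpl <- resample_trace(tmpl, dt)
    if (all(tmpl$samples == 0)) stop("degenerate (all-zero) template")
    dose[i] <- peak_dose_pp * tmpl$meta$n_protons
    sw <- signal_window_from_template(tmpl)
    p_sig <- max(moving_average_power(tmpl, sw[2] - sw[1])$samples)
    snr_raw[i] <- p_sig / noise_rms^2
    ac <- fft_crosscorr(tmpl$samples, tmpl$samples)
    d_corr <- correlation_window_from_template(tmpl)
    ac_trace <- pressure_trace(0, dt, ac$values, kind = "measurement")
    p_sig_c <- max(moving_average_power(ac_trace, d_corr)$samples)
    ccn <- fft_crosscorr(noise$samples, tmpl$samples)
    p_noise_c <- mean(ccn$values^2)
    snr_corr[i] <- p_sig_c / p_noise_c
  }
  snr_d_raw <- snr_raw / dose
  snr_d_corr <- snr_corr / dose
  structure(list(durations = durations,
                 snr_d_raw = snr_d_raw, snr_d_corr = snr_d_corr,
                 argmax_raw = .log_argmax(durations, snr_d_raw),
                 argmax_corr = .log_argmax(durations, snr_d_corr),
                 plateau_raw = .plateau_band(durations, snr_d_raw, fraction),
                 plateau_corr = .plateau_band(durations, snr_d_corr, fraction),
                 dose = dose, fraction = fraction, shape = shape, mode = mode,
                 beam = beam, detector = detector, current = current,
                 noise_rms = noise_rms, seed = seed, dt = dt),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "pulse-duration sweep (%s, %.4g MeV, %d points %.3g-%.3g s)\n",
    x$shape, x$beam$energy, length(x$durations), min(x$durations),
    max(x$durations)))
  cat(sprintf("  SNR_D,S argmax %.4g s  (%.0f%% band %.3g-%.3g s)\n",
              x$argmax_raw, 100 * x$fraction, x$plateau_raw[1],
              x$plateau_raw[2]))
  cat(sprintf("  SNR_D,C argmax %.4g s  (%.0f%% band %.3g-%.3g s)\n",
              x$argmax_corr, 100 * x$fraction, x$plateau_corr[1],
              x$plateau_corr[2]))
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(duration = x$durations, snr_d_raw = x$snr_d_raw,
             snr_d_corr = x$snr_d_corr, dose = x$dose)
}

#' Beam-current scaling at a fixed dose budget
#'
#' For each current, the number of averaged shots is chosen to meet
#' `dose_limit`; a measurement (template plus averaged noise) is synthesized
#' and its power SNR measured. The signal amplitude is proportional to the
#' current while averaging n shots reduces the noise power by n, so under a
#' fixed total dose the SNR is predicted to scale linearly with the current.
#'
#' @param currents Instantaneous beam currents in amperes (at least 2 for a
#'   ratio).
#' @param dose_limit Total accumulated peak dose in Gy.
#' @param beam,detector,medium Setup objects as in [sweep_pulse_duration()].
#' @param duration Pulse duration in seconds.
#' @param noise_rms Per-shot noise RMS in Pa.
#' @param seed Seed for the noise realizations.
#' @param ... Passed to [pdelta()].
#' @return A data.frame with `current`, `n_averages`, `dose_per_shot`,
#'   `snr` (measured), `snr_predicted` (scaled linearly in current,
#'   anchored at the first row).
#' @export
current_scaling_study <- function(currents, dose_limit, beam, detector,
                                  medium = water_properties(20.1),
                                  duration = 150e-9, noise_rms = 0.01,
                                  seed = 1L, ...) {
  stopifnot(length(currents) >= 1L, dose_limit > 0)
  if (noise_rms <= 0) stop("zero noise: SNR unbounded")
  grid <- default_dose_grid(beam)
  peak_dose_pp <- max(grid$values)
  pd <- pdelta(grid, detector, medium, pad = 1.5 * duration, ...)
  set.seed(seed)
  rows <- lapply(currents, function(I) {
    dose_per_shot <- peak_dose_pp * protons_per_pulse(I, duration)
    n_avg <- floor(dose_limit / dose_per_shot)
    if (n_avg < 1L) {
      stop(sprintf("dose per shot (%.3g Gy) exceeds the dose limit", dose_per_shot))
    }
    pulse <- rectangular_pulse(duration, dt = pd$dt, current = I)
    tmpl <- simulate_template(beam, pulse, detector, medium, pdelta_trace = pd)
    sw <- signal_window_from_template(tmpl)
    # averaged measurement: signal unchanged, noise RMS reduced by sqrt(n)
    pre <- 3L * length(tmpl$samples)
    y <- c(numeric(pre), tmpl$samples)
    y <- y + stats::rnorm(length(y), sd = noise_rms / sqrt(n_avg))
    tr <- pressure_trace(0, pd$dt, y, kind = "measurement")
    rep <- snr(tr, sw[2] - sw[1],
               noise_window = c(0, (pre - 1L) * pd$dt))
    data.frame(current = I, n_averages = n_avg,
               dose_per_shot = dose_per_shot, snr = rep$snr)
  })
  out <- do.call(rbind, rows)
  out$snr_predicted <- out$snr[1] * out$current / out$current[1]
  out
}

#' Single long pulse versus a chopped-and-averaged train
#'
#' Compares, at a fixed total dose and fixed instantaneous current per
#' duration, the dose-limited SNR of one single pulse of duration `tau`
#' against a train of `round(tau / reference_duration)` pulses of the
#' reference duration at the same current, averaged to the same dose.
#' Gaussian pulse shapes are used in the single-pulse branch (the rectangular
#' idealization of infinitely short edges fails for very short pulses);
#' the chopped train uses the reference duration with the same shape.
#'
#' @param durations Single-pulse durations in seconds.
#' @param reference_duration Chopping duration in seconds (the ideal pulse
#'   duration).
#' @param dose_limit Dose in Gy deposited by each single pulse (and by each
#'   chopped train).
#' @param beam,detector,medium Setup objects.
#' @param noise_rms Noise RMS in Pa.
#' @param seed Seed for the correlation noise realization.
#' @param ... Passed to [pdelta()].
#' @return A data.frame with per-duration dose-limited SNRs (raw and
#'   correlation) of the single pulse and of the chopped train (`NA` where the
#'   duration is below the reference).
#' @export
single_vs_chopped <- function(durations, reference_duration, dose_limit,
                              beam, detector,
                              medium = water_properties(20.1),
                              noise_rms = 0.01, seed = 1L, ...) {
  stopifnot(reference_duration <= max(durations))
  grid <- default_dose_grid(beam)
  peak_dose_pp <- max(grid$values)
  dt <- if (beam$energy <= 30) 1 / 156e6 else 1 / 15.6e6
  pd <- pdelta(grid, detector, medium, pad = 1.5 * max(durations), ...)
  noise <- make_noise(2^14, dt, noise_rms, seed = seed)
  I0 <- 1e-6
  eval_powers <- function(tau, current) {
    pulse <- gaussian_pulse(tau, dt = dt, current = current)
    tmpl <- resample_trace(simulate_template(beam, pulse, detector, medium,
                                             pdelta_trace = pd), dt)
    sw <- signal_window_from_template(tmpl)
    p_sig <- max(moving_average_power(tmpl, sw[2] - sw[1])$samples)
    ac <- fft_crosscorr(tmpl$samples, tmpl$samples)
    d_corr <- correlation_window_from_template(tmpl)
    p_sig_c <- max(moving_average_power(
      pressure_trace(0, dt, ac$values, kind = "measurement"), d_corr)$samples)
    ccn <- fft_crosscorr(noise$samples, tmpl$samples)
    list(raw = p_sig / noise_rms^2, corr = p_sig_c / mean(ccn$values^2))
  }
  rows <- lapply(durations, function(tau) {
    # current such that one pulse of duration tau deposits the dose limit
    dose_ref <- peak_dose_pp * protons_per_pulse(I0, tau)
    I_tau <- I0 * dose_limit / dose_ref
    single <- eval_powers(tau, I_tau)
    # idealized dose-matched averaging count (continuous; each reference
    # pulse at current I_tau deposits dose_limit * ref / tau)
    n_chop <- tau / reference_duration
    if (n_chop >= 1) {
      ref <- eval_powers(reference_duration, I_tau)
      chopped_raw <- n_chop * ref$raw
      chopped_corr <- n_chop * ref$corr
    } else {
      chopped_raw <- chopped_corr <- NA_real_
    }
    data.frame(duration = tau, current = I_tau,
               snr_d_single_raw = single$raw / dose_limit,
               snr_d_single_corr = single$corr / dose_limit,
               snr_d_chopped_raw = chopped_raw / dose_limit,
               snr_d_chopped_corr = chopped_corr / dose_limit)
  })
  do.call(rbind, rows)
}

#' Central frequency of a trace
#'
#' Frequency of the maximum of the amplitude spectrum, computed on a
#' zero-padded FFT with three-point parabolic interpolation of the spectral
#' peak. The DC bin is excluded.
#'
#' @param trace A [pressure_trace()].
#' @param pad_factor Zero-padding factor (default 8).
#' @return Frequency in Hz.
#' @export
central_frequency <- function(trace, pad_factor = 8) {
  y <- trace$samples
  if (all(y == 0)) stop("all-zero trace")
  n <- stats::nextn(pad_factor * length(y), 2)
  sp <- abs(stats::fft(c(y, numeric(n - length(y)))))
  half <- sp[2:(n %/% 2)] # exclude DC and the Nyquist fold
  freqs <- (seq_along(half)) / (n * trace$dt)
  i <- which.max(half)
  .parabolic_peak(freqs, half, i)
}

#' Ideal pulse duration versus beam energy
#'
#' Runs [sweep_pulse_duration()] in idealized far-field mode (broadband point
#' sensor on axis at `farfield_factor` times the range) per energy, with a
#' log-spaced Gaussian-FWHM grid scaled to the straggling-broadened Bragg-peak
#' width of each energy, and reports the ideal FWHM maximizing the
#' correlation-based dose-limited SNR, the band reaching `fraction` of its
#' maximum, and the central frequency of the template at the ideal duration.
#'
#' @param energies Beam energies in MeV.
#' @param shape Pulse shape (default `"gaussian"`).
#' @param fraction Plateau threshold (default 0.9).
#' @param n_durations Durations per energy (log-spaced over a fixed window
#'   around the Bragg-width time scale).
#' @param medium A [water_properties()] object.
#' @param lateral Lateral beam profile (default 5 mm Gaussian spot).
#' @param farfield_factor Detector distance in multiples of the range.
#' @param seed Seed for the correlation noise.
#' @param ... Passed to [sweep_pulse_duration()] (e.g. `n_theta`, `n_phi`).
#' @return A data.frame with one row per energy: `energy`, `ideal_fwhm` (s),
#'   `band_lo`, `band_hi` (s), `central_frequency` (Hz), `argmax_raw` (s).
#' @export
ideal_duration_vs_energy <- function(energies, shape = "gaussian",
                                     fraction = 0.9, n_durations = 16L,
                                     medium = water_properties(20.1),
                                     lateral = lateral_gaussian(5),
                                     farfield_factor = 10, seed = 1L, ...) {
  rows <- lapply(energies, function(E) {
    beam <- beam_spec(E, lateral = lateral)
    R <- range_energy(E)
    vs <- medium$sound_speed
    tau0 <- 2.355 * sigma_range(E) * 1e-3 / vs # Bragg FWHM transit time
    durations <- exp(seq(log(tau0 / 8), log(tau0 * 8),
                         length.out = n_durations))
    det <- axial_detector(beam, farfield_factor * R, band = NULL)
    dt <- max(min(durations) / 12, sigma_range(E) * 1e-3 / vs / 12)
    grid <- default_dose_grid(beam)
    pd <- pdelta(grid, det, medium, pad = 1.5 * max(durations), ...)
    sw <- sweep_pulse_duration(beam, det, durations, shape = shape,
                               medium = medium, fraction = fraction,
                               seed = seed, dt = dt, grid = grid,
                               pdelta_trace = pd)
    ideal <- sw$argmax_corr
    pulse <- .make_pulse(shape, ideal, sw$dt, 1e-6)
    tmpl <- simulate_template(beam, pulse, det, medium, pdelta_trace = pd)
    data.frame(energy = E, ideal_fwhm = ideal,
               band_lo = sw$plateau_corr[1], band_hi = sw$plateau_corr[2],
               central_frequency = central_frequency(tmpl),
               argmax_raw = sw$argmax_raw)
  })
  do.call(rbind, rows)
}
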