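# Matched filtering by normalized cross-correlation and SNR quantification
# via moving-average power, for raw and correlated signals.

#' Normalized cross-correlation of a measurement with a template
#'
#' \deqn{CC_{M,T}(\tau) = \frac{\sum_t M(t) T(t+\tau)}
#'   {\sqrt{AC_{M,M}(0)\,AC_{T,T}(0)}}}
#' with global (zero-lag autocorrelation energy) normalization, which bounds
#' the values to \[-1, 1\]. All full-overlap and partial-overlap lags of the
#' zero-padded sequences are returned. The lag axis is anchored in absolute
#' time: a waveform that sits at time `t_s` inside the template and arrives at
#' time `t_a` in the measurement produces a peak at lag `t_a - t_s`.
#'
#' @param measurement,template [pressure_trace()] objects with equal `dt`
#'   (the template is resampled otherwise). The template must not be longer
#'   than the measurement.
#' @return An object of class `correlation_result`: list with `lags` (s),
#'   `values` (in \[-1, 1\]), `peak_lag`, `peak_value` (earliest lag on ties),
#'   `peak_lag_interp` (three-point parabolic sub-sample refinement), `dt` and
#'   `norm` (the normalization energy, for unnormalized powers).
#' @export
normalized_crosscorr <- function(measurement, template) {
  stopifnot(inherits(measurement, "pressure_trace"),
            inherits(template, "pressure_trace"))
  template <- resample_trace(template, measurement$dt)
  m <- measurement$samples; tm <- template$samples
  if (length(tm) > length(m)) stop("template longer than measurement")
  em <- sum(m^2); et <- sum(tm^2)
  if (em == 0 || et == 0) {
    stop("normalization undefined: all-zero measurement or template")
  }
  cc <- fft_crosscorr(m, tm)
  norm <- sqrt(em * et)
  vals <- cc$values / norm
  lags <- measurement$t0 + cc$lag_index * measurement$dt - template$t0
  ipk <- which.max(vals) # which.max returns the earliest maximum
  structure(list(lags = lags, values = vals,
                 peak_lag = lags[ipk], peak_value = vals[ipk],
                 peak_lag_interp = .parabolic_peak(lags, vals, ipk),
                 dt = measurement$dt, norm = norm),
            class = "correlation_result")
}

# Three-point parabolic interpolation of a discrete argmax.
.parabolic_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[i] - x[i - 1])
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation: %d lags, peak %.4f at lag %.4g s\n",
              length(x$values), x$peak_value, x$peak_lag))
  invisible(x)
}

#' Signal window of a template from amplitude thresholds
#'
#' Start of the signal: first crossing of 20% of the maximum amplitude on the
#' rising edge into the global maximum. End of the signal: last crossing of
#' 20% of the minimum amplitude after the global minimum. The template must be
#' bipolar with the compression (positive) peak preceding the rarefaction
#' (negative) trough.
#'
#' @param template A [pressure_trace()].
#' @param threshold Relative amplitude threshold (default 0.2).
#' @return Numeric `c(t_start, t_end)` in seconds.
#' @export
signal_window_from_template <- function(template, threshold = 0.2) {
  y <- template$samples
  tt <- trace_times(template)
  imax <- which.max(y); imin <- which.min(y)
  if (y[imax] <= 0 || y[imin] >= 0 || imin < imax) {
    stop("template must have a positive maximum followed by a negative minimum")
  }
  up <- threshold * y[imax]
  below <- which(y[seq_len(imax)] < up)
  if (!length(below)) {
    t_start <- tt[1]
  } else {
    i0 <- below[length(below)] # last sample below threshold before the max
    frac <- (up - y[i0]) / (y[i0 + 1] - y[i0])
    t_start <- tt[i0] + frac * template$dt
  }
  dn <- threshold * y[imin] # negative level
  after <- seq(imin, length(y))
  deep <- after[y[after] <= dn]
  i1 <- deep[length(deep)] # last sample at or below the threshold
  if (i1 < length(y)) {
    frac <- (y[i1] - dn) / (y[i1] - y[i1 + 1])
    t_end <- tt[i1] + frac * template$dt
  } else {
    t_end <- tt[i1]
  }
  c(t_start, t_end)
}

#' Correlation window from the template autocorrelation
#'
#' Duration between the zero-crossings of the template's autocorrelation
#' immediately left and right of zero lag; the window used for the
#' moving-average power of correlation functions. Lower-frequency templates
#' produce broader correlation peaks and hence longer windows.
#'
#' @param template A [pressure_trace()].
#' @return Window duration in seconds.
#' @export
correlation_window_from_template <- function(template) {
  y <- template$samples
  if (all(y == 0)) stop("all-zero template")
  ac <- fft_crosscorr(y, y)
  v <- ac$values
  i0 <- which(ac$lag_index == 0L)
  right <- which(v[seq(i0, length(v))] <= 0)
  left <- which(rev(v[seq_len(i0)]) <= 0)
  if (!length(right) || !length(left)) {
    # no sign change: fall back to the full lag span
    return((length(v) - 1L) * template$dt)
  }
  # linear interpolation of the crossing positions
  ir <- right[1]; il <- left[1]
  fr <- v[i0 + ir - 2L] / (v[i0 + ir - 2L] - v[i0 + ir - 1L])
  fl <- v[i0 - il + 2L] / (v[i0 - il + 2L] - v[i0 - il + 1L])
  ((ir - 2L + fr) + (il - 2L + fl)) * template$dt
}

#' Moving-average power of a trace
#'
#' \deqn{P(p) = \frac{1}{n_d}\sum_{i=p}^{p+n_d-1} A^2(i)}
#' for every start index with full support, where the window holds
#' `n_d = max(2, round(d / dt))` samples.
#'
#' @param trace A [pressure_trace()].
#' @param duration Window duration `d` in seconds.
#' @return A `pressure_trace` whose samples are the windowed mean power
#'   (units squared), time-stamped at the window start.
#' @export
moving_average_power <- function(trace, duration) {
  n_d <- max(2L, round(duration / trace$dt))
  x2 <- trace$samples^2
  n <- length(x2)
  if (n_d > n) stop("window longer than the trace")
  cs <- cumsum(c(0, x2))
  p <- (cs[(n_d + 1L):(n + 1L)] - cs[seq_len(n - n_d + 1L)]) / n_d
  pressure_trace(trace$t0, trace$dt, p, kind = trace$kind,
                 meta = c(trace$meta, list(power_window = n_d * trace$dt)))
}

#' Signal-to-noise ratio of a trace
#'
#' Average signal power divided by average noise power: the signal power is
#' the maximum of the moving-average power (window `signal_duration`) over the
#' search region, the noise power is the mean power over the noise window,
#' which must precede any possible signal arrival.
#'
#' @param trace A [pressure_trace()].
#' @param signal_duration Signal window duration in seconds (e.g. from
#'   [signal_window_from_template()]).
#' @param noise_window Numeric `c(t_start, t_end)` in seconds.
#' @param arrival_hint Optional `c(t_start, t_end)` restricting the search for
#'   the signal power (used to exclude secondary signals and reflections);
#'   defaults to everything after the noise window.
#' @return An object of class `snr_report`: list with `signal_power`,
#'   `noise_power`, `snr`, `signal_window`, `noise_window`, `n_repeats`.
#' @export
snr <- function(trace, signal_duration, noise_window, arrival_hint = NULL) {
  stopifnot(length(noise_window) == 2L, noise_window[1] < noise_window[2])
  tt <- trace_times(trace)
  nidx <- tt >= noise_window[1] & tt <= noise_window[2]
  if (sum(nidx) < 2L) stop("noise window contains fewer than 2 samples")
  if (diff(noise_window) < 5 * signal_duration) {
    warning("noise window shorter than 5x the signal duration: poor noise estimate")
  }
  noise_power <- mean(trace$samples[nidx]^2)
  if (noise_power == 0) stop("zero noise power: SNR undefined")
  search <- if (is.null(arrival_hint)) c(noise_window[2], Inf) else arrival_hint
  if (search[1] < noise_window[2]) {
    stop("signal search region must start after the noise window")
  }
  pw <- moving_average_power(trace, signal_duration)
  ptt <- trace_times(pw)
  sidx <- ptt >= search[1] & ptt <= search[2]
  if (!any(sidx)) stop("signal search region contains no power samples")
  signal_power <- max(pw$samples[sidx])
  i_rel <- which(sidx)[which.max(pw$samples[sidx])]
  structure(list(signal_power = signal_power, noise_power = noise_power,
                 snr = signal_power / noise_power,
                 signal_window = c(ptt[i_rel],
                                   ptt[i_rel] + pw$meta$power_window),
                 noise_window = noise_window, n_repeats = 1L),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR = %.3g (signal power %.4g, noise power %.4g, n_repeats %d)\n",
              x$snr, x$signal_power, x$noise_power, x$n_repeats))
  invisible(x)
}

#' SNR of a correlation-filtered measurement
#'
#' Correlates the measurement with the template and quantifies the SNR of the
#' correlation function: signal power is the peak moving-average power (window
#' from [correlation_window_from_template()]), noise power is obtained by
#' correlating the template against independent noise-only realizations drawn
#' from `noise_source` and averaging over `n_repeats` repetitions. Correlation
#' sums are used unnormalized so that the noise power is proportional to the
#' template energy, exactly as in the physical matched-filter output; the
#' normalization constant would cancel in any self-consistent ratio.
#'
#' @param measurement A [pressure_trace()].
#' @param template A [pressure_trace()].
#' @param noise_source Function `(n_samples, dt)` returning a noise
#'   [pressure_trace()], e.g. a closure over [make_noise()].
#' @param n_repeats Number of noise realizations to average (default 100).
#' @param seed Optional integer seed making the report reproducible.
#' @return An `snr_report` with `n_repeats` set accordingly.
#' @export
snr_of_correlation <- function(measurement, template, noise_source,
                               n_repeats = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  template <- resample_trace(template, measurement$dt)
  cc <- fft_crosscorr(measurement$samples, template$samples)
  d_corr <- correlation_window_from_template(template)
  cc_trace <- pressure_trace(0, measurement$dt, cc$values, kind = "measurement")
  pw <- moving_average_power(cc_trace, d_corr)
  signal_power <- max(pw$samples)
  noise_powers <- vapply(seq_len(n_repeats), function(i) {
    nz <- noise_source(length(measurement$samples), measurement$dt)
    ccn <- fft_crosscorr(nz$samples, template$samples)
    mean(ccn$values^2)
  }, numeric(1))
  noise_power <- mean(noise_powers)
  if (noise_power == 0) stop("zero correlation noise power: SNR undefined")
  structure(list(signal_power = signal_power, noise_power = noise_power,
                 snr = signal_power / noise_power,
                 signal_window = c(NA_real_, NA_real_),
                 noise_window = c(NA_real_, NA_real_),
                 n_repeats = as.integer(n_repeats)),
            class = "snr_report")
}

#' Dose-limited SNR
#'
#' SNR divided by the deposited (peak) dose; the figure of merit whose maximum
#' over pulse duration defines the ideal trade-off between applied dose and
#' signal quality.
#'
#' @param report An `snr_report` (or a bare SNR value).
#' @param dose Deposited peak dose in Gy, > 0.
#' @return Dose-limited SNR in 1/Gy.
#' @export
snr_d <- function(report, dose) {
  if (!is.numeric(dose) || dose <= 0) stop("dose must be positive")
  s <- if (inherits(report, "snr_report")) report$snr else report
  s / dose
}
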