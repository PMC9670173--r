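# Uniformly sampled time series container used throughout: the delta-excitation
# kernel (Pa s), pressure and templates (Pa), measurements, correlations.

#' Pressure trace container
#'
#' @param t0 Time of the first sample in seconds.
#' @param dt Sampling interval in seconds.
#' @param samples Numeric vector of samples (Pa, or Pa s for a `pdelta` trace).
#' @param kind One of `"pdelta"`, `"pressure"`, `"template"`, `"measurement"`.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(t0, dt, samples,
                           kind = c("pressure", "pdelta", "template",
                                    "measurement"),
                           meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(samples), dt > 0, is.finite(t0))
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(t0 = t0, dt = dt, samples = as.numeric(samples),
                 kind = kind, meta = meta),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("pressure trace [%s]: %d samples, dt %.4g s, t0 %.4g s, peak %.4g\n",
              x$kind, length(x$samples), x$dt, x$t0, max(abs(x$samples))))
  invisible(x)
}

#' @export
as.data.frame.pressure_trace <- function(x, ...) {
  data.frame(time = trace_times(x), amplitude = x$samples)
}

#' Sample times of a trace
#'
#' @param trace A [pressure_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) * trace$dt
}

#' Resample a trace to a new sampling interval
#'
#' Linear interpolation onto a grid with spacing `dt` covering the original
#' time span; samples outside the original span are zero.
#'
#' @param trace A [pressure_trace()].
#' @param dt New sampling interval in seconds.
#' @return A resampled `pressure_trace`.
#' @export
resample_trace <- function(trace, dt) {
  if (abs(dt - trace$dt) < 1e-9 * dt) return(trace)
  tt <- trace_times(trace)
  tg <- seq(trace$t0, tt[length(tt)], by = dt)
  y <- stats::approx(tt, trace$samples, xout = tg, rule = 2)$y
  pressure_trace(trace$t0, dt, y, kind = trace$kind, meta = trace$meta)
}

#' Crop a trace to a time window
#'
#' @param trace A [pressure_trace()].
#' @param from,to Window bounds in seconds (inclusive).
#' @return The cropped `pressure_trace`.
#' @export
crop_trace <- function(trace, from = -Inf, to = Inf) {
  tt <- trace_times(trace)
  keep <- tt >= from & tt <= to
  if (!any(keep)) stop("crop window contains no samples")
  i1 <- which(keep)[1]
  pressure_trace(tt[i1], trace$dt, trace$samples[keep], kind = trace$kind,
                 meta = trace$meta)
}

# Linear convolution via FFT with zero padding. Returns the 'full' convolution
# of length na + nb - 1.
fft_convolve <- function(a, b) {
  na <- length(a); nb <- length(b)
  n <- stats::nextn(na + nb - 1L, 2)
  fa <- stats::fft(c(a, numeric(n - na)))
  fb <- stats::fft(c(b, numeric(n - nb)))
  out <- Re(stats::fft(fa * fb, inverse = TRUE)) / n
  out[seq_len(na + nb - 1L)]
}

# Linear cross-correlation sum c[k] = sum_i a[i] * b[i - k] for
# k = -(nb - 1) .. (na - 1), via FFT. Returns list(lag_index, values).
fft_crosscorr <- function(a, b) {
  na <- length(a); nb <- length(b)
  cc <- fft_convolve(a, rev(b))
  # index j of cc corresponds to k = j - nb
  list(lag_index = seq_len(na + nb - 1L) - nb, values = cc)
}
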