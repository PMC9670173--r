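# Temporal heating functions H_t(t): normalized beam-current pulse shapes and
# their exact time derivatives. H_t is the beam current normalized to unit
# integral, so that convolution with the delta-excitation pressure kernel and
# scaling by the pulse charge yields the physical pressure.

new_heating_profile <- function(t0, dt, samples, shape, duration,
                                rise_time = 0, instantaneous_current = NA_real_) {
  stopifnot(dt > 0, all(is.finite(samples)))
  structure(list(
    t0 = t0, dt = dt, samples = samples, shape = shape,
    duration = duration, rise_time = rise_time,
    instantaneous_current = instantaneous_current
  ), class = "heating_profile")
}

#' @export
print.heating_profile <- function(x, ...) {
  cat(sprintf("heating profile (%s): duration %.4g s, dt %.4g s, %d samples",
              x$shape, x$duration, x$dt, length(x$samples)))
  if (is.finite(x$instantaneous_current)) {
    cat(sprintf(", peak current %.4g A", x$instantaneous_current))
  }
  cat("\n")
  invisible(x)
}

profile_times <- function(profile) profile$t0 + (seq_along(profile$samples) - 1L) * profile$dt

#' Effective pulse length of a heating profile
#'
#' Charge-equivalent duration: the width of the rectangle with the profile's
#' peak height and the same unit integral, `1 / (max(samples))`. For an ideal
#' rectangle this is the duration; for a Gaussian it is `sigma * sqrt(2*pi)`.
#' Used to convert an instantaneous (peak) beam current into protons per pulse.
#'
#' @param profile A [heating_profile][rectangular_pulse].
#' @return Effective duration in seconds.
#' @export
effective_duration <- function(profile) 1 / max(profile$samples)

#' Rectangular (trapezoidal) beam pulse
#'
#' Normalized beam-current profile of a chopped rectangular proton pulse with
#' linear rise and fall edges. `duration` is interpreted as the full width at
#' half maximum, i.e. plateau plus one edge width, which matches how nominal
#' chopper durations relate to measured current profiles (a nominal 200 ns
#' pulse with 15 ns edges has FWHM just below 200 ns). Edges are split
#' symmetrically. The discrete integral is exactly 1.
#'
#' @param duration Nominal pulse duration (FWHM) in seconds.
#' @param rise_time 10--90% rise time in seconds (0 for an ideal rectangle).
#'   The full linear edge lasts `rise_time / 0.8`.
#' @param dt Sampling interval in seconds. Must resolve the edge:
#'   `dt <= rise_time / 3` whenever `rise_time > 0`.
#' @param t0 Time of the leading edge's start, seconds.
#' @param current Instantaneous (plateau) beam current in amperes, carried as
#'   metadata for dose and pressure scaling.
#' @return A `heating_profile` object with unit-integral samples in s^-1.
#' @export
rectangular_pulse <- function(duration, rise_time = 0, dt,
                              t0 = 0, current = NA_real_) {
  stopifnot(duration > 0, rise_time >= 0, dt > 0)
  if (rise_time >= duration) stop("rise_time must be smaller than duration")
  if (rise_time > 0 && dt > rise_time / 3) {
    stop("dt too coarse to resolve the edge: need dt <= rise_time / 3")
  }
  edge <- rise_time / 0.8 # full 0-100% edge from the 10-90% rise time
  plateau <- duration - edge # FWHM = plateau + edge
  if (plateau < 0) stop("duration too short for the requested rise_time")
  total <- plateau + 2 * edge
  n <- max(2L, ceiling(total / dt) + 1L)
  tt <- (seq_len(n) - 1L) * dt
  h <- 1 / duration # height so that integral = h * (plateau + edge) = 1
  y <- numeric(n)
  if (edge > 0) {
    y <- pmin(1, pmax(0, pmin(tt / edge, (total - tt) / edge)))
  } else {
    y <- as.numeric(tt >= 0 & tt < duration)
  }
  y <- y * h
  y <- y / (sum(y) * dt) # exact discrete normalization
  new_heating_profile(t0, dt, y, "rectangular", duration,
                      rise_time, current)
}

#' Gaussian beam pulse
#'
#' Truncated, renormalized Gaussian beam-current profile, as delivered e.g. by
#' a synchrocyclotron after low-pass filtering of its microbunch structure.
#'
#' @param fwhm Full width at half maximum in seconds.
#' @param dt Sampling interval in seconds.
#' @param support Half-support in multiples of sigma (default 5); values below
#'   4 trigger a truncation warning.
#' @param t0 Optional start time; by default the pulse is centered at
#'   `support * sigma` so the profile starts at time 0.
#' @param current Peak beam current in amperes (metadata).
#' @return A `heating_profile` with unit-integral samples.
#' @export
gaussian_pulse <- function(fwhm, dt, support = 5, t0 = 0, current = NA_real_) {
  stopifnot(fwhm > 0, dt > 0)
  if (support < 4) warning("support < 4 sigma truncates the Gaussian noticeably")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- support * sigma
  n <- max(3L, 2L * ceiling(half / dt) + 1L)
  tt <- (seq_len(n) - 1L) * dt
  center <- (n - 1L) / 2 * dt
  y <- exp(-0.5 * ((tt - center) / sigma)^2)
  y <- y / (sum(y) * dt)
  prof <- new_heating_profile(t0, dt, y, "gaussian", fwhm, 0, current)
  prof$sigma <- sigma
  prof$center <- t0 + center
  prof
}

#' Load a measured beam-current profile
#'
#' Reads a two-column delimited text file (time in seconds, current in
#' amperes), resamples it to `dt` by linear interpolation, subtracts the
#' baseline (median of the first 5% of samples), clips negative excursions to
#' zero and normalizes to unit integral.
#'
#' @param path Path to the delimited file. Separator is auto-detected among
#'   comma, tab and whitespace; lines starting with `#` are ignored.
#' @param dt Target sampling interval in seconds.
#' @param current Peak beam current in amperes (metadata); if `NA`, taken as
#'   the maximum of the baseline-subtracted current column.
#' @return A `heating_profile` with shape tag `"measured"`.
#' @export
load_measured_profile <- function(path, dt, current = NA_real_) {
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", fill = FALSE)
  if (ncol(raw) == 1L) { # try comma separation
    raw <- utils::read.table(path, header = FALSE, comment.char = "#", sep = ",")
  }
  if (ncol(raw) < 2L) stop("expected two columns: time [s], current [A]")
  tt <- raw[[1]]; ii <- raw[[2]]
  if (any(diff(tt) <= 0)) stop("time column must be strictly increasing")
  nb <- max(1L, floor(0.05 * length(ii)))
  ii <- ii - stats::median(ii[seq_len(nb)])
  ii <- pmax(ii, 0)
  if (all(ii == 0)) stop("profile is all zero after baseline subtraction")
  tg <- seq(tt[1], tt[length(tt)], by = dt)
  y <- stats::approx(tt, ii, xout = tg, rule = 2)$y
  if (is.na(current)) current <- max(y)
  # FWHM of the resampled profile as the nominal duration
  half <- max(y) / 2
  above <- which(y >= half)
  duration <- (above[length(above)] - above[1]) * dt
  y <- y / (sum(y) * dt)
  new_heating_profile(tg[1], dt, y, "measured", duration, 0, current)
}

#' Time derivative of a heating profile
#'
#' The pressure at the detector is the convolution of dH_t/dt with the
#' delta-excitation kernel. For rectangular pulses the derivative is a pair of
#' opposite-sign boxcars over the edges (delta-like impulses for zero rise
#' time); for Gaussian pulses it is the analytic derivative; measured shapes
#' are differentiated by central finite differences. The discrete integral of
#' the returned trace is forced to zero to machine precision.
#'
#' @param profile A `heating_profile`.
#' @return A list with `t0`, `dt` and `samples` (units s^-2).
#' @export
heating_derivative <- function(profile) {
  stopifnot(inherits(profile, "heating_profile"))
  dt <- profile$dt
  tt <- profile_times(profile) - profile$t0
  n <- length(profile$samples)
  if (profile$shape == "rectangular") {
    edge <- profile$rise_time / 0.8
    h <- 1 / profile$duration
    if (edge == 0) {
      ioff <- round(profile$duration / dt)
      d <- numeric(max(n, ioff + 1L))
      d[1L] <- h / dt
      d[ioff + 1L] <- d[ioff + 1L] - h / dt
    } else {
      total <- (profile$duration - edge) + 2 * edge
      slope <- h / edge
      d <- numeric(n)
      d[tt >= 0 & tt < edge] <- slope
      d[tt >= total - edge & tt < total] <- -slope
      d <- d - sum(d) / n
    }
  } else if (profile$shape == "gaussian") {
    center <- (n - 1L) / 2 * dt
    s <- profile$sigma
    g <- exp(-0.5 * ((tt - center) / s)^2)
    g <- g / (sum(g) * dt)
    d <- -(tt - center) / s^2 * g
    d <- d - sum(d) / n
  } else {
    d <- numeric(n)
    d[2:(n - 1L)] <- (profile$samples[3:n] - profile$samples[1:(n - 2L)]) / (2 * dt)
    d[1L] <- (profile$samples[2L] - profile$samples[1L]) / dt
    d[n] <- (profile$samples[n] - profile$samples[n - 1L]) / dt
    d <- d - sum(d) / n
  }
  list(t0 = profile$t0, dt = dt, samples = d)
}

#' Measured full width at half maximum of a sampled profile
#'
#' @param profile A `heating_profile`.
#' @return FWHM in seconds, from linear interpolation of the half-maximum
#'   crossings.
#' @export
profile_fwhm <- function(profile) {
  y <- profile$samples
  half <- max(y) / 2
  i1 <- which(y >= half)[1]
  i2 <- rev(which(y >= half))[1]
  # linear interpolation at both edges
  f1 <- if (i1 > 1) (y[i1] - half) / (y[i1] - y[i1 - 1]) else 0
  f2 <- if (i2 < length(y)) (y[i2] - half) / (y[i2] - y[i2 + 1]) else 0
  ((i2 - i1) + f1 + f2) * profile$dt
}
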