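# Acoustic forward model: delta-excitation pressure kernel from a dose grid
# (solid-angle integral of the initial pressure over spheres centered on the
# detector), full pressure trace (convolution with the temporal heating
# derivative), and a causal band-pass surrogate for the detector response.

#' Detector specification
#'
#' @param position Numeric length-3 position in grid coordinates (mm).
#' @param band Optional length-2 pass band `c(f_lo, f_hi)` in Hz approximating
#'   the transducer's -6 dB bandwidth; `NULL` for an ideal broadband point
#'   sensor.
#' @param filter_order Butterworth order per band edge (default 1).
#' @param label Free-text label.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(position, band = NULL, filter_order = 1L,
                          label = "") {
  stopifnot(length(position) == 3L, all(is.finite(position)))
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2])
  }
  structure(list(position = as.numeric(position), band = band,
                 filter_order = as.integer(filter_order), label = label),
            class = "detector_spec")
}

#' Axial detector distal to the Bragg peak
#'
#' Convenience constructor placing the detector on the beam axis at
#' `distance` mm beyond the Bragg peak of `beam`.
#'
#' @param beam A [beam_spec()].
#' @param distance Bragg-peak-to-detector distance in mm.
#' @param ... Passed to [detector_spec()].
#' @return A `detector_spec`.
#' @export
axial_detector <- function(beam, distance, ...) {
  R <- range_energy(beam$energy, beam$range_shift)
  detector_spec(c(0, 0, R + distance), ...)
}

#' Olympus V382-SU immersion transducer surrogate
#'
#' First-order Butterworth band-pass over the transducer's -6 dB bandwidth,
#' 2.2 to 4.7 MHz (central frequency 3.5 MHz, 72% fractional bandwidth).
#' @return Length-2 band in Hz.
#' @export
olympus_band <- function() c(2.2e6, 4.7e6)

#' Hydrophone surrogate band
#'
#' Flat-response region of the low-frequency hydrophone used at clinical
#' energies, 10 to 250 kHz.
#' @return Length-2 band in Hz.
#' @export
hydrophone_band <- function() c(10e3, 250e3)

# Bounding description of the grid as seen from a detector position: distance
# range to the voxel-center bounding box and the enclosing angular cap about
# the axis towards the box center.
.grid_cap <- function(grid, det) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  rel <- sweep(corners, 2, det)
  dists <- sqrt(rowSums(rel^2))
  center <- (lo + hi) / 2
  axis <- center - det
  axis <- axis / sqrt(sum(axis^2))
  cosang <- (rel %*% axis) / dists
  inside <- all(det >= lo & det <= hi)
  # nearest distance from point to box
  dmin <- if (inside) 0 else
    sqrt(sum(pmax(lo - det, 0, det - hi)^2))
  cos_theta_max <- if (inside) -1 else max(-1, min(cosang) - 0.02 * (1 - min(cosang)) - 1e-9)
  list(axis = axis, cos_theta_max = cos_theta_max,
       dmin = dmin, dmax = max(dists))
}

#' Delta-excitation pressure kernel at a detector
#'
#' Computes the pressure kernel for an instantaneous (delta) beam pulse,
#' \deqn{P_\delta(t) = \frac{t}{4\pi} \oint \Gamma \rho D\,d\Omega,}
#' the solid-angle integral of the initial pressure (Grueneisen parameter
#' times dose times density) over the sphere of radius `v_s * t` centered on
#' the detector. The integral is evaluated by a midpoint product rule over the
#' angular cap enclosing the dose grid, with trilinear interpolation of the
#' dose; dose is zero outside the grid bounding box. With a per-proton dose
#' grid the kernel is in Pa s per proton.
#'
#' @param grid A `dose_grid` (values in Gy per proton).
#' @param detector A [detector_spec()]; only the position is used here.
#' @param medium A [water_properties()] object.
#' @param time_grid Optional vector of sample times in seconds (uniform). By
#'   default a grid spanning the sphere radii that intersect the dose region,
#'   with `dt` resolving half a voxel.
#' @param dt Sampling interval used when `time_grid` is `NULL`.
#' @param n_theta,n_phi Angular quadrature nodes over the cap (polar, azimuth).
#' @param pad Extra time padding in seconds appended after the farthest voxel.
#' @return A [pressure_trace()] of kind `"pdelta"` (units Pa s per proton).
#' @export
pdelta <- function(grid, detector, medium, time_grid = NULL, dt = NULL,
                   n_theta = 128L, n_phi = 256L, pad = 0) {
  stopifnot(inherits(grid, "dose_grid"), inherits(detector, "detector_spec"),
            inherits(medium, "medium_properties"))
  vs <- medium$sound_speed # m/s
  det <- detector$position # mm
  cap <- .grid_cap(grid, det)
  if (cap$dmin == 0) {
    local_dose <- .trilinear_sample(grid$values, grid$shape, grid$origin,
                                    grid$spacing, matrix(det, nrow = 1))
    if (local_dose > 0) warning("detector inside a dosed voxel: near-field result")
  }
  if (is.null(time_grid)) {
    if (is.null(dt)) dt <- min(grid$spacing) * 1e-3 / vs / 2
    t_lo <- max(0, cap$dmin * 1e-3 / vs - 2 * dt)
    t_hi <- cap$dmax * 1e-3 / vs + 2 * dt + pad
    time_grid <- seq(t_lo, t_hi, by = dt)
  } else {
    if (length(time_grid) < 2L) stop("time_grid needs at least 2 samples")
    dts <- diff(time_grid)
    if (max(abs(dts - dts[1])) > 1e-9 * dts[1]) {
      stop("time_grid must be uniformly sampled")
    }
    dt <- dts[1]
  }
  radii_mm <- vs * time_grid * 1e3
  S <- .shell_integral(grid$values, grid$shape, grid$origin, grid$spacing,
                       det, radii_mm, cap$axis, cap$cos_theta_max,
                       as.integer(n_theta), as.integer(n_phi))
  samples <- time_grid * medium$gruneisen * medium$density * S / (4 * pi)
  if (all(samples == 0)) {
    warning("pdelta is identically zero: time grid does not reach the dose region")
  }
  if (max(time_grid) < cap$dmax * 1e-3 / vs) {
    warning("time grid shorter than the farthest voxel arrival")
  }
  pressure_trace(time_grid[1], dt, samples, kind = "pdelta",
                 meta = list(detector = detector, n_theta = n_theta,
                             n_phi = n_phi, per_proton = TRUE,
                             sound_speed = vs))
}

#' Pressure trace from a heating profile and a delta kernel
#'
#' Convolves the time derivative of the temporal heating function with the
#' delta-excitation kernel (discrete convolution carries the factor `dt`) and
#' scales by the number of protons in the pulse,
#' `instantaneous_current * effective_duration / e`. If the profile carries no
#' current, the per-proton pressure is returned.
#'
#' @param pdelta_trace A `pdelta` [pressure_trace()] (per proton).
#' @param profile A [heating_profile][rectangular_pulse].
#' @return A `pressure_trace` of kind `"pressure"` in Pa.
#' @export
pressure <- function(pdelta_trace, profile) {
  stopifnot(inherits(pdelta_trace, "pressure_trace"),
            pdelta_trace$kind == "pdelta",
            inherits(profile, "heating_profile"))
  dt_fine <- min(pdelta_trace$dt, profile$dt)
  pd <- resample_trace(pdelta_trace, dt_fine)
  if (abs(profile$dt - dt_fine) >= 1e-9 * dt_fine) {
    tt <- profile_times(profile)
    tg <- seq(profile$t0, tt[length(tt)], by = dt_fine)
    y <- stats::approx(tt, profile$samples, xout = tg, rule = 2)$y
    y <- y / (sum(y) * dt_fine)
    profile <- new_heating_profile(profile$t0, dt_fine, y, profile$shape,
                                   profile$duration, profile$rise_time,
                                   profile$instantaneous_current)
    if (profile$shape == "gaussian") {
      profile$sigma <- profile$duration / (2 * sqrt(2 * log(2)))
    }
  }
  dh <- heating_derivative(profile)
  n_protons <- if (is.finite(profile$instantaneous_current)) {
    profile$instantaneous_current * effective_duration(profile) /
      ELEMENTARY_CHARGE
  } else 1
  samples <- fft_convolve(pd$samples, dh$samples) * dt_fine * n_protons
  pressure_trace(pd$t0 + dh$t0, dt_fine, samples, kind = "pressure",
                 meta = c(pd$meta, list(pulse_shape = profile$shape,
                                        pulse_duration = profile$duration,
                                        current = profile$instantaneous_current,
                                        n_protons = n_protons)))
}

#' Apply the detector band-pass surrogate
#'
#' Causal Butterworth band-pass (bilinear transform, applied as a one-pass LTI
#' filter) standing in for the transducer transfer function; with `band =
#' NULL` the trace is returned unchanged. The physical transducer is causal,
#' so no zero-phase filtering is used and the output shows the corresponding
#' phase distortion.
#'
#' @param trace A [pressure_trace()].
#' @param detector A [detector_spec()].
#' @return The filtered `pressure_trace` (kind `"template"` if the input was a
#'   pressure trace).
#' @export
apply_detector <- function(trace, detector) {
  stopifnot(inherits(trace, "pressure_trace"),
            inherits(detector, "detector_spec"))
  if (is.null(detector$band)) return(trace)
  fs <- 1 / trace$dt
  if (detector$band[2] >= fs / 2) {
    stop("detector band upper edge at or above Nyquist frequency")
  }
  bf <- signal::butter(detector$filter_order, detector$band / (fs / 2),
                       type = "pass")
  y <- as.numeric(signal::filter(bf, trace$samples))
  pressure_trace(trace$t0, trace$dt, y, kind = trace$kind,
                 meta = c(trace$meta, list(band = detector$band,
                                           filter_order = detector$filter_order)))
}

#' Simulate a template: dose, propagation, detector
#'
#' Full three-stage template pipeline: per-proton dose grid from the analytic
#' Bragg-curve model, delta-excitation kernel at the detector, convolution
#' with the heating derivative scaled to the pulse charge, and the detector
#' band-pass surrogate. Metadata records all inputs.
#'
#' @param beam A [beam_spec()].
#' @param pulse A [heating_profile][rectangular_pulse].
#' @param detector A [detector_spec()].
#' @param medium A [water_properties()] object.
#' @param grid Optional `dose_grid`; defaults to [default_dose_grid()].
#' @param pdelta_trace Optional precomputed `pdelta` kernel (reused across
#'   pulse durations in sweeps).
#' @param ... Passed to [pdelta()] (`n_theta`, `n_phi`, `dt`, ...).
#' @return A [pressure_trace()] of kind `"template"`.
#' @export
simulate_template <- function(beam, pulse, detector, medium, grid = NULL,
                              pdelta_trace = NULL, ...) {
  if (is.null(pdelta_trace)) {
    if (is.null(grid)) grid <- default_dose_grid(beam)
    pdelta_trace <- pdelta(grid, detector, medium, ...)
  }
  p <- pressure(pdelta_trace, pulse)
  out <- apply_detector(p, detector)
  out$kind <- "template"
  out$meta$beam <- beam
  out$meta$detector <- detector
  out$meta$temperature <- medium$temperature
  out
}
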