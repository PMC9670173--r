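# Shared fixtures, memoized per test run: the acoustic forward model is the
# expensive stage, so the 20 MeV and 220 MeV kernels and sweeps are built once
# and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_medium <- function() {
  fixture("medium", function() {
    water_properties(20.1, overrides = list(sound_speed = 1482))
  })
}

fix_beam20 <- function() {
  fixture("beam20", function() beam_spec(20, range_shift = tandem_window_shift()))
}

fix_grid20 <- function() {
  fixture("grid20", function() {
    suppressWarnings(default_dose_grid(fix_beam20()))
  })
}

# delta kernel at the Olympus position, padded for pulses up to 1 us
fix_pdelta20 <- function() {
  fixture("pdelta20", function() {
    det <- axial_detector(fix_beam20(), 25.4)
    pdelta(fix_grid20(), det, fix_medium(), pad = 1.5e-6)
  })
}

# 130 ns rectangular-pulse template with the Olympus band (the paper's
# range-verification configuration)
fix_template20 <- function() {
  fixture("template20", function() {
    det <- axial_detector(fix_beam20(), 25.4, band = olympus_band())
    pulse <- rectangular_pulse(130e-9, dt = 1 / 156e6, current = 4.5e-6)
    tmpl <- simulate_template(fix_beam20(), pulse, det, fix_medium(),
                              pdelta_trace = fix_pdelta20())
    resample_trace(tmpl, 1 / 156e6)
  })
}

fix_sweep20 <- function() {
  fixture("sweep20", function() {
    det <- axial_detector(fix_beam20(), 25.4, band = olympus_band())
    durations <- exp(seq(log(50e-9), log(1e-6), length.out = 24))
    sweep_pulse_duration(fix_beam20(), det, durations,
                         grid = fix_grid20(), medium = fix_medium(),
                         seed = 1L)
  })
}

fix_beam220 <- function() {
  fixture("beam220", function() beam_spec(220, lateral = lateral_gaussian(5)))
}

fix_sweep220 <- function(shape) {
  fixture(paste0("sweep220_", shape), function() {
    beam <- fix_beam220()
    det <- axial_detector(beam, 75, band = hydrophone_band())
    durations <- exp(seq(log(1e-6), log(20e-6), length.out = 24))
    sweep_pulse_duration(beam, det, durations, shape = shape,
                         medium = fix_medium(), current = 0.43e-6, seed = 1L)
  })
}

# brute-force O(N^2) cross-correlation oracle, independent of the FFT path
brute_crosscorr <- function(m, t) {
  nm <- length(m); nt <- length(t)
  lags <- seq(-(nt - 1L), nm - 1L)
  vals <- vapply(lags, function(k) {
    s <- 0
    for (i in seq_len(nm)) {
      j <- i - k
      if (j >= 1L && j <= nt) s <- s + m[i] * t[j]
    }
    s
  }, numeric(1))
  list(lags = lags, values = vals / sqrt(sum(m^2) * sum(t^2)))
}

# simple synthetic band-limited burst template for detection tests: a few
# cycles of a sine under a raised-cosine envelope, bipolar (+ then -)
burst_template <- function(n_cycles = 2, freq = 1e6, dt = 1 / 50e6,
                           amplitude = 1, t0 = 0) {
  dur <- n_cycles / freq
  tt <- seq(0, dur, by = dt)
  y <- amplitude * sin(2 * pi * freq * tt) * sin(pi * tt / dur)^2
  pressure_trace(t0, dt, y, kind = "template")
}
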