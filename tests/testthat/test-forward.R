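# The quadrature oracle: an isotropic Gaussian ball has a closed-form shell
# average around any external point; the angular quadrature with trilinear
# interpolation must reproduce it.

gaussian_ball_grid <- function(s = 1.5, center = c(0, 0, 30), n = 41,
                               spacing = 0.25) {
  half <- (n - 1) / 2 * spacing
  orig <- center - half
  ax <- lapply(1:3, function(k) orig[k] + (seq_len(n) - 1) * spacing)
  vals <- array(0, c(n, n, n))
  gx <- exp(-(ax[[1]] - center[1])^2 / (2 * s^2))
  gy <- exp(-(ax[[2]] - center[2])^2 / (2 * s^2))
  gz <- exp(-(ax[[3]] - center[3])^2 / (2 * s^2))
  for (k in seq_len(n)) vals[, , k] <- outer(gx, gy) * gz[k]
  structure(list(origin = orig, spacing = rep(spacing, 3), shape = rep(n, 3L),
                 values = vals, beam = NULL, depth_dose = NULL),
            class = "dose_grid")
}

test_that("shell quadrature matches the closed-form Gaussian-ball average", {
  s <- 1.5; L <- 30
  grid <- gaussian_ball_grid(s = s, center = c(0, 0, L))
  det <- detector_spec(c(0, 0, 0))
  med <- water_properties(20, overrides = list(sound_speed = 1482))
  tg <- seq(26e-3, 34e-3, by = 2e-5) / 1482
  pd <- suppressWarnings(pdelta(grid, det, med, time_grid = tg))
  Rp <- 1482e3 * tg # mm
  shell_avg <- pd$samples / (tg * med$gruneisen * med$density)
  closed <- exp(-(Rp^2 + L^2) / (2 * s^2)) * (s^2 / (Rp * L)) *
    sinh(Rp * L / s^2)
  l2 <- sqrt(sum((shell_avg - closed)^2) / sum(closed^2))
  expect_lt(l2, 0.01)
})

test_that("pdelta is linear, zero for zero dose, and arrives on time", {
  grid <- fix_grid20()
  det <- axial_detector(fix_beam20(), 25.4)
  med <- fix_medium()
  pd <- fix_pdelta20()
  # linearity in the dose
  g2 <- grid; g2$values <- grid$values * 3
  pd3 <- suppressWarnings(pdelta(g2, det, med,
                                 time_grid = trace_times(pd)[1:200]))
  expect_lt(max(abs(pd3$samples - 3 * pd$samples[1:200])) / max(pd$samples),
            1e-10)
  # additivity over disjoint sub-volumes (split at the depth midpoint)
  ksplit <- round(grid$shape[3] / 2)
  ga <- grid; ga$values[, , (ksplit + 1):grid$shape[3]] <- 0
  gb <- grid; gb$values[, , 1:ksplit] <- 0
  tg <- trace_times(pd)[seq(1, length(pd$samples), by = 5)]
  pa <- suppressWarnings(pdelta(ga, det, med, time_grid = tg))
  pb <- suppressWarnings(pdelta(gb, det, med, time_grid = tg))
  pab <- suppressWarnings(pdelta(grid, det, med, time_grid = tg))
  expect_lt(max(abs(pa$samples + pb$samples - pab$samples)) / max(pab$samples),
            1e-10)
  # zero dose: identically zero with a warning
  gz <- grid; gz$values[] <- 0
  ws <- testthat::capture_warnings(pz <- pdelta(gz, det, med, time_grid = tg))
  expect_match(ws, "identically zero", all = FALSE)
  expect_true(all(pz$samples == 0))
  # leading edge near the arrival from the closest substantially dosed voxel
  thr <- 1e-3
  dosed <- which(grid$values > thr * max(grid$values), arr.ind = TRUE)
  pos <- t(t(dosed - 1) * grid$spacing + grid$origin)
  dmin <- sqrt(min(colSums((t(pos) - det$position)^2)))
  t_first <- trace_times(pd)[which(pd$samples > thr * max(pd$samples))[1]]
  expect_lt(abs(t_first - dmin * 1e-3 / med$sound_speed), 5 * pd$dt)
})

test_that("far-field amplitude falls off as 1/R", {
  med <- fix_medium()
  pd1 <- fix_pdelta20()
  det2 <- axial_detector(fix_beam20(), 50.8)
  pd2 <- pdelta(fix_grid20(), det2, med)
  expect_equal(max(pd1$samples) / max(pd2$samples), 2, tolerance = 0.05)
})

test_that("pressure composes the heating derivative with the kernel", {
  pd <- fix_pdelta20()
  dt <- 1 / 156e6
  # near-delta heating: pressure approximates the kernel derivative
  pdr <- resample_trace(pd, dt)
  p_delta <- pressure(pd, rectangular_pulse(2 * dt, dt = dt))
  dnum <- diff(pdr$samples) / dt
  expect_lt(abs(max(p_delta$samples) / max(dnum) - 1), 0.15)
  # rectangular heating: compression plus shifted negative kernel copy
  tau <- 500e-9
  I <- 320e-9
  p <- pressure(pd, rectangular_pulse(tau, dt = dt, current = I))
  rate <- I / 1.602176634e-19 # protons per second
  pd_t <- stats::approx(trace_times(pdr), pdr$samples,
                        xout = trace_times(p), rule = 2)$y
  pd_shift <- stats::approx(trace_times(pdr), pdr$samples,
                            xout = trace_times(p) - tau, rule = 2)$y
  expected <- rate * (pd_t - pd_shift)
  mask <- abs(expected) > 0.05 * max(abs(expected))
  expect_lt(max(abs(p$samples[mask] - expected[mask])) / max(abs(expected)),
            0.05)
  # amplitude saturates: 500 ns and 1 us peaks agree within 2%
  p1 <- pressure(pd, rectangular_pulse(1e-6, dt = dt, current = I))
  expect_equal(max(p$samples), max(p1$samples), tolerance = 0.02)
  # and both exceed the 50 ns amplitude markedly
  p50 <- pressure(pd, rectangular_pulse(50e-9, dt = dt, current = I))
  expect_gt(max(p$samples) / max(p50$samples), 1.4)
  # zero current gives a zero trace
  p0 <- pressure(pd, rectangular_pulse(tau, dt = dt, current = 0))
  expect_true(all(p0$samples == 0))
})

test_that("detector surrogate is a causal band-pass with the expected response", {
  det <- detector_spec(c(0, 0, 0), band = c(2.2e6, 4.7e6))
  dt <- 1 / 156e6
  tt <- seq(0, 2e-5, by = dt)
  # band = NULL is the identity
  tr <- pressure_trace(0, dt, sin(2 * pi * 3.2e6 * tt) + 0.5)
  expect_identical(apply_detector(tr, detector_spec(c(0, 0, 0))), tr)
  # DC is removed
  dc <- apply_detector(pressure_trace(0, dt, rep(1, 4000)), det)
  expect_lt(abs(mean(dc$samples[2000:4000])), 1e-6)
  # mid-band passes within 3 dB; deep out-of-band tones attenuated >= 15 dB
  gain <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- apply_detector(pressure_trace(0, dt, x), det)
    max(abs(y$samples[round(length(tt) / 2):length(tt)]))
  }
  f_mid <- sqrt(2.2e6 * 4.7e6)
  expect_gt(gain(f_mid), 10^(-3 / 20))
  expect_lt(gain(2.2e5), 10^(-15 / 20))
  # upper edge above Nyquist is rejected
  expect_error(apply_detector(tr, detector_spec(c(0, 0, 0),
                                                band = c(1e6, 100e6))),
               "Nyquist")
})

test_that("templates respond to the detector band and scale with current", {
  tmpl_band <- fix_template20()
  med <- fix_medium()
  det_open <- axial_detector(fix_beam20(), 25.4)
  pulse <- rectangular_pulse(130e-9, dt = 1 / 156e6, current = 4.5e-6)
  tmpl_open <- resample_trace(
    simulate_template(fix_beam20(), pulse, det_open, med,
                      pdelta_trace = fix_pdelta20()), 1 / 156e6)
  n <- min(length(tmpl_band$samples), length(tmpl_open$samples))
  r <- stats::cor(tmpl_band$samples[seq_len(n)], tmpl_open$samples[seq_len(n)])
  expect_lt(abs(r), 0.99)
})
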