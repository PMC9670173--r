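test_that("pulse-duration sweeps validate their inputs and are reproducible", {
  beam <- fix_beam20()
  det <- axial_detector(beam, 25.4, band = olympus_band())
  expect_error(sweep_pulse_duration(beam, det, durations = c(1e-7, 2e-7)),
               "at least 8")
  expect_error(sweep_pulse_duration(beam, det,
                                    durations = seq(1e-7, 5e-7,
                                                    length.out = 10)),
               "decade")
  sw <- fix_sweep20()
  expect_true(all(sw$snr_d_raw >= 0) && all(sw$snr_d_corr >= 0))
  # the argmax lies inside the 90% plateau band
  expect_true(sw$argmax_raw >= sw$plateau_raw[1] &&
                sw$argmax_raw <= sw$plateau_raw[2])
  expect_true(sw$argmax_corr >= sw$plateau_corr[1] &&
                sw$argmax_corr <= sw$plateau_corr[2])
  # dose accounting: linear in duration at fixed current
  fit <- stats::lm(sw$dose ~ sw$durations)
  expect_gt(summary(fit)$r.squared, 0.9999)
  # identical seed reproduces the sweep bit for bit
  sw2 <- sweep_pulse_duration(beam, det, sw$durations, grid = fix_grid20(),
                              medium = fix_medium(), seed = 1L)
  expect_identical(sw2$snr_d_corr, sw$snr_d_corr)
  expect_identical(sw2$argmax_corr, sw$argmax_corr)
})

test_that("correlation gain over the raw SNR rises with pulse duration", {
  sw <- fix_sweep20()
  gain <- sw$snr_d_corr / sw$snr_d_raw
  i50 <- which.min(abs(sw$durations - 50e-9))
  i500 <- which.min(abs(sw$durations - 500e-9))
  expect_gt(gain[i500], gain[i50])
  # monotone trend on a smoothed scale (pairwise over 3-point means)
  g3 <- stats::filter(gain[i50:i500], rep(1 / 3, 3))
  g3 <- g3[!is.na(g3)]
  expect_gt(mean(diff(g3) > 0), 0.8)
})

test_that("current scaling at a dose limit follows the current ratio", {
  med <- fix_medium()
  beam <- fix_beam20()
  det <- axial_detector(beam, 25.4, band = olympus_band())
  cs <- suppressWarnings(
    current_scaling_study(c(0.65e-6, 4.5e-6), dose_limit = 12, beam, det,
                          medium = med, duration = 160e-9, noise_rms = 0.5,
                          seed = 3))
  expect_equal(cs$snr[2] / cs$snr[1], 4.5 / 0.65, tolerance = 0.25)
  # a single current row compares to itself
  one <- suppressWarnings(
    current_scaling_study(4.5e-6, dose_limit = 12, beam, det, medium = med,
                          duration = 160e-9, noise_rms = 0.5, seed = 3))
  expect_equal(one$snr, one$snr_predicted)
  expect_error(current_scaling_study(4.5e-6, dose_limit = 12, beam, det,
                                     medium = med, noise_rms = 0),
               "zero noise")
  expect_error(suppressWarnings(
    current_scaling_study(4.5e-6, dose_limit = 1e-6, beam, det, medium = med,
                          duration = 160e-9, noise_rms = 0.5)),
    "exceeds the dose limit")
})

test_that("chopping long pulses at the ideal duration wins at equal dose", {
  med <- fix_medium()
  beam <- fix_beam20()
  det <- axial_detector(beam, 25.4) # broadband point sensor
  durations <- exp(seq(log(5e-8), log(2e-6), length.out = 10))
  tab <- single_vs_chopped(durations, reference_duration = 150e-9,
                           dose_limit = 1, beam, det, medium = med)
  long <- tab$duration >= 2 * 150e-9
  expect_true(all(tab$snr_d_chopped_raw[long] > tab$snr_d_single_raw[long]))
  expect_true(all(tab$snr_d_chopped_corr[long] > tab$snr_d_single_corr[long]))
  # at the reference duration both strategies coincide
  tab_ref <- single_vs_chopped(c(150e-9, 150e-9 * 2, 150e-9 * 20),
                               reference_duration = 150e-9, dose_limit = 1,
                               beam, det, medium = med)
  expect_equal(tab_ref$snr_d_chopped_raw[1], tab_ref$snr_d_single_raw[1],
               tolerance = 1e-9)
  # shrinking the single pulse below the reference keeps raising SNR_D
  short <- tab[tab$duration <= 150e-9, ]
  expect_true(all(diff(short$snr_d_single_raw) < 0)) # decreasing with duration
})

test_that("central frequency matches spectral oracles", {
  dt <- 1e-7
  tt <- seq(0, 5e-4, by = dt)
  f0 <- 1.23e5
  tone <- pressure_trace(0, dt, sin(2 * pi * f0 * tt))
  expect_equal(central_frequency(tone), f0, tolerance = 0.01)
  # amplitude scaling leaves it unchanged
  tone5 <- pressure_trace(0, dt, 5 * sin(2 * pi * f0 * tt))
  expect_equal(central_frequency(tone5), central_frequency(tone))
  # Gaussian-windowed sinusoid: the spectrum is a Gaussian centered at f0
  env <- exp(-0.5 * ((tt - 2.5e-4) / 5e-5)^2)
  gaus <- pressure_trace(0, dt, env * sin(2 * pi * f0 * tt))
  expect_equal(central_frequency(gaus), f0, tolerance = 0.01)
  expect_error(central_frequency(pressure_trace(0, dt, numeric(100))),
               "all-zero")
})

test_that("ideal durations lengthen and spectra soften with beam energy", {
  tab <- suppressWarnings(
    ideal_duration_vs_energy(c(70, 150, 230), n_durations = 12,
                             n_theta = 64, n_phi = 128))
  expect_true(all(diff(tab$ideal_fwhm) > 0))
  expect_true(all(diff(tab$central_frequency) < 0))
  # the plateau band brackets the optimum
  expect_true(all(tab$band_lo <= tab$ideal_fwhm &
                    tab$ideal_fwhm <= tab$band_hi))
})
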