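test_that("normalized cross-correlation obeys the matched-filter identities", {
  tm <- burst_template()
  m_self <- pressure_trace(tm$t0, tm$dt, tm$samples, kind = "measurement")
  cc <- normalized_crosscorr(m_self, tm)
  expect_equal(cc$peak_value, 1, tolerance = 1e-12)
  expect_equal(cc$peak_lag, 0, tolerance = 1e-15)
  expect_true(all(abs(cc$values) <= 1 + 1e-9))
  # pure delay: peak at exactly k * dt
  k <- 37L
  delayed <- pressure_trace(0, tm$dt, c(numeric(k), tm$samples, numeric(40)),
                            kind = "measurement")
  ccd <- normalized_crosscorr(delayed, tm)
  expect_equal(ccd$peak_lag, k * tm$dt, tolerance = 1e-15)
  expect_equal(ccd$peak_value, 1, tolerance = 1e-12)
  # anti-correlation
  anti <- pressure_trace(0, tm$dt, -tm$samples, kind = "measurement")
  cca <- normalized_crosscorr(anti, tm)
  expect_equal(min(cca$values), -1, tolerance = 1e-12)
  # degenerate inputs
  zero <- pressure_trace(0, tm$dt, numeric(length(tm$samples)))
  expect_error(normalized_crosscorr(zero, tm), "all-zero")
  expect_error(normalized_crosscorr(m_self, zero), "all-zero")
})

test_that("FFT correlation equals the brute-force quadratic-time oracle", {
  set.seed(5)
  for (rep in 1:3) {
    m <- rnorm(400); t <- rnorm(150)
    mm <- pressure_trace(0, 1e-6, m, kind = "measurement")
    tt <- pressure_trace(0, 1e-6, t, kind = "template")
    cc <- normalized_crosscorr(mm, tt)
    ref <- brute_crosscorr(m, t)
    expect_equal(cc$values, ref$values, tolerance = 1e-10)
    expect_equal(cc$lags, ref$lags * 1e-6, tolerance = 1e-12)
  }
})

test_that("signal window follows the 20% threshold rule", {
  dt <- 0.01
  # piecewise-linear bipolar shape: 0 -> 1 over [0,1], 1 -> -1 over [1,2],
  # -1 -> 0 over [2,3]; closed-form 20% crossings at 0.2 and 2.8
  tt <- seq(0, 3, by = dt)
  y <- ifelse(tt <= 1, tt, ifelse(tt <= 2, 1 - 2 * (tt - 1), -1 + (tt - 2)))
  tr <- pressure_trace(0, dt, y, kind = "template")
  w <- signal_window_from_template(tr)
  expect_equal(w[1], 0.2, tolerance = dt)
  expect_equal(w[2], 2.8, tolerance = dt)
  # threshold is relative: amplitude scaling leaves the window unchanged
  tr10 <- pressure_trace(0, dt, 10 * y, kind = "template")
  expect_equal(signal_window_from_template(tr10), w, tolerance = 1e-12)
  # unipolar shape has no negative lobe
  tri <- pressure_trace(0, dt, pmax(0, 1 - abs(tt - 1)), kind = "template")
  expect_error(signal_window_from_template(tri), "negative minimum")
})

test_that("correlation window comes from the autocorrelation zero crossings", {
  dt <- 1e-3
  period <- 0.2
  tt <- seq(0, period - dt, by = dt)
  y <- sin(2 * pi * tt / period)
  sine <- pressure_trace(0, dt, y, kind = "template")
  w <- correlation_window_from_template(sine)
  # independent oracle: brute-force autocorrelation, zero crossings adjacent
  # to the main peak found by direct scan
  n <- length(y)
  ac <- vapply(0:(n - 1), function(k) {
    sum(y[seq_len(n - k)] * y[seq_len(n - k) + k])
  }, numeric(1))
  kz <- which(ac <= 0)[1]
  fz <- ac[kz - 1] / (ac[kz - 1] - ac[kz])
  w_oracle <- 2 * (kz - 2 + fz) * dt # symmetric about zero lag
  expect_equal(w, w_oracle, tolerance = dt / w_oracle)
  # near half a period (finite-window autocorrelation shifts it slightly)
  expect_gt(w, period / 4)
  expect_lt(w, 3 * period / 4)
  # amplitude invariance
  sine5 <- pressure_trace(0, dt, 5 * sin(2 * pi * tt / period))
  expect_equal(correlation_window_from_template(sine5), w, tolerance = 1e-12)
  # longer, lower-frequency templates broaden the correlation peak
  w_long <- correlation_window_from_template(burst_template(n_cycles = 2,
                                                            freq = 2.5e5))
  w_short <- correlation_window_from_template(burst_template(n_cycles = 2,
                                                             freq = 1e6))
  expect_gt(w_long, w_short)
})

test_that("moving-average power matches closed forms and noise statistics", {
  dt <- 1e-6
  const <- pressure_trace(0, dt, rep(3, 500))
  expect_true(all(abs(moving_average_power(const, 20 * dt)$samples - 9) < 1e-12))
  # burst of amplitude A and window length: max power is exactly A^2
  nd <- 25L
  y <- c(numeric(100), rep(2, nd), numeric(100))
  burst <- pressure_trace(0, dt, y)
  expect_equal(max(moving_average_power(burst, nd * dt)$samples), 4)
  # white noise: mean windowed power estimates the variance
  set.seed(21)
  sigma <- 0.7
  nz <- pressure_trace(0, dt, rnorm(20000, sd = sigma))
  pw <- moving_average_power(nz, 50 * dt)
  expect_equal(mean(pw$samples), sigma^2, tolerance = 0.05)
  expect_error(moving_average_power(const, 1000 * dt), "longer than the trace")
})

test_that("snr matches its definition and guards degenerate input", {
  dt <- 1e-6
  set.seed(3)
  sig <- c(numeric(600), 5 * sin(2 * pi * (1:60) / 20), numeric(200))
  noise <- rnorm(length(sig), sd = 0.05)
  tr <- pressure_trace(0, dt, sig + noise, kind = "measurement")
  rep1 <- snr(tr, 60 * dt, noise_window = c(0, 500 * dt))
  # amplitude x2 at fixed noise: power SNR x4 (small-noise regime)
  tr2 <- pressure_trace(0, dt, 2 * sig + noise, kind = "measurement")
  rep2 <- snr(tr2, 60 * dt, noise_window = c(0, 500 * dt))
  expect_equal(rep2$snr / rep1$snr, 4, tolerance = 0.05)
  # windows: noise precedes signal; search region after the noise window
  expect_true(rep1$noise_window[2] <= rep1$signal_window[1])
  expect_equal(rep1$snr, rep1$signal_power / rep1$noise_power)
  # zero noise power is undefined
  clean <- pressure_trace(0, dt, sig, kind = "measurement")
  expect_error(snr(clean, 60 * dt, noise_window = c(0, 500 * dt)),
               "zero noise power")
  # short noise window warns
  expect_warning(snr(tr, 200 * dt, noise_window = c(0, 500 * dt)),
                 "noise window shorter")
})

test_that("snr of pure noise matches a Monte Carlo max-of-windows oracle", {
  dt <- 1e-6
  n <- 2000L; nw <- 50L
  # independent oracle: direct loop over window means, no package code
  oracle_one <- function(x) {
    x2 <- x^2
    best <- -Inf
    for (p in seq(1001L, n - nw + 1L, by = 1L)) {
      best <- max(best, mean(x2[p:(p + nw - 1L)]))
    }
    best / mean(x2[1:1000])
  }
  set.seed(17)
  oracle <- mean(replicate(40, oracle_one(rnorm(n))))
  set.seed(17)
  got <- mean(replicate(40, {
    tr <- pressure_trace(0, dt, rnorm(n), kind = "measurement")
    snr(tr, nw * dt, noise_window = c(0, 999 * dt))$snr
  }))
  expect_equal(got, oracle, tolerance = 0.05)
  # and the value itself is near unity (max-of-windows bias is mild)
  expect_lt(abs(got - 1), 1)
})

test_that("correlation SNR is reproducible and grows with template energy", {
  dt <- 1 / 50e6
  noise_src <- function(n, dt) make_noise(n, dt, rms = 0.2)
  meas_of <- function(tm) {
    pressure_trace(0, dt, c(numeric(300), tm$samples, numeric(300)),
                   kind = "measurement")
  }
  t_short <- burst_template(n_cycles = 1)
  t_long <- burst_template(n_cycles = 6)
  r1 <- snr_of_correlation(meas_of(t_short), t_short, noise_src,
                           n_repeats = 30, seed = 9)
  r1b <- snr_of_correlation(meas_of(t_short), t_short, noise_src,
                            n_repeats = 30, seed = 9)
  expect_identical(r1$snr, r1b$snr) # fixed seed, bit-identical
  r2 <- snr_of_correlation(meas_of(t_long), t_long, noise_src,
                           n_repeats = 30, seed = 9)
  # same peak amplitude, more contained energy -> higher correlation SNR
  expect_gt(r2$snr, r1$snr)
  # zero noise is guarded
  zero_src <- function(n, dt) pressure_trace(0, dt, numeric(n))
  expect_error(snr_of_correlation(meas_of(t_short), t_short, zero_src,
                                  n_repeats = 2),
               "zero correlation noise power")
})

test_that("dose-limited SNR is the SNR per gray", {
  expect_equal(snr_d(28, 0.5), 56)
  expect_equal(snr_d(28, 1), 28)
  expect_equal(snr_d(2 * 28, 2 * 0.5), 56) # joint scaling invariance
  expect_error(snr_d(28, 0), "positive")
})

test_that("the matched filter beats a panel of alternative linear filters", {
  dt <- 1 / 50e6
  tm <- burst_template(n_cycles = 2, freq = 1e6, dt = dt)
  nt <- length(tm$samples)
  fs <- 1 / dt
  alt_filters <- list(
    narrow = signal::butter(1, c(0.5e6, 2e6) / (fs / 2), type = "pass"),
    wide = signal::butter(1, c(0.2e6, 8e6) / (fs / 2), type = "pass")
  )
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    m <- c(numeric(400), tm$samples, numeric(400)) + rnorm(800 + nt, sd = 0.5)
    noise_only <- rnorm(800 + nt, sd = 0.5)
    peak_snr <- function(x, xn) max(x^2) / mean(xn^2)
    mm <- pressure_trace(0, dt, m, kind = "measurement")
    matched <- normalized_crosscorr(mm, tm)
    matched_noise <- normalized_crosscorr(
      pressure_trace(0, dt, noise_only, kind = "measurement"), tm)
    s_m <- peak_snr(matched$values, matched_noise$values)
    s_alt <- vapply(alt_filters, function(bf) {
      peak_snr(as.numeric(signal::filter(bf, m)),
               as.numeric(signal::filter(bf, noise_only)))
    }, numeric(1))
    s_diff <- peak_snr(diff(m), diff(noise_only))
    all(s_m >= c(s_alt, s_diff))
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})
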