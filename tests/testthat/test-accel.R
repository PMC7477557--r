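test_that("vibration magnitude is the Euclidean norm and rotation-invariant", {
  tr <- accel_trace(gx = c(3, 0, 1), gy = c(4, 0, 1), gz = c(0, 1, 1),
                    sample_rate = 10)
  expect_equal(vibration_magnitude(tr), c(5, 1, sqrt(3)))

  set.seed(7)
  n <- 200
  g <- matrix(rnorm(3 * n), ncol = 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthogonal matrix
  gr <- g %*% R
  m1 <- vibration_magnitude(accel_trace(g[, 1], g[, 2], g[, 3]))
  m2 <- vibration_magnitude(accel_trace(gr[, 1], gr[, 2], gr[, 3]))
  expect_equal(m1, m2, tolerance = 1e-12)

  expect_error(accel_trace(1:3, 1:2, 1:3), "same length")
})

test_that("high-pass design meets the stopband and passband specification", {
  filt <- design_highpass()
  # single-pass stopband: >= 60 dB down at the 5 Hz edge
  expect_lte(filter_response(filt, 5), 10^(-60 / 20))
  # deep stopband stays at least as attenuated as the edge
  expect_gte(-20 * log10(filter_response(filt, 2)),
             -20 * log10(filter_response(filt, 5)))
  # passband within 1 dB of unity from the 10 Hz edge up
  f_pass <- c(10, 10.5, 12, 20, 50, 100, 500, 1000, 2400)
  resp_db <- 20 * log10(filter_response(filt, f_pass))
  expect_true(all(resp_db >= -1 - 1e-3 & resp_db <= 1e-3))

  expect_error(filter_spec(stop_hz = 10, pass_hz = 5), "stop_hz < pass_hz")
})

test_that("zero-phase filtering removes stopband tones, keeps passband, zero lag", {
  filt <- design_highpass()
  fs <- 5000
  t <- seq(0, 30, by = 1 / fs)

  # 1 Hz tone: doubled 60 dB attenuation, measured away from edge transients
  y1 <- zero_phase_filter(sin(2 * pi * 1 * t), filt)
  interior <- (5 * fs):(25 * fs)
  expect_lt(max(abs(y1[interior])), 1e-6 + 1e-6)

  # DC is annihilated
  ydc <- zero_phase_filter(rep(3.7, 5 * fs), filt)
  expect_lt(max(abs(ydc)), 1e-4)

  # 100 Hz tone: amplitude within the doubled passband ripple, peak at lag 0
  x100 <- sin(2 * pi * 100 * t)
  y100 <- zero_phase_filter(x100, filt)
  amp <- max(abs(y100[interior]))
  expect_gt(amp, 10^(-2 / 20))  # 2 dB = doubled 1 dB ripple
  expect_lte(amp, 1 + 1e-6)
  cc <- ccf(y100[interior], x100[interior], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # forward-backward symmetry: filtering a reversed signal reverses the
  # output once endpoint-driven edge transients have decayed (compared on
  # the interior; a wider-band filter keeps the transients short)
  set.seed(1)
  filt2 <- design_highpass(filter_spec(stop_hz = 200, pass_hz = 400,
                                       sample_rate = 5000))
  x <- rnorm(4000)
  interior <- 1000:3000
  expect_equal(zero_phase_filter(rev(x), filt2)[interior],
               rev(zero_phase_filter(x, filt2))[interior], tolerance = 1e-8)

  expect_error(zero_phase_filter(rnorm(10), filt), "too short")
})

test_that("RMS bins follow closed forms and drop the trailing partial bin", {
  fs <- 100
  # constant c over full bins -> |c|
  rb <- rms_bins(rep(-2, 3 * fs), fs)
  expect_equal(rb$rms, rep(2, 3))
  expect_equal(rb$bin_start_s, 0:2)
  # sinusoid with integer cycles per bin -> A/sqrt(2)
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  rb <- rms_bins(3 * sin(2 * pi * 5 * t), fs)
  expect_equal(rb$rms, rep(3 / sqrt(2), 2), tolerance = 1e-6)
  # zeros -> 0; partial bin dropped; empty in -> empty out
  expect_equal(rms_bins(rep(0, 250), fs)$rms, c(0, 0))
  expect_equal(nrow(rms_bins(numeric(0), fs)), 0)
  # identical bins give identical RMS
  x <- rnorm(fs)
  rb <- rms_bins(rep(x, 4), fs)
  expect_equal(rb$rms, rep(rb$rms[1], 4))
})

test_that("Welch PSD locates tones and conserves broadband power", {
  fs <- 5000
  t <- seq(0, 8, by = 1 / fs)

  p <- welch_psd(sin(2 * pi * 250 * t), fs)
  df <- diff(p$freq_hz[1:2])
  expect_lt(abs(p$freq_hz[which.max(p$power)] - 250), df + 1e-9)

  # two tones -> local maxima at both frequencies
  x <- sin(2 * pi * 116 * t) + sin(2 * pi * 876 * t)
  p <- welch_psd(x, fs)
  for (f0 in c(116, 876)) {
    near <- which(abs(p$freq_hz - f0) < 5)
    expect_lt(abs(p$freq_hz[near[which.max(p$power[near])]] - f0), df + 1e-9)
  }

  # Parseval: integral of one-sided PSD ~ variance of white noise
  set.seed(42)
  sigma <- 0.7
  x <- rnorm(length(t), 0, sigma)
  p <- welch_psd(x, fs)
  expect_lt(abs(sum(p$power) * df - sigma^2) / sigma^2, 0.1)

  expect_error(welch_psd(rnorm(20), fs), "too short")
})
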