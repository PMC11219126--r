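test_that("identity filter has a flat 0 dB response", {
  f <- design_fir_lowpass(80, 84, 1000)
  f$b <- 1
  resp <- response_direct(f, passes = 1)
  expect_equal(resp$gain_db, rep(0, nrow(resp)), tolerance = 1e-12)
})

test_that("direct response agrees with steady-state sinusoid simulation", {
  fs <- 1000
  iir <- design_butterworth_lowpass(7, 81, fs)
  resp <- response_direct(iir, passes = 2)
  t <- (0:9999) / fs
  for (fr in seq(10, 105, by = 5)) { # 20 probes across pass and transition band
    x <- sin(2 * pi * fr * t)
    amp <- fit_sine_amplitude(filter_zero_phase_for_test(iir, x), fr, fs, trim = 2000)
    grid_gain <- stats::approx(resp$freq_hz, resp$gain_db, xout = fr)$y
    expect_equal(20 * log10(amp), grid_gain, tolerance = 0.05)
  }
})

test_that("table 1 designs place their zero-phase -3 dB points at ~75 Hz", {
  d <- lapply(table1_filters(), response_direct)
  expect_equal(crossing_frequency(d$sg, -3), 74.9, tolerance = 1)
  expect_equal(crossing_frequency(d$iir, -3), 75.4, tolerance = 1)
  expect_equal(crossing_frequency(d$fir, -3), 75.0, tolerance = 1)
  # the IIR gain at the published crossing is -3 dB within 0.2 dB
  g754 <- stats::approx(d$iir$freq_hz, d$iir$gain_db, xout = 75.4)$y
  expect_equal(g754, -3, tolerance = 0.2)
})

test_that("crossing search interpolates linearly and flags unreached levels", {
  # synthetic monotone curve gain = -f/10: -30 dB exactly at 300 Hz
  lin <- structure(
    tibble::tibble(freq_hz = seq(0, 500, by = 2), gain_db = -seq(0, 500, by = 2) / 10),
    class = c("freq_response", class(tibble::tibble()))
  )
  expect_equal(crossing_frequency(lin, -30), 300)
  expect_true(is.na(crossing_frequency(lin, -60)))
  expect_error(crossing_frequency(lin, 1), class = "gazefilt_invalid_input")
})

test_that("crossings deepen with level: f(-40) >= f(-30) >= f(-3)", {
  for (resp in lapply(table1_filters(), response_direct)) {
    c3 <- crossing_frequency(resp, -3)
    c30 <- crossing_frequency(resp, -30)
    c40 <- crossing_frequency(resp, -40)
    expect_gte(c30, c3)
    if (!is.na(c40)) expect_gte(c40, c30)
  }
})

test_that("last exceedance brackets ringing responses from above", {
  sg <- response_direct(design_savgol(23, 5))
  first <- crossing_frequency(sg, -30)
  last <- last_exceedance(sg, -30)
  expect_lt(first, 110) # narrow notch near 106 Hz
  # SG stop-band lobes stay above -30 dB all the way to Nyquist
  expect_gt(last, 490)
})

test_that("dB levels map to the conventional percent-of-power annotations", {
  expect_equal(round(percent_remaining(-18), 2), 1.58)
  expect_equal(round(percent_remaining(-25), 2), 0.32)
  expect_equal(percent_remaining(-30), 0.1, tolerance = 1e-9)
})

test_that("ratio of a spectrum set with itself is 0 dB", {
  withr::local_seed(2)
  blocks <- matrix(rnorm(256 * 20), nrow = 256)
  s <- average_spectra(blocks)
  resp <- response_by_ratio(s, s)
  expect_equal(resp$gain_db[-1], rep(0, 127), tolerance = 1e-9)
})

test_that("ratio method matches the direct response where the curve is resolvable", {
  # white-noise ratio estimates are leakage-limited at the 3.906 Hz grid,
  # so the comparison is made on the resolvable region: bins where the
  # response is above -25 dB and locally flat relative to the bin width
  # (changes < 3 dB per bin); there agreement is within 1 dB
  for (f in table1_filters()) {
    direct <- response_direct(f)
    meas <- measured_response(f, n_blocks = 300, seed = 10)
    dg <- stats::approx(direct$freq_hz, direct$gain_db, xout = meas$freq_hz)$y
    step <- pmax(abs(c(NA, diff(dg))), abs(c(diff(dg), NA)))
    keep <- !is.na(step) & meas$freq_hz > 0 & meas$freq_hz < 450 &
      dg > -25 & step < 3
    expect_gt(sum(keep), 15)
    expect_lt(max(abs(meas$gain_db[keep] - dg[keep])), 1)
  }
})

test_that("ratio and direct -3 dB crossings agree within one spectral bin", {
  for (f in table1_filters()) {
    c_dir <- crossing_frequency(response_direct(f), -3)
    c_rat <- crossing_frequency(measured_response(f, n_blocks = 300, seed = 11), -3)
    expect_lt(abs(c_dir - c_rat), 3.90625)
  }
})

test_that("mismatched spectrum sets are rejected by the ratio method", {
  withr::local_seed(3)
  a <- average_spectra(matrix(rnorm(256 * 5), 256))
  b <- average_spectra(matrix(rnorm(512 * 5), 512))
  expect_error(response_by_ratio(a, b), class = "gazefilt_invalid_input")
})

test_that("complex per-block ratio mode recovers the response of a smooth filter", {
  iir <- design_butterworth_lowpass(7, 81, 1000)
  x <- withr::with_seed(21, rnorm(300 * 256 + 2048))
  y <- filter_zero_phase_for_test(iir, x)
  idx <- 1024 + seq_len(300 * 256)
  bu <- average_spectra(matrix(x[idx], 256), keep_complex = TRUE)
  bf <- average_spectra(matrix(y[idx], 256), keep_complex = TRUE)
  resp <- response_by_ratio(bu, bf, mode = "complex")
  direct <- response_direct(iir)
  dg <- stats::approx(direct$freq_hz, direct$gain_db, xout = resp$freq_hz)$y
  keep <- resp$freq_hz > 0 & dg > -15
  expect_lt(stats::median(abs(resp$gain_db[keep] - dg[keep])), 1)
})
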