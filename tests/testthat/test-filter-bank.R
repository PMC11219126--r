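test_that("SG design validates its window and order", {
  expect_error(design_savgol(22, 5), class = "gazefilt_invalid_parameter")
  expect_error(design_savgol(23, 23), class = "gazefilt_invalid_parameter")
})

test_that("degree-4 SG fit through 5 points is the identity kernel", {
  f <- design_savgol(5, 4)
  expect_equal(f$b, c(0, 0, 1, 0, 0), tolerance = 1e-10)
})

test_that("SG kernel equals the explicit normal-equations projection row", {
  for (cfg in list(c(11, 2), c(23, 5), c(9, 4))) {
    f <- design_savgol(cfg[1], cfg[2])
    expect_equal(f$b, savgol_kernel_naive(cfg[1], cfg[2]), tolerance = 1e-9)
    # symmetric about the centre and unit DC gain
    expect_equal(f$b, rev(f$b), tolerance = 1e-9)
    expect_equal(sum(f$b), 1, tolerance = 1e-9)
  }
})

test_that("SG filtering reproduces per-window polynomial fits at interior samples", {
  withr::local_seed(4)
  x <- cumsum(rnorm(200))
  tr <- gaze_trace(x, fs_hz = 1000)
  out <- apply_filter(tr, design_savgol(11, 2))$x_dva
  for (i in c(30, 100, 171)) {
    win <- x[(i - 5):(i + 5)]
    t <- seq(-5, 5)
    fit <- lm(win ~ t + I(t^2))
    expect_equal(out[i], unname(coef(fit)[1]), tolerance = 1e-9)
  }
})

test_that("Butterworth design hits -3 dB at its cutoff and matches the analog magnitude", {
  f <- design_butterworth_lowpass(7, 81, 1000)
  expect_equal(20 * log10(tf_mag_naive(f$b, f$a, 81, 1000)), -3.0103, tolerance = 0.1)
  # far below Nyquist the bilinear warp is negligible: closed-form analog
  # Butterworth magnitude 1/sqrt(1 + (f/81)^14) within 0.05 dB up to 40 Hz
  for (fr in seq(5, 40, by = 5)) {
    got <- 20 * log10(tf_mag_naive(f$b, f$a, fr, 1000))
    want <- 20 * log10(1 / sqrt(1 + (fr / 81)^14))
    expect_equal(got, want, tolerance = 0.05)
  }
  expect_error(design_butterworth_lowpass(7, 500, 1000), class = "gazefilt_invalid_parameter")
})

test_that("FIR design is unit-DC, linear-phase, and near signal::fir1's", {
  f <- design_fir_lowpass(80, 84, 1000)
  expect_equal(sum(f$b), 1, tolerance = 1e-9)
  expect_equal(f$b, rev(f$b), tolerance = 1e-12) # symmetric taps
  # the same design by signal::fir1 (its cutoff convention differs slightly);
  # the two-pass -3 dB points should sit within ~1 Hz of each other
  alt <- signal::fir1(79, 84 / 500)
  c1 <- crossing_frequency(response_direct(f, passes = 2), -3)
  g <- design_fir_lowpass(80, 84, 1000)
  g$b <- as.numeric(alt) / sum(alt)
  c2 <- crossing_frequency(response_direct(g, passes = 2), -3)
  expect_lt(abs(c1 - c2), 1)
  expect_error(design_fir_lowpass(1, 84, 1000), class = "gazefilt_invalid_parameter")
})

test_that("tap-count estimate follows the Bellanger formula with a floor of 2", {
  # (2/3) * log10(1e4) * 25 = 66.67 -> 67
  expect_identical(estimate_fir_taps(0.01, 0.001, 1000, 40), 67L)
  # 10 * d1 * d2 = 1 -> log term 0 -> floor of 2
  expect_identical(estimate_fir_taps(0.5, 0.2, 1000, 40), 2L)
  # fs = transition width, 10 * d1 * d2 = 1e-3 -> exactly 2
  expect_identical(estimate_fir_taps(0.01, 0.01, 500, 500), 2L)
  expect_error(estimate_fir_taps(0, 0.1, 1000, 40), class = "gazefilt_invalid_parameter")
})

test_that("every designed filter leaves a constant trace unchanged", {
  tr <- gaze_trace(rep(3.5, 2000), fs_hz = 1000)
  for (f in table1_filters()) {
    out <- apply_filter(tr, f)$x_dva
    expect_equal(out, rep(3.5, 2000), tolerance = 1e-9)
  }
})

test_that("zero-phase filtering has no delay and squares the magnitude response", {
  fs <- 1000
  t <- (0:5999) / fs
  x <- sin(2 * pi * 20 * t)
  iir <- design_butterworth_lowpass(7, 81, fs)
  y <- filter_zero_phase_for_test(iir, x)
  # amplitude equals single-pass |H(20)|^2
  amp <- fit_sine_amplitude(y, 20, fs)
  expect_equal(amp, tf_mag_naive(iir$b, iir$a, 20, fs)^2, tolerance = 0.005)
  # no lag: cross-correlation with the input peaks at lag 0
  cc <- stats::ccf(y[501:5500], x[501:5500], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("two-pass attenuation is exactly twice the single-pass attenuation in dB", {
  fs <- 1000
  t <- (0:7999) / fs
  for (f in list(
    design_butterworth_lowpass(7, 81, fs),
    design_fir_lowpass(80, 84, fs)
  )) {
    for (fr in c(10, 40, 60, 75)) { # steady-state measurable band
      x <- sin(2 * pi * fr * t)
      one <- fit_sine_amplitude(as.numeric(signal::filter(f$b, f$a, x)), fr, fs, trim = 1500)
      two <- fit_sine_amplitude(filter_zero_phase_for_test(f, x), fr, fs, trim = 1500)
      expect_equal(20 * log10(two), 2 * 20 * log10(one), tolerance = 0.05)
    }
  }
})

test_that("zero-phase filtering commutes with time reversal", {
  withr::local_seed(8)
  x <- cumsum(rnorm(4000)) / 10
  iir <- design_butterworth_lowpass(7, 81, 1000)
  a <- filter_zero_phase_for_test(iir, rev(x))
  b <- rev(filter_zero_phase_for_test(iir, x))
  core <- 200:3800 # edges excluded
  expect_equal(a[core], b[core], tolerance = 1e-8)
})

test_that("traces too short for zero-phase edge handling are rejected", {
  short <- gaze_trace(rnorm(20), fs_hz = 1000)
  expect_error(
    apply_filter(short, design_fir_lowpass(80, 84, 1000)),
    class = "gazefilt_invalid_input"
  )
})

test_that("unit-circle stability test separates stable and unstable feedback", {
  expect_true(is_stable(design_butterworth_lowpass(7, 81, 1000)))
  expect_true(is_stable(design_fir_lowpass(80, 84, 1000))) # FIR always stable
  expect_true(is_stable(design_savgol(23, 5)))
  # hand-built feedback polynomial with a root at modulus 1.01
  bad <- design_butterworth_lowpass(2, 100, 1000)
  bad$a <- c(1, -1.01) # y[n] = 1.01 y[n-1] + ... : root at z = 1.01
  expect_equal(max(Mod(polyroot(rev(bad$a)))), 1.01, tolerance = 1e-9)
  expect_false(is_stable(bad))
})

test_that("filters round-trip through the two-column text + JSON sidecar", {
  path <- withr::local_tempfile(fileext = ".txt")
  f <- design_fir_lowpass(80, 84, 1000)
  write_filter(f, path)
  g <- read_filter(path)
  expect_equal(g$b, f$b, tolerance = 1e-4) # six significant digits stored
  expect_identical(g$a, 1)
  expect_equal(g$spec$cutoff_hz, 84)
  expect_identical(g$spec$family, "fir_window")
  # writing the re-read filter reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_filter(g, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("filter tidiers expose coefficients and design summaries", {
  f <- design_butterworth_lowpass(7, 81, 1000)
  td <- tidy(f)
  expect_equal(nrow(td), 8)
  expect_equal(td$a[1], 1)
  gl <- glance(f)
  expect_identical(gl$family, "butterworth")
  expect_true(gl$stable)
  expect_equal(gl$dc_gain, 1, tolerance = 1e-9)
})
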