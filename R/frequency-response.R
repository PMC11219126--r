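#' Frequency response directly from filter coefficients
#'
#' Evaluates the discrete-time transfer function `H(z) = B(z)/A(z)` on a
#' uniform frequency grid from 0 to Nyquist and returns the gain in dB
#' (reference 1). For zero-phase (forward-backward) filters the two-pass
#' response is the squared magnitude, i.e. the single-pass attenuation in
#' dB doubled.
#'
#' @param filter A `lowpass_filter`.
#' @param n_grid Number of grid points (>= 512; default 8192 keeps the
#'   interpolation error of crossing searches well below 0.1 Hz).
#' @param passes 1 or 2; defaults to 2 when the filter was designed
#'   zero-phase, else 1.
#' @return A `freq_response` tibble with columns `freq_hz`, `gain_db` and
#'   attributes `passes`, `method = "direct"` and `fs_hz`.
#' @examples
#' resp <- response_direct(design_butterworth_lowpass(7, 81, 1000))
#' crossing_frequency(resp, -3)
#' @export
response_direct <- function(filter, n_grid = 8192, passes = NULL) {
  if (n_grid < 512) {
    abort("`n_grid` must be at least 512.", class = "gazefilt_invalid_parameter")
  }
  fs <- filter$spec$fs_hz
  passes <- passes %||% if (isTRUE(filter$spec$zero_phase)) 2L else 1L
  f <- seq(0, fs / 2, length.out = n_grid)
  h <- eval_transfer(filter$b, filter$a, f, fs)
  new_freq_response(f, passes * db_amplitude(Mod(h)),
    passes = passes, method = "direct", fs_hz = fs
  )
}

## H(e^{i 2 pi f / fs}); vectorised Horner evaluation in z^-1
eval_transfer <- function(b, a, f, fs) {
  zi <- exp(-2i * pi * f / fs)
  horner <- function(p) {
    acc <- rep(p[length(p)] + 0i, length(zi))
    if (length(p) > 1) {
      for (k in seq(length(p) - 1, 1)) acc <- acc * zi + p[k]
    }
    acc
  }
  horner(b) / horner(a)
}

db_amplitude <- function(amp) 20 * log10(pmax(amp, 1e-300))

new_freq_response <- function(freq_hz, gain_db, passes, method, fs_hz,
                              n_blocks = NA_integer_) {
  out <- new_tibble(list(freq_hz = freq_hz, gain_db = gain_db),
    nrow = length(freq_hz), class = "freq_response"
  )
  attr(out, "passes") <- passes
  attr(out, "method") <- method
  attr(out, "fs_hz") <- fs_hz
  attr(out, "n_blocks") <- n_blocks
  out
}

#' Empirical frequency response by the FFT ratio method
#'
#' Estimates a filter's gain curve as the bin-wise ratio of the averaged
#' magnitude spectrum of the filtered signal (`B`) to that of the
#' unfiltered signal (`A`): `C = B / A`, in dB. This is the only route
#' available for filters without coefficients (e.g. proprietary on-device
#' smoothers) and is computed here from two [spectrum_set] objects built
#' from the same blocks before and after filtering.
#'
#' Averaging the magnitude spectra first (the default) is the stable
#' estimator; `mode = "complex"` instead averages the real part of the
#' per-block complex ratios `FFT(filtered)/FFT(unfiltered)`, the literal
#' textbook ratio, which is noisier.
#'
#' Bins where the denominator underflows are flagged `NA` and ignored by
#' crossing searches. Note the estimate is leakage-limited: at the
#' 3.906 Hz resolution of 256-sample blocks the measured curve cannot
#' follow a response that falls faster than a few dB per bin, so deep
#' stop bands saturate at a leakage floor (see the package vignette).
#'
#' @param unfiltered,filtered `spectrum_set` objects over the same blocks
#'   (equal block length, count and sampling rate).
#' @param mode `"magnitude"` (ratio of averaged magnitude spectra) or
#'   `"complex"` (mean real part of per-block complex ratios).
#' @return A `freq_response` tibble with `method = "ratio"`.
#' @export
response_by_ratio <- function(unfiltered, filtered, mode = c("magnitude", "complex")) {
  mode <- match.arg(mode)
  stopifnot(inherits(unfiltered, "spectrum_set"), inherits(filtered, "spectrum_set"))
  if (unfiltered$block_len != filtered$block_len ||
    unfiltered$fs_hz != filtered$fs_hz ||
    unfiltered$n_blocks != filtered$n_blocks) {
    abort("The two spectrum sets must share block length, count and sampling rate.",
      class = "gazefilt_invalid_input"
    )
  }
  if (mode == "magnitude") {
    num <- filtered$mean_magnitude
    den <- unfiltered$mean_magnitude
    ratio <- ifelse(den > 0, num / den, NA_real_)
    gain <- ifelse(is.na(ratio), NA_real_, db_amplitude(ratio))
  } else {
    cu <- unfiltered$coef
    cf <- filtered$coef
    if (is.null(cu) || is.null(cf)) {
      abort("Complex mode needs spectrum sets built with `keep_complex = TRUE`.",
        class = "gazefilt_invalid_input"
      )
    }
    r <- rowMeans(Re(cf / cu))
    gain <- db_amplitude(abs(r))
  }
  new_freq_response(unfiltered$freq_hz, gain,
    passes = NA_integer_, method = "ratio",
    fs_hz = unfiltered$fs_hz, n_blocks = unfiltered$n_blocks
  )
}

#' Measure a filter's response on seeded white noise
#'
#' Runs the full ratio-method pipeline on synthetic white noise: a long
#' seeded Gaussian trace is filtered (zero-phase or single pass per the
#' design), both versions are cut into aligned blocks, each block is
#' quadratically detrended and Hanning-windowed, magnitude spectra are
#' averaged across blocks and the ratio is returned in dB. This reproduces
#' the measured gain curve of the study, including its resolution limits.
#'
#' @param filter A `lowpass_filter`.
#' @param n_blocks Number of blocks to average (>= 200 recommended).
#' @param block_len Block length in samples (power of two).
#' @param seed Integer RNG seed.
#' @return A `freq_response` tibble with `method = "ratio"`.
#' @export
measured_response <- function(filter, n_blocks = 400, block_len = 256, seed = 1) {
  fs <- filter$spec$fs_hz
  guard <- 4 * block_len # discard edges of the long trace
  n <- n_blocks * block_len + 2 * guard
  x <- withr::with_seed(seed, rnorm(n))
  y <- filter_series(x, filter, mode = "auto")
  idx <- guard + seq_len(n_blocks * block_len)
  bx <- matrix(x[idx], nrow = block_len)
  by <- matrix(y[idx], nrow = block_len)
  response_by_ratio(
    average_spectra(bx, fs_hz = fs),
    average_spectra(by, fs_hz = fs)
  )
}

#' Locate dB-level crossings of a response
#'
#' `crossing_frequency()` returns the first frequency at which the gain
#' curve falls to `level_db`, linearly interpolated between the bracketing
#' grid points, or `NA` if the level is never reached.
#' `last_exceedance()` returns the last frequency at which the curve is
#' still above `level_db` -- for responses with stop-band ringing (e.g.
#' Savitzky-Golay) the two together bracket the ambiguity of "reaches
#' level X at frequency f". `percent_remaining()` converts a dB level to
#' the percentage of signal power remaining (`100 * 10^(level/10)`), the
#' annotation convention used alongside such crossings.
#'
#' @param resp A `freq_response`.
#' @param level_db Level in dB (negative for attenuation).
#' @return A frequency in Hz (`NA_real_` if never crossed / exceeded).
#' @examples
#' resp <- response_direct(design_fir_lowpass(80, 84, 1000))
#' crossing_frequency(resp, -30)
#' @export
crossing_frequency <- function(resp, level_db) {
  f <- resp$freq_hz
  g <- resp$gain_db
  keep <- !is.na(g)
  f <- f[keep]
  g <- g[keep]
  if (length(g) == 0 || g[1] <= level_db) {
    abort("Response must start above `level_db` at its lowest frequency.",
      class = "gazefilt_invalid_input"
    )
  }
  below <- which(g <= level_db)
  if (length(below) == 0) {
    return(NA_real_)
  }
  i <- below[1]
  interp_level(f[i - 1], f[i], g[i - 1], g[i], level_db)
}

interp_level <- function(f0, f1, g0, g1, level) {
  if (g1 == g0) {
    return(f1)
  }
  f0 + (level - g0) * (f1 - f0) / (g1 - g0)
}

#' @rdname crossing_frequency
#' @export
last_exceedance <- function(resp, level_db) {
  f <- resp$freq_hz
  g <- resp$gain_db
  keep <- !is.na(g)
  f <- f[keep]
  g <- g[keep]
  above <- which(g > level_db)
  if (length(above) == 0) {
    return(NA_real_)
  }
  i <- above[length(above)]
  if (i == length(g)) {
    return(f[i])
  }
  interp_level(f[i], f[i + 1], g[i], g[i + 1], level_db)
}

#' @rdname crossing_frequency
#' @export
percent_remaining <- function(level_db) 100 * 10^(level_db / 10)

#' Crossing table for a set of filters
#'
#' Tabulates the interpolated level crossings of several responses at
#' several dB levels, with the power-percentage annotation and, for ringing
#' responses, the companion last-exceedance frequency.
#'
#' @param responses Named list of `freq_response` objects.
#' @param levels_db Numeric vector of dB levels.
#' @return A tibble with columns `filter`, `level_db`, `freq_hz`,
#'   `last_exceedance_hz`, `pct_power_remaining`.
#' @export
crossing_table <- function(responses, levels_db = c(-3, -30, -40)) {
  purrr::imap_dfr(responses, function(resp, name) {
    tibble(
      filter = name,
      level_db = levels_db,
      freq_hz = purrr::map_dbl(levels_db, ~ crossing_frequency(resp, .x)),
      last_exceedance_hz = purrr::map_dbl(levels_db, ~ last_exceedance(resp, .x)),
      pct_power_remaining = percent_remaining(levels_db)
    )
  })
}

#' Plot a frequency response
#'
#' @param object A `freq_response`.
#' @param ... Further responses to overlay, named.
#' @return A ggplot.
#' @method autoplot freq_response
#' @export
autoplot.freq_response <- function(object, ...) {
  extra <- list(...)
  dat <- dplyr::bind_rows(
    c(list(response = as_tibble(object)), purrr::map(extra, as_tibble)),
    .id = "curve"
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq_hz, .data$gain_db, colour = .data$curve)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Gain (dB re 1)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(-80, 5))
}
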