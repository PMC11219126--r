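#' Designed low-pass filters
#'
#' All designs return a `lowpass_filter`: a list with feed-forward
#' coefficients `b`, feedback coefficients `a` (`a = 1` for the FIR-type
#' filters) and a `spec` recording the design parameters. The three
#' constructors cover the filter families routinely applied to 1000 Hz
#' video-oculography signals:
#'
#' * `design_savgol()` -- Savitzky-Golay smoothing: the output at each
#'   sample is the centre value of a least-squares polynomial fit over a
#'   sliding window. The kernel is symmetric, hence inherently zero-phase,
#'   and is applied single-pass.
#' * `design_butterworth_lowpass()` -- digital Butterworth via the analog
#'   prototype and bilinear transform (maximally flat passband, monotone
#'   stopband), intended for forward-backward (zero-phase) use.
#' * `design_fir_lowpass()` -- windowed-sinc linear-phase FIR, coefficients
#'   normalised to unit DC gain, intended for forward-backward use.
#'
#' The reference designs of the study are window 23 / order 5 for SG,
#' order 7 / cutoff 81 Hz for the Butterworth, and 80 taps / cutoff 84 Hz
#' for the FIR; after the forward-backward pass all three place their
#' -3 dB point at ~75 Hz (see [table1_filters()]).
#'
#' @param window_length Odd SG window length in samples.
#' @param polyorder SG polynomial order, strictly less than `window_length`.
#' @param order Butterworth filter order.
#' @param cutoff_hz Nominal -3 dB design cutoff (single pass), in Hz.
#' @param fs_hz Sampling rate in Hz.
#' @param num_taps Number of FIR coefficients.
#' @param window FIR design window, `"hamming"` (default), `"hann"` or
#'   `"blackman"`.
#' @param zero_phase Whether the filter is meant to be applied
#'   forward-backward. Defaults follow the study: `TRUE` for Butterworth
#'   and FIR, `FALSE` (single centred pass) for SG.
#'
#' @return An object of class `lowpass_filter`.
#' @examples
#' fir <- design_fir_lowpass(80, 84, 1000)
#' sum(fir$b) # unit DC gain
#' @name filter_design
NULL

new_lowpass_filter <- function(b, a, spec) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (a[1] != 1) { # normalise so a[1] == 1
    b <- b / a[1]
    a <- a / a[1]
  }
  structure(list(b = b, a = a, spec = spec), class = "lowpass_filter")
}

#' @export
print.lowpass_filter <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<lowpass_filter> %s | %s | fs = %g Hz | %s\n",
    s$family,
    switch(s$family,
      savitzky_golay = sprintf("window %d, order %d", s$window_length, s$order),
      butterworth = sprintf("order %d, cutoff %g Hz", s$order, s$cutoff_hz),
      fir_window = sprintf("%d taps, cutoff %g Hz", s$num_taps, s$cutoff_hz),
      "custom"
    ),
    s$fs_hz,
    if (isTRUE(s$zero_phase)) "zero-phase (2 passes)" else "single pass"
  ))
  invisible(x)
}

check_cutoff <- function(cutoff_hz, fs_hz) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency.",
      class = "gazefilt_invalid_parameter"
    )
  }
}

#' @rdname filter_design
#' @export
design_savgol <- function(window_length, polyorder, fs_hz = 1000) {
  if (window_length %% 2 == 0) {
    abort("SG `window_length` must be odd.", class = "gazefilt_invalid_parameter")
  }
  if (polyorder >= window_length) {
    abort("SG `polyorder` must be smaller than `window_length`.",
      class = "gazefilt_invalid_parameter"
    )
  }
  proj <- signal::sgolay(p = polyorder, n = window_length)
  kernel <- as.numeric(proj[(window_length + 1) / 2, ])
  new_lowpass_filter(kernel, 1, spec = list(
    family = "savitzky_golay", order = polyorder, window_length = window_length,
    num_taps = window_length, cutoff_hz = NA_real_, fs_hz = fs_hz, zero_phase = FALSE
  ))
}

#' @rdname filter_design
#' @export
design_butterworth_lowpass <- function(order, cutoff_hz, fs_hz = 1000,
                                       zero_phase = TRUE) {
  check_cutoff(cutoff_hz, fs_hz)
  bw <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  new_lowpass_filter(bw$b, bw$a, spec = list(
    family = "butterworth", order = order, window_length = NA_integer_,
    num_taps = NA_integer_, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
    zero_phase = zero_phase
  ))
}

#' @rdname filter_design
#' @export
design_fir_lowpass <- function(num_taps, cutoff_hz, fs_hz = 1000,
                               window = c("hamming", "hann", "blackman"),
                               zero_phase = TRUE) {
  window <- match.arg(window)
  if (num_taps < 2) {
    abort("`num_taps` must be at least 2.", class = "gazefilt_invalid_parameter")
  }
  check_cutoff(cutoff_hz, fs_hz)
  m <- seq_len(num_taps) - 1 - (num_taps - 1) / 2
  fc <- cutoff_hz / fs_hz # cycles per sample
  h <- 2 * fc * sinc(2 * fc * m)
  n <- seq_len(num_taps) - 1
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * n / (num_taps - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * n / (num_taps - 1)),
    blackman = 0.42 - 0.5 * cos(2 * pi * n / (num_taps - 1)) +
      0.08 * cos(4 * pi * n / (num_taps - 1))
  )
  h <- h * w
  h <- h / sum(h) # unit DC gain
  new_lowpass_filter(h, 1, spec = list(
    family = "fir_window", order = num_taps - 1, window_length = NA_integer_,
    num_taps = num_taps, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
    zero_phase = zero_phase, window = window
  ))
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' The reference filter bank of the study
#'
#' Convenience constructor for the three filters compared throughout the
#' package: SG(23, 5), zero-phase Butterworth(7, 81 Hz) and zero-phase
#' windowed-sinc FIR(80 taps, 84 Hz), all at 1000 Hz.
#'
#' @param fs_hz Sampling rate in Hz.
#' @return Named list of `lowpass_filter` objects (`sg`, `iir`, `fir`).
#' @export
table1_filters <- function(fs_hz = 1000) {
  list(
    sg = design_savgol(23, 5, fs_hz),
    iir = design_butterworth_lowpass(7, 81, fs_hz),
    fir = design_fir_lowpass(80, 84, fs_hz)
  )
}

#' Estimate the FIR tap count for a target design
#'
#' Bellanger's rule of thumb for the length of a windowed/equiripple FIR
#' low-pass: `N ~ (2/3) * log10(1 / (10 * delta1 * delta2)) * fs / df`,
#' where `delta1` is the allowed passband ripple, `delta2` the stopband
#' suppression (both linear), `fs` the sampling rate and `df` the
#' transition width. The estimate is rounded up and never less than 2.
#'
#' @param delta1,delta2 Passband ripple and stopband suppression, linear,
#'   each in (0, 1).
#' @param fs_hz Sampling rate (Hz).
#' @param transition_hz Transition width (Hz), positive.
#' @return Integer tap count (minimum 2).
#' @examples
#' estimate_fir_taps(0.01, 0.001, 1000, 40) # 67
#' @export
estimate_fir_taps <- function(delta1, delta2, fs_hz, transition_hz) {
  if (delta1 <= 0 || delta1 >= 1 || delta2 <= 0 || delta2 >= 1) {
    abort("`delta1` and `delta2` must lie in (0, 1).", class = "gazefilt_invalid_parameter")
  }
  if (transition_hz <= 0) {
    abort("`transition_hz` must be positive.", class = "gazefilt_invalid_parameter")
  }
  n <- (2 / 3) * log10(1 / (10 * delta1 * delta2)) * fs_hz / transition_hz
  max(2L, as.integer(ceiling(n)))
}

#' Check IIR stability by the unit-circle test
#'
#' A recursive filter is stable iff every root of its feedback polynomial
#' lies strictly inside the unit circle. FIR-type filters (feedback
#' polynomial of length 1) are unconditionally stable.
#'
#' @param filter A `lowpass_filter`.
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(filter) {
  a <- filter$a
  if (length(a) < 2) {
    return(TRUE)
  }
  ## roots of a[1] + a[2] z^-1 + ... == roots of reversed polynomial in z
  r <- polyroot(rev(a))
  all(Mod(r) < 1)
}

## ---- application -----------------------------------------------------------

## causal single pass (direct form)
lfilter <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x))
}

## one causal pass initialised as if the input had been constant at x[1]
## forever (past inputs x[1], past outputs x[1] * DC gain); together with
## the odd-reflection pad this suppresses the start-up transient -- the
## usual filtfilt initial-condition treatment
lfilter_ss <- function(b, a, x) {
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
    init.x = rep(x[1], length(b) - 1),
    init.y = rep(x[1] * g, length(a) - 1)
  ))
}

## odd-reflection pad: continues the signal anti-symmetrically about its
## endpoints so low-order trends cross the boundary without a step
odd_pad <- function(x, n) {
  n <- min(n, length(x) - 1)
  left <- 2 * x[1] - x[seq(n + 1, 2)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - n)]
  c(left, x, right)
}

## forward-backward (zero-phase) pass with odd-reflection padding of
## 3 x filter length, mirroring the usual filtfilt edge treatment
filtfilt_zp <- function(b, a, x) {
  pad <- 3 * max(length(b), length(a))
  if (length(x) <= pad) {
    abort("Trace too short for stable zero-phase edge handling.",
      class = "gazefilt_invalid_input"
    )
  }
  xp <- odd_pad(x, pad)
  y <- lfilter_ss(b, a, xp)
  y <- rev(lfilter_ss(b, a, rev(y)))
  y[seq(pad + 1, pad + length(x))]
}

## centred convolution for symmetric kernels (SG), odd-reflection edges
conv_centered <- function(k, x) {
  half <- (length(k) - 1) / 2
  xp <- odd_pad(x, half)
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[seq(half + 1, half + length(x))])
}

## dispatch on a plain numeric series
filter_series <- function(x, filter, mode = c("auto", "zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (isTRUE(filter$spec$zero_phase)) "zero_phase" else "single_pass"
  }
  sg <- identical(filter$spec$family, "savitzky_golay")
  if (mode == "zero_phase" && !sg) {
    filtfilt_zp(filter$b, filter$a, x)
  } else if (sg) {
    ## SG is a symmetric kernel: its single pass is already zero-phase
    conv_centered(filter$b, x)
  } else {
    lfilter(filter$b, filter$a, x)
  }
}

#' Apply a low-pass filter to a gaze trace
#'
#' Filters the gaze channels of a trace. In `zero_phase` mode the signal is
#' passed through the filter forwards, reversed, and passed through again:
#' this cancels phase shift and group delay and squares the magnitude
#' response (attenuation in dB doubles at every frequency). Edges are
#' handled by odd-reflection padding of three filter lengths. Savitzky-Golay
#' kernels are symmetric and are always applied as a single centred
#' convolution, which is already zero-phase.
#'
#' @param data A `gaze_trace` (or data frame with `x_dva` and optionally
#'   `y_dva`).
#' @param filter A `lowpass_filter`.
#' @param mode `"auto"` (follow the filter's `zero_phase` flag, the
#'   default), `"zero_phase"` or `"single_pass"`.
#' @return The trace with filtered gaze columns; length and time axis are
#'   unchanged.
#' @examples
#' tr <- simulate_fixation(fixation_model(duration_s = 1, seed = 1))
#' flt <- apply_filter(tr, design_butterworth_lowpass(7, 81, 1000))
#' @export
apply_filter <- function(data, filter, mode = c("auto", "zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  out <- data
  for (col in intersect(c("x_dva", "y_dva"), names(data))) {
    out[[col]] <- filter_series(as.numeric(data[[col]]), filter, mode)
  }
  out
}

## ---- coefficient I/O -------------------------------------------------------

#' Export and import filter coefficients
#'
#' Coefficients are stored as two-column whitespace-separated plain text
#' (`b`, `a`, padded with zeros to equal length, six decimal significant
#' digits) with a JSON sidecar `<path>.json` carrying the design spec so a
#' filter round-trips including its metadata.
#'
#' @param filter A `lowpass_filter`.
#' @param path Coefficient file path.
#' @return `read_filter()` returns a `lowpass_filter`; `write_filter()`
#'   returns `path` invisibly.
#' @export
write_filter <- function(filter, path) {
  n <- max(length(filter$b), length(filter$a))
  tab <- data.frame(
    b = signif(c(filter$b, rep(0, n - length(filter$b))), 6),
    a = signif(c(filter$a, rep(0, n - length(filter$a))), 6)
  )
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(filter$spec, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  spec <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- tab$a
  a <- a[seq_len(max(1, max(which(a != 0))))]
  new_lowpass_filter(tab$b, a, spec = spec)
}

## ---- tidiers ---------------------------------------------------------------

#' Tidy methods for designed filters
#'
#' `tidy()` returns one row per coefficient; `glance()` a one-row summary
#' of the design (family, order or taps, cutoff, DC gain, stability).
#'
#' @param x A `lowpass_filter`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lowpass_filter
#' @export
tidy.lowpass_filter <- function(x, ...) {
  n <- max(length(x$b), length(x$a))
  tibble(
    index = seq_len(n) - 1L,
    b = c(x$b, rep(0, n - length(x$b))),
    a = c(x$a, rep(0, n - length(x$a)))
  )
}

#' @rdname tidy.lowpass_filter
#' @method glance lowpass_filter
#' @export
glance.lowpass_filter <- function(x, ...) {
  s <- x$spec
  tibble(
    family = s$family,
    order = s$order %||% NA_integer_,
    num_taps = s$num_taps %||% NA_integer_,
    window_length = s$window_length %||% NA_integer_,
    cutoff_hz = s$cutoff_hz %||% NA_real_,
    fs_hz = s$fs_hz,
    zero_phase = isTRUE(s$zero_phase),
    dc_gain = sum(x$b) / sum(x$a),
    stable = is_stable(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
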