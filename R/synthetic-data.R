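#' Synthetic gaze models
#'
#' Parameter bundles for the seeded gaze simulator. The fixation model is a
#' minimal three-component description of a stationary-gaze recording from
#' a 1000 Hz video eye tracker:
#'
#' * **drift** -- a slow wandering of gaze (low-pass filtered Gaussian
#'   noise inside `drift_band_hz`), dominating the spectrum below ~30 Hz;
#' * **tremor** -- a small band-limited physiological component inside
#'   `tremor_band_hz`;
#' * **sensor noise** -- Gaussian noise whose spectrum is given a gentle
#'   high-frequency emphasis (`amplitude ~ floor + (f / Nyquist)^p` with
#'   `p = hf_rise_exponent`), so that the total amplitude spectrum of the
#'   trace is largest below 30 Hz, reaches its minimum near 150 Hz and
#'   rises again toward 500 Hz, the shape characteristic of unfiltered
#'   video-oculography fixation data.
#'
#' The saccade model describes a single rapid gaze shift with a smooth
#' raised-cosine displacement profile (bell-shaped velocity, peak
#' `2 * amplitude / duration`) plus additive white measurement noise, used
#' as the "noisy saccade" exemplar for velocity-noise metrics.
#'
#' Identical seeds give bit-identical traces.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Trace length (s).
#' @param drift_amp_dva RMS amplitude of the drift component (dva).
#' @param drift_band_hz Upper edge of the drift band (Hz).
#' @param tremor_band_hz Length-2 passband of the tremor component (Hz).
#' @param tremor_amp_dva RMS amplitude of the tremor component (dva).
#' @param hf_noise_sd_dva Standard deviation of the sensor-noise component
#'   (dva).
#' @param hf_rise_exponent Spectral slope exponent of the high-frequency
#'   emphasis.
#' @param amplitude_dva Signed saccade size (dva).
#' @param duration_ms Saccade duration (ms).
#' @param onset_s Saccade onset time (s).
#' @param noise_sd_dva SD of additive white noise on the saccade segment
#'   (dva); the default emulates a very noisy recording whose unfiltered
#'   instantaneous-velocity SD is of order 100 deg/s.
#' @param seed Integer RNG seed.
#' @return A list of class `fixation_model` / `saccade_model`.
#' @export
fixation_model <- function(fs_hz = 1000, duration_s = 30,
                           drift_amp_dva = 0.03, drift_band_hz = 8,
                           tremor_band_hz = c(40, 100), tremor_amp_dva = 0.006,
                           hf_noise_sd_dva = 0.014, hf_rise_exponent = 2,
                           seed = 1) {
  if (fs_hz <= 0 || duration_s <= 0) {
    abort("`fs_hz` and `duration_s` must be positive.", class = "gazefilt_invalid_parameter")
  }
  if (drift_amp_dva < 0 || tremor_amp_dva < 0 || hf_noise_sd_dva < 0) {
    abort("Amplitude parameters must be non-negative.", class = "gazefilt_invalid_parameter")
  }
  if (length(tremor_band_hz) != 2 || any(tremor_band_hz <= 0) ||
    tremor_band_hz[2] <= tremor_band_hz[1] || tremor_band_hz[2] >= fs_hz / 2) {
    abort("`tremor_band_hz` must be an increasing pair below Nyquist.",
      class = "gazefilt_invalid_parameter"
    )
  }
  structure(
    list(
      fs_hz = fs_hz, duration_s = duration_s,
      drift_amp_dva = drift_amp_dva, drift_band_hz = drift_band_hz,
      tremor_band_hz = tremor_band_hz, tremor_amp_dva = tremor_amp_dva,
      hf_noise_sd_dva = hf_noise_sd_dva, hf_rise_exponent = hf_rise_exponent,
      seed = seed
    ),
    class = "fixation_model"
  )
}

#' @rdname fixation_model
#' @export
saccade_model <- function(amplitude_dva = 1.25, duration_ms = 30,
                          onset_s = 0.2, noise_sd_dva = 0.08, seed = 1) {
  if (duration_ms <= 0) {
    abort("`duration_ms` must be positive.", class = "gazefilt_invalid_parameter")
  }
  if (noise_sd_dva < 0) {
    abort("`noise_sd_dva` must be non-negative.", class = "gazefilt_invalid_parameter")
  }
  structure(
    list(
      amplitude_dva = amplitude_dva, duration_ms = duration_ms,
      onset_s = onset_s, noise_sd_dva = noise_sd_dva, seed = seed
    ),
    class = "saccade_model"
  )
}

## rescale a component to a target RMS (no-op for zero target or flat input)
scale_rms <- function(x, target) {
  s <- stats::sd(x)
  if (target == 0 || s == 0) {
    return(x * 0)
  }
  x * target / s
}

#' Simulate a fixation trace
#'
#' Generates a seeded horizontal gaze trace from a [fixation_model()]. With
#' the default parameters the six-point velocity stays below the 25 deg/s
#' saccade screen for essentially all seeds, the averaged 256-sample
#' amplitude spectrum peaks below 30 Hz, dips to a minimum between 100 and
#' 200 Hz and rises again toward Nyquist.
#'
#' @param model A `fixation_model`.
#' @return A [gaze_trace()] of `round(fs_hz * duration_s)` samples.
#' @examples
#' tr <- simulate_fixation(fixation_model(duration_s = 2, seed = 42))
#' @export
simulate_fixation <- function(model) {
  stopifnot(inherits(model, "fixation_model"))
  fs <- model$fs_hz
  n <- round(fs * model$duration_s)
  comps <- withr::with_seed(model$seed, {
    list(drift = rnorm(n), tremor = rnorm(n), hf = rnorm(n))
  })

  drift <- if (model$drift_amp_dva > 0 && n > 30) {
    lp <- signal::butter(2, min(model$drift_band_hz, fs / 2 * 0.9) / (fs / 2), type = "low")
    scale_rms(filtfilt_zp(lp$b, lp$a, comps$drift), model$drift_amp_dva)
  } else {
    numeric(n)
  }

  tremor <- if (model$tremor_amp_dva > 0 && n > 30) {
    bp <- signal::butter(2, model$tremor_band_hz / (fs / 2), type = "pass")
    scale_rms(filtfilt_zp(bp$b, bp$a, comps$tremor), model$tremor_amp_dva)
  } else {
    numeric(n)
  }

  hf <- if (model$hf_noise_sd_dva > 0) {
    shape_highfreq(comps$hf, fs, model$hf_rise_exponent, model$hf_noise_sd_dva)
  } else {
    numeric(n)
  }

  gaze_trace(drift + tremor + hf, fs_hz = fs)
}

## FFT-domain emphasis: amplitude gain floor + (f/Nyquist)^p, then rescaled
## to the requested RMS; deterministic given the input noise
shape_highfreq <- function(z, fs, p, target_sd, floor = 0.1) {
  n <- length(z)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  g <- floor + (f / (fs / 2))^p
  x <- Re(fft(fft(z) * g, inverse = TRUE)) / n
  scale_rms(x, target_sd)
}

#' Simulate a saccade segment
#'
#' Generates a trace containing one saccade: the noiseless displacement
#' follows the raised-cosine sigmoid `s(u) = u - sin(2*pi*u) / (2*pi)`
#' (smooth, bell-shaped velocity, peak `2 * amplitude / duration`), scaled
#' to `amplitude_dva`, with seeded white Gaussian noise added on top. The
#' noiseless end-minus-start displacement equals the requested amplitude
#' exactly.
#'
#' @param model A `saccade_model`.
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Total segment length (s); the saccade must fit inside.
#' @return A [gaze_trace()].
#' @examples
#' tr <- simulate_saccade(saccade_model(amplitude_dva = 1.25), duration_s = 0.5)
#' @export
simulate_saccade <- function(model, fs_hz = 1000, duration_s = 0.5) {
  stopifnot(inherits(model, "saccade_model"))
  dur_s <- model$duration_ms / 1000
  if (model$onset_s < 0 || model$onset_s + dur_s > duration_s) {
    abort("The saccade must fit inside the segment (`onset_s` + duration <= `duration_s`).",
      class = "gazefilt_invalid_parameter"
    )
  }
  n <- round(fs_hz * duration_s)
  t <- (seq_len(n) - 1) / fs_hz
  u <- pmin(pmax((t - model$onset_s) / dur_s, 0), 1)
  x <- model$amplitude_dva * (u - sin(2 * pi * u) / (2 * pi))
  noise <- if (model$noise_sd_dva > 0) {
    withr::with_seed(model$seed, rnorm(n, 0, model$noise_sd_dva))
  } else {
    numeric(n)
  }
  gaze_trace(x + noise, fs_hz = fs_hz)
}
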