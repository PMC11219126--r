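#' Quadratic detrending of a block
#'
#' Subtracts the least-squares 2nd-order polynomial (in sample index) from
#' a block, removing offset, linear drift and slow curvature before
#' spectral analysis. Residuals have mean zero by construction.
#'
#' @param x Numeric block (length >= 3).
#' @return Residual block of the same length.
#' @export
detrend_poly2 <- function(x) {
  n <- length(x)
  if (n < 3) {
    abort("Quadratic detrending needs at least 3 samples.", class = "gazefilt_invalid_input")
  }
  t <- seq_len(n)
  as.numeric(x - stats::fitted(stats::lm(x ~ t + I(t^2))))
}

## periodic Hann window (the FFT-averaging convention)
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Amplitude spectrum of a single block
#'
#' Detrends the block with a 2nd-order polynomial, applies a periodic Hann
#' ("Hanning") window, takes the FFT and returns the magnitudes at the
#' `n/2` non-negative-frequency bins below Nyquist, scaled by
#' `2 / sum(window)` so a unit-amplitude sinusoid centred on a bin reports
#' magnitude ~ 1 (interpretable in dva).
#'
#' @param x Numeric block whose length is a power of two (256 in the
#'   reference pipeline, giving a 3.906 Hz grid at 1000 Hz).
#' @param fs_hz Sampling rate in Hz.
#' @param detrend Apply the quadratic detrend first (default `TRUE`).
#' @return A tibble with columns `freq_hz` and `magnitude`.
#' @examples
#' blk <- sin(2 * pi * 39.0625 * (0:255) / 1000)
#' sp <- block_amplitude_spectrum(blk, 1000)
#' sp$freq_hz[which.max(sp$magnitude)] # 39.06 Hz
#' @export
block_amplitude_spectrum <- function(x, fs_hz = 1000, detrend = TRUE) {
  n <- length(x)
  if (n < 8 || bitwAnd(n, n - 1L) != 0) {
    abort("Block length must be a power of two (>= 8).", class = "gazefilt_invalid_parameter")
  }
  if (detrend) x <- detrend_poly2(x)
  w <- hann_periodic(n)
  co <- fft(x * w)[seq_len(n / 2)]
  tibble(
    freq_hz = (seq_len(n / 2) - 1) * fs_hz / n,
    magnitude = Mod(co) * 2 / sum(w)
  )
}

#' Average amplitude spectra across blocks
#'
#' Computes the per-block amplitude spectrum (quadratic detrend + Hanning
#' window + FFT magnitude) for every column of a block matrix and averages
#' the magnitudes bin-wise. Magnitudes -- never complex FFT values -- are
#' averaged, so components with random phase across blocks do not cancel.
#'
#' @param blocks Numeric matrix, one column per block (rows = samples), or
#'   a single numeric block.
#' @param fs_hz Sampling rate in Hz.
#' @param detrend Apply the per-block quadratic detrend (default `TRUE`).
#' @param keep_complex Also retain the complex FFT coefficients (needed by
#'   [response_by_ratio()]'s `"complex"` mode).
#' @return A `spectrum_set`: list with the 128-point (for 256-sample
#'   blocks) grid `freq_hz`, the per-block magnitude matrix `magnitudes`,
#'   their bin-wise `mean_magnitude`, `n_blocks`, `block_len` and `fs_hz`.
#' @export
average_spectra <- function(blocks, fs_hz = 1000, detrend = TRUE, keep_complex = FALSE) {
  if (is.numeric(blocks) && is.null(dim(blocks))) {
    blocks <- matrix(blocks, ncol = 1)
  }
  if (!is.matrix(blocks) || ncol(blocks) < 1) {
    abort("`blocks` must be a matrix with at least one column.",
      class = "gazefilt_invalid_input"
    )
  }
  n <- nrow(blocks)
  if (n < 8 || bitwAnd(n, n - 1L) != 0) {
    abort("Block length must be a power of two (>= 8).", class = "gazefilt_invalid_parameter")
  }
  if (detrend) {
    t <- seq_len(n)
    basis <- cbind(1, t, t^2)
    proj <- basis %*% solve(crossprod(basis), t(basis))
    blocks <- blocks - proj %*% blocks
  }
  w <- hann_periodic(n)
  co <- stats::mvfft(blocks * w)[seq_len(n / 2), , drop = FALSE]
  mags <- Mod(co) * 2 / sum(w)
  structure(
    list(
      freq_hz = (seq_len(n / 2) - 1) * fs_hz / n,
      magnitudes = mags,
      mean_magnitude = rowMeans(mags),
      coef = if (keep_complex) co else NULL,
      n_blocks = ncol(blocks),
      block_len = n,
      fs_hz = fs_hz
    ),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<spectrum_set> %d blocks of %d samples | fs = %g Hz | resolution %.3f Hz | %d bins\n",
    x$n_blocks, x$block_len, x$fs_hz, x$fs_hz / x$block_len, length(x$freq_hz)
  ))
  invisible(x)
}

#' Tidy methods for spectrum sets
#'
#' `tidy()` returns the long per-block spectra plus the cross-block mean
#' (block `"mean"`); `glance()` a one-row summary including the grid
#' resolution and the number of discriminable frequencies.
#'
#' @param x A `spectrum_set`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spectrum_set
#' @export
tidy.spectrum_set <- function(x, ...) {
  long <- tibble(
    freq_hz = rep(x$freq_hz, times = x$n_blocks),
    block = rep(seq_len(x$n_blocks), each = length(x$freq_hz)),
    magnitude = as.vector(x$magnitudes)
  )
  dplyr::bind_rows(
    dplyr::mutate(long, block = as.character(.data$block)),
    tibble(freq_hz = x$freq_hz, block = "mean", magnitude = x$mean_magnitude)
  )
}

#' @rdname tidy.spectrum_set
#' @method glance spectrum_set
#' @export
glance.spectrum_set <- function(x, ...) {
  tibble(
    n_blocks = x$n_blocks,
    block_len = x$block_len,
    fs_hz = x$fs_hz,
    resolution_hz = x$fs_hz / x$block_len,
    n_bins = length(x$freq_hz)
  )
}

#' Plot the averaged amplitude spectrum
#'
#' @param object A `spectrum_set`.
#' @param ... Further `spectrum_set`s to overlay, named.
#' @return A ggplot on a log10 magnitude scale (DC bin dropped).
#' @method autoplot spectrum_set
#' @export
autoplot.spectrum_set <- function(object, ...) {
  sets <- c(list(unfiltered = object), list(...))
  dat <- purrr::imap_dfr(sets, function(s, nm) {
    tibble(curve = nm, freq_hz = s$freq_hz, magnitude = s$mean_magnitude)
  })
  dat <- dplyr::filter(dat, .data$freq_hz > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq_hz, .data$magnitude, colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Mean amplitude (dva)", colour = NULL)
}
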