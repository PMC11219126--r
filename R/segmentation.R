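#' Six-point central-difference velocity
#'
#' The saccade-screening velocity estimate: `v[t] = (x[t+3] - x[t-3]) /
#' (6 / fs)` in deg/s. The three samples at each edge have no defined
#' velocity and are returned as `NA`. The 6-sample span makes the estimate
#' exact for linear signals and robust to single-sample noise, at the cost
#' of attenuating frequencies near Nyquist.
#'
#' @param data A `gaze_trace`.
#' @param col Gaze column to differentiate (default `"x_dva"`).
#' @return The input tibble with an added `v_dps` column.
#' @examples
#' tr <- gaze_trace(2 * (0:99) / 1000, fs_hz = 1000) # 2 dva/s ramp
#' sixpoint_velocity(tr)$v_dps[10] # 2
#' @export
sixpoint_velocity <- function(data, col = "x_dva") {
  x <- trace_signal(data, col)
  fs <- gaze_fs(data)
  n <- length(x)
  if (n < 7) {
    abort("Six-point velocity needs at least 7 samples.", class = "gazefilt_invalid_input")
  }
  v <- rep(NA_real_, n)
  idx <- 4:(n - 3)
  v[idx] <- (x[idx + 3] - x[idx - 3]) / (6 / fs)
  out <- data
  out$v_dps <- v
  out
}

sixpoint_velocity_series <- function(x, fs) {
  sixpoint_velocity(gaze_trace(x, fs_hz = fs))$v_dps
}

#' Select clean fixation segments by a velocity screen
#'
#' Finds the maximum number of non-overlapping `seg_len`-sample windows in
#' which every defined six-point velocity sample stays at or below
#' `vmax_dps` in absolute value (the saccade/artefact screen). The search
#' is a left-to-right greedy scan -- advance one sample on a violation,
#' jump a full segment on acceptance -- which is optimal for
#' identical-length windows. An empty result is valid: noisy recordings
#' may contain no admissible segment.
#'
#' @param data A `gaze_trace`.
#' @param seg_len Segment length in samples (2048 in the reference
#'   pipeline).
#' @param vmax_dps Velocity threshold in deg/s (25 in the reference
#'   pipeline).
#' @param channel `"x"` screens the horizontal channel only (the default);
#'   `"both"` screens the vector magnitude of horizontal and vertical
#'   velocity (requires a `y_dva` column).
#' @return A tibble of class `segment_set` with columns `segment` and
#'   `start` (1-based sample index), and attributes `seg_len`, `vmax_dps`
#'   and `fs_hz`.
#' @export
find_clean_segments <- function(data, seg_len = 2048, vmax_dps = 25,
                                channel = c("x", "both")) {
  channel <- match.arg(channel)
  fs <- gaze_fs(data)
  vx <- sixpoint_velocity_series(trace_signal(data, "x_dva"), fs)
  speed <- if (channel == "both") {
    vy <- sixpoint_velocity_series(trace_signal(data, "y_dva"), fs)
    sqrt(vx^2 + vy^2)
  } else {
    abs(vx)
  }
  ok <- is.na(speed) | speed <= vmax_dps # undefined edge samples don't reject
  seg_len <- as.integer(seg_len)
  n <- length(ok)
  ## prefix sums let each window be tested in O(1)
  bad <- cumsum(!ok)
  starts <- integer(0)
  i <- 1L
  while (i + seg_len - 1L <= n) {
    if (bad[i + seg_len - 1L] - (if (i > 1L) bad[i - 1L] else 0L) == 0L) {
      starts <- c(starts, i)
      i <- i + seg_len
    } else {
      i <- i + 1L
    }
  }
  out <- new_tibble(
    list(segment = seq_along(starts), start = starts),
    nrow = length(starts), class = "segment_set"
  )
  attr(out, "seg_len") <- seg_len
  attr(out, "vmax_dps") <- vmax_dps
  attr(out, "fs_hz") <- fs
  out
}

#' Split a segment into contiguous blocks
#'
#' Partitions a segment into `seg_len / block_len` contiguous,
#' non-overlapping, order-preserving blocks (eight 256-sample blocks per
#' 2048-sample segment in the reference pipeline). Concatenating the
#' columns of the result restores the input.
#'
#' @param x Numeric segment whose length is divisible by `block_len`.
#' @param block_len Block length in samples.
#' @return A matrix with `block_len` rows, one column per block.
#' @export
split_blocks <- function(x, block_len = 256) {
  if (length(x) %% block_len != 0) {
    abort("Segment length must be divisible by `block_len`.",
      class = "gazefilt_invalid_parameter"
    )
  }
  matrix(x, nrow = block_len)
}

#' Extract analysis blocks from a trace
#'
#' Cuts the accepted segments of a [find_clean_segments()] result out of a
#' trace and splits each into `block_len`-sample blocks, yielding the block
#' matrix consumed by [average_spectra()] and the autocorrelation analysis
#' (27 segments of 2048 samples become 216 blocks of 256).
#'
#' @param data The `gaze_trace` the segments were found in (or a filtered
#'   copy of it with identical length).
#' @param segments A `segment_set`.
#' @param block_len Block length in samples.
#' @param col Gaze column to extract.
#' @return A numeric matrix, one column per block.
#' @export
extract_blocks <- function(data, segments, block_len = 256, col = "x_dva") {
  x <- trace_signal(data, col)
  seg_len <- attr(segments, "seg_len")
  if (nrow(segments) == 0) {
    abort("No accepted segments to extract.", class = "gazefilt_invalid_input")
  }
  mats <- lapply(segments$start, function(s) {
    split_blocks(x[seq(s, s + seg_len - 1)], block_len)
  })
  do.call(cbind, mats)
}
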