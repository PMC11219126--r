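#' Build a gaze trace
#'
#' A gaze trace is the universal signal container of the package: a tibble
#' with one row per sample, a uniform time column `t_s` (seconds), a
#' horizontal gaze column `x_dva` (degrees of visual angle) and optionally a
#' vertical column `y_dva`. The sampling rate is carried as the `fs_hz`
#' attribute so traces can be piped through the filtering and analysis verbs
#' without repeating it.
#'
#' @param x Numeric vector of horizontal gaze positions (dva).
#' @param y Optional numeric vector of vertical gaze positions (dva); must
#'   have the same length as `x`.
#' @param fs_hz Sampling rate in Hz (samples are `1/fs_hz` seconds apart).
#' @param t0 Time of the first sample in seconds.
#'
#' @return A tibble of class `gaze_trace` with columns `t_s`, `x_dva` and
#'   (if `y` is given) `y_dva`, and attribute `fs_hz`.
#' @examples
#' tr <- gaze_trace(sin(2 * pi * 5 * (0:999) / 1000), fs_hz = 1000)
#' gaze_fs(tr)
#' @export
gaze_trace <- function(x, y = NULL, fs_hz = 1000, t0 = 0) {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.", class = "gazefilt_invalid_parameter")
  }
  x <- as.numeric(x)
  if (length(x) < 1L) {
    abort("A gaze trace needs at least one sample.", class = "gazefilt_invalid_input")
  }
  cols <- list(t_s = t0 + (seq_along(x) - 1) / fs_hz, x_dva = x)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != length(x)) {
      abort("`x` and `y` must have the same length.", class = "gazefilt_invalid_input")
    }
    cols$y_dva <- y
  }
  out <- new_tibble(cols, nrow = length(x), class = "gaze_trace")
  attr(out, "fs_hz") <- fs_hz
  out
}

#' Sampling rate of a gaze trace
#'
#' Returns the `fs_hz` attribute when present, otherwise infers the rate
#' from the median spacing of the `t_s` column (useful for traces read back
#' from CSV by other tools).
#'
#' @param data A `gaze_trace` or any data frame with a `t_s` column.
#' @return Sampling rate in Hz.
#' @export
gaze_fs <- function(data) {
  fs <- attr(data, "fs_hz")
  if (!is.null(fs)) {
    return(fs)
  }
  if (!"t_s" %in% names(data) || nrow(data) < 2L) {
    abort("Cannot infer a sampling rate: no `fs_hz` attribute and no usable `t_s` column.",
      class = "gazefilt_invalid_input"
    )
  }
  1 / median(diff(data$t_s))
}

## internal: pull the signal column and fs, with checks shared by the verbs
trace_signal <- function(data, col = "x_dva") {
  if (!col %in% names(data)) {
    abort(sprintf("Column `%s` not found in the trace.", col), class = "gazefilt_invalid_input")
  }
  as.numeric(data[[col]])
}

#' Read and write gaze traces as CSV
#'
#' The on-disk dialect is plain CSV with header `t_s,x_dva` or
#' `t_s,x_dva,y_dva`, one row per sample -- the single supported exchange
#' format of the package. `read_gaze_csv()` restores the `gaze_trace` class
#' and sampling-rate attribute; a column mapping can be supplied for foreign
#' exports whose headers differ.
#'
#' @param data A `gaze_trace`.
#' @param path File path.
#' @param col_map Named character vector mapping the standard names to the
#'   file's names, e.g. `c(t_s = "time", x_dva = "gx")`.
#' @return `read_gaze_csv()` returns a `gaze_trace`; `write_gaze_csv()`
#'   returns `path` invisibly.
#' @export
write_gaze_csv <- function(data, path) {
  keep <- intersect(c("t_s", "x_dva", "y_dva"), names(data))
  readr::write_csv(as_tibble(data)[keep], path)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  if (!all(c("t_s", "x_dva") %in% names(raw))) {
    abort("Gaze CSV must provide `t_s` and `x_dva` columns (or a `col_map` to them).",
      class = "gazefilt_invalid_input"
    )
  }
  fs <- 1 / median(diff(raw$t_s))
  gaze_trace(raw$x_dva,
    y = if ("y_dva" %in% names(raw)) raw$y_dva else NULL,
    fs_hz = round(fs, 6), t0 = raw$t_s[1]
  )
}
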