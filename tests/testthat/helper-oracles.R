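# Independent oracles used across the suite. Each is deliberately naive
# (normal equations, dense grids, exhaustive search) and shares no code with
# the implementation paths it checks.

# least-squares amplitude/phase of a sinusoid at a known frequency,
# measured over an interior window to avoid edge transients
fit_sine_amplitude <- function(x, f, fs, trim = 500) {
  n <- length(x)
  idx <- seq(trim + 1, n - trim)
  t <- (idx - 1) / fs
  basis <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  cf <- solve(crossprod(basis), crossprod(basis, x[idx]))
  sqrt(sum(cf^2))
}

# transfer-function magnitude at one frequency by brute polynomial sums
tf_mag_naive <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- sum(b * z^(seq_along(b) - 1))
  den <- sum(a * z^(seq_along(a) - 1))
  Mod(num / den)
}

# Savitzky-Golay kernel from explicit normal equations: weights of the
# centre fitted value as a linear function of the window samples
savgol_kernel_naive <- function(window, order) {
  half <- (window - 1) / 2
  t <- seq(-half, half)
  basis <- outer(t, 0:order, `^`)
  proj <- basis %*% solve(crossprod(basis), t(basis))
  proj[half + 1, ]
}

# quadratic detrend by explicit normal equations
detrend2_naive <- function(x) {
  t <- seq_along(x)
  basis <- cbind(1, t, t^2)
  as.numeric(x - basis %*% solve(crossprod(basis), crossprod(basis, x)))
}

# maximum number of non-overlapping clean windows by dynamic programming
# (exhaustive over placements; for short traces only)
max_segments_naive <- function(ok, seg_len) {
  n <- length(ok)
  clean <- vapply(seq_len(max(0, n - seg_len + 1)), function(i) {
    all(ok[seq(i, i + seg_len - 1)])
  }, logical(1))
  best <- integer(n + 1) # best[i+1] = max count using samples >= i
  for (i in seq(n, 1)) {
    take <- if (i <= length(clean) && clean[i]) {
      1L + best[min(i + seg_len, n + 1)]
    } else {
      0L
    }
    best[i] <- max(best[i + 1], take)
  }
  best[1]
}

# tie-corrected Friedman chi-square from first principles
friedman_stat_naive <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  colsum <- colSums(ranks)
  num <- (12 * sum((colsum - n * (k + 1) / 2)^2))
  ties <- sum(apply(mat, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  den <- n * k * (k + 1) - ties / (k - 1)
  num / den
}

# pooled synthetic fixation blocks used by several analysis tests
fixation_blocks <- function(seeds = 1:2, n_blocks = NULL) {
  blocks <- do.call(cbind, lapply(seeds, function(s) {
    tr <- simulate_fixation(fixation_model(seed = s))
    extract_blocks(tr, find_clean_segments(tr))
  }))
  if (!is.null(n_blocks)) blocks <- blocks[, seq_len(n_blocks)]
  blocks
}

# zero-phase application of a filter to a bare numeric series via the
# public trace interface
filter_zero_phase_for_test <- function(filter, x) {
  apply_filter(gaze_trace(x, fs_hz = filter$spec$fs_hz), filter, mode = "zero_phase")$x_dva
}
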