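#' Sample autocorrelations of a block
#'
#' Biased-normalisation sample autocorrelation of a mean-removed block at
#' lags 1..`n_lags` (the lag-0 value is identically 1 and is not
#' returned). The biased convention (divide by `n`) guarantees `|r| <= 1`.
#'
#' @param x Numeric block (length > `n_lags` + 2).
#' @param n_lags Number of lags (default 5).
#' @return Numeric vector `r[1..n_lags]`.
#' @examples
#' acf_lags(as.numeric(arima.sim(list(ar = 0.6), 1000)), 2)
#' @export
acf_lags <- function(x, n_lags = 5) {
  n <- length(x)
  if (n <= n_lags + 2) {
    abort("Block too short for the requested number of lags.",
      class = "gazefilt_invalid_input"
    )
  }
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom < 1e-300 || stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    abort("Autocorrelation undefined for a (near-)constant block.",
      class = "gazefilt_undefined_acf"
    )
  }
  vapply(seq_len(n_lags), function(k) {
    sum(x[seq_len(n - k)] * x[seq(k + 1, n)]) / denom
  }, numeric(1))
}

#' Fisher-Z transformation
#'
#' `fisher_z()` maps a correlation to `atanh(r) = 0.5 * log((1 + r) /
#' (1 - r))`, rendering it approximately normal for testing;
#' `inverse_fisher_z()` maps back with `tanh`.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @param z Fisher-Z value(s).
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    abort("`r` must lie strictly inside (-1, 1).", class = "gazefilt_domain_error")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Significance of a lag-1 autocorrelation
#'
#' Two-sided normal test of `r1 = 0` using the Fisher-Z statistic
#' `z * sqrt(n - 3)`, the test consistent with the Fisher-Z scale used for
#' all other autocorrelation statistics in the package.
#'
#' @param r1 Lag-1 autocorrelation.
#' @param n Block length in samples (> 3).
#' @return Two-sided p-value.
#' @examples
#' lag1_significance(0.579, 256) # far below 1e-4
#' @export
lag1_significance <- function(r1, n) {
  if (n <= 3) {
    abort("`n` must exceed 3.", class = "gazefilt_invalid_parameter")
  }
  2 * pnorm(-abs(fisher_z(r1)) * sqrt(n - 3))
}

#' Per-block, per-condition autocorrelation table
#'
#' Applies each filter of `filters` to every block, computes lag-1..`n_lags`
#' autocorrelations of the unfiltered and each filtered version, and
#' returns the long table that the Friedman analysis consumes. Condition
#' `"unfiltered"` is always included first.
#'
#' @param blocks Numeric matrix, one column per block.
#' @param filters Named list of `lowpass_filter` objects (the names become
#'   condition labels).
#' @param fs_hz Sampling rate (Hz); only used to filter the blocks.
#' @param n_lags Number of lags (default 5).
#' @return A tibble of class `acf_table` with columns `block`, `condition`
#'   (factor, conditions in order), `lag`, `r`, `z`, and attributes
#'   `n_blocks` and `block_len`.
#' @export
acf_conditions <- function(blocks, filters, fs_hz = 1000, n_lags = 5) {
  stopifnot(is.matrix(blocks))
  conds <- c("unfiltered", names(filters))
  versions <- c(
    list(unfiltered = blocks),
    purrr::map(filters, function(f) {
      apply(blocks, 2, function(col) filter_series(col, f, mode = "auto"))
    })
  )
  rows <- purrr::imap_dfr(versions, function(mat, cond) {
    purrr::map_dfr(seq_len(ncol(mat)), function(j) {
      r <- acf_lags(mat[, j], n_lags)
      tibble(block = j, condition = cond, lag = seq_len(n_lags), r = r)
    })
  })
  rows$condition <- factor(rows$condition, levels = conds)
  rows$z <- fisher_z(rows$r)
  out <- new_tibble(as.list(rows), nrow = nrow(rows), class = "acf_table")
  attr(out, "n_blocks") <- ncol(blocks)
  attr(out, "block_len") <- nrow(blocks)
  out
}

#' Friedman test across filter conditions
#'
#' Nonparametric repeated-measures comparison of the Fisher-Z transformed
#' autocorrelations at one lag: blocks are the repeated measure, filter
#' conditions the treatments. The (tie-corrected, average-rank) Friedman
#' chi-square is followed by Tukey-style pairwise comparisons on the
#' within-block mean ranks: for each of the `choose(k, 2)` condition
#' pairs the standardised mean-rank difference is referred to the
#' studentized-range distribution (`q = sqrt(2) * |d| / SE`,
#' `SE = sqrt(k (k + 1) / (6 n))`, `p_adj = P(Q_{k, Inf} > q)`), the
#' multiple-comparison route conventionally applied after a significant
#' Friedman test. The pairwise table also reports the difference of
#' condition mean Fisher-Z values, since the rank difference alone has no
#' physical unit.
#'
#' @param acf_tbl An [acf_conditions()] table.
#' @param lag Which lag to test.
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return An object of class `friedman_ranks`: list with `lag`,
#'   `statistic` (chi-square), `df`, `p_value`, `n_blocks`,
#'   `mean_ranks` (tibble) and `pairwise` (tibble with one row per
#'   unordered condition pair).
#' @export
friedman_conditions <- function(acf_tbl, lag = 1, alpha = 0.05) {
  sub <- acf_tbl[acf_tbl$lag == lag, c("block", "condition", "z")]
  wide <- tidyr::pivot_wider(sub, names_from = "condition", values_from = "z")
  mat <- as.matrix(wide[, -1])
  if (any(is.na(mat)) || ncol(mat) < 2 || nrow(mat) < 2) {
    abort("Friedman test needs a complete table with >= 2 conditions and >= 2 blocks.",
      class = "gazefilt_invalid_input"
    )
  }
  k <- ncol(mat)
  n <- nrow(mat)
  ft <- friedman.test(mat)
  if (is.nan(ft$statistic)) {
    # fully tied table: the tie-corrected statistic degenerates to 0/0;
    # by continuity there is no effect at all
    ft$statistic <- 0
    ft$p.value <- 1
  }
  ranks <- t(apply(mat, 1, rank)) # average ranks on ties
  rbar <- colMeans(ranks)
  pairs <- utils::combn(colnames(mat), 2)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    d <- rbar[[a]] - rbar[[b]]
    q <- sqrt(2) * abs(d) / se
    tibble(
      condition_a = a, condition_b = b,
      rank_diff = d,
      z_diff = mean(mat[, a]) - mean(mat[, b]),
      q = q,
      p_adj = ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    )
  })
  pairwise$significant <- pairwise$p_adj < alpha
  structure(
    list(
      lag = lag,
      statistic = unname(ft$statistic),
      df = unname(ft$parameter),
      p_value = ft$p.value,
      n_blocks = n,
      mean_ranks = tibble(condition = colnames(mat), mean_rank = unname(rbar)),
      pairwise = pairwise,
      alpha = alpha
    ),
    class = "friedman_ranks"
  )
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat(sprintf(
    "Friedman test on Fisher-Z autocorrelations, lag %d: chi2(%d) = %.2f, p = %.3g (n = %d blocks)\n",
    x$lag, x$df, x$statistic, x$p_value, x$n_blocks
  ))
  print(x$pairwise)
  invisible(x)
}

#' Tidy methods for Friedman results
#'
#' `tidy()` returns the pairwise comparison table; `glance()` the omnibus
#' test as one row.
#'
#' @param x A `friedman_ranks` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy friedman_ranks
#' @export
tidy.friedman_ranks <- function(x, ...) {
  dplyr::mutate(x$pairwise, lag = x$lag, .before = 1)
}

#' @rdname tidy.friedman_ranks
#' @method glance friedman_ranks
#' @export
glance.friedman_ranks <- function(x, ...) {
  tibble(
    lag = x$lag, statistic = x$statistic, df = x$df,
    p_value = x$p_value, n_blocks = x$n_blocks
  )
}

#' Boxplots of Fisher-Z autocorrelations by condition
#'
#' @param object An `acf_table`.
#' @param lags Which lags to show.
#' @param ... Unused.
#' @return A ggplot, one panel per lag.
#' @method autoplot acf_table
#' @export
autoplot.acf_table <- function(object, lags = unique(object$lag), ...) {
  dat <- dplyr::filter(as_tibble(object), .data$lag %in% lags)
  ggplot2::ggplot(dat, ggplot2::aes(.data$condition, .data$z)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~lag, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Fisher-Z autocorrelation")
}
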