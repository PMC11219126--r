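#' Instantaneous (sample-to-sample) velocity
#'
#' `v[t] = (x[t] - x[t-1]) * fs`, the noisiest common velocity estimate and
#' therefore the most sensitive probe of filtering: white positional noise
#' of SD `sigma` dva at 1000 Hz produces a velocity SD of about
#' `sigma * 1000 * sqrt(2)` deg/s.
#'
#' @param data A `gaze_trace` (length >= 2).
#' @param col Gaze column to differentiate.
#' @return A tibble with columns `t_s` (time of the later sample) and
#'   `v_dps`, one row per sample pair.
#' @export
instantaneous_velocity <- function(data, col = "x_dva") {
  x <- trace_signal(data, col)
  if (length(x) < 2) {
    abort("Instantaneous velocity needs at least 2 samples.", class = "gazefilt_invalid_input")
  }
  fs <- gaze_fs(data)
  tibble(t_s = data$t_s[-1], v_dps = diff(x) * fs)
}

#' Velocity-noise metrics
#'
#' Summarises a velocity series with the three precision-style metrics
#' used to compare filters on the noisy-saccade exemplar:
#'
#' * `sd_dps` -- standard deviation of the velocity series;
#' * `rms_signal_dps` -- root-mean-square of the series itself (equals the
#'   SD when the mean velocity is zero, exceeds it otherwise);
#' * `rms_s2s_dps` -- root-mean-square of the sample-to-sample velocity
#'   differences, the standard eye-tracking precision metric. Unlike the
#'   signal RMS this can fall below the SD for smooth (autocorrelated)
#'   series, which is why both variants are reported.
#'
#' @param v Numeric velocity series (deg/s) or the tibble returned by
#'   [instantaneous_velocity()].
#' @return A one-row tibble with the three metrics.
#' @examples
#' velocity_metrics(c(1, -1, 1, -1, 1, -1)) # sd ~ 1, rms ~ 1, rms_s2s ~ 2
#' @export
velocity_metrics <- function(v) {
  if (is.data.frame(v)) v <- v$v_dps
  v <- as.numeric(v)
  if (length(v) < 2) {
    abort("Velocity metrics need at least 2 samples.", class = "gazefilt_invalid_input")
  }
  tibble(
    sd_dps = stats::sd(v),
    rms_signal_dps = sqrt(mean(v^2)),
    rms_s2s_dps = sqrt(mean(diff(v)^2))
  )
}

#' Study configuration
#'
#' Bundles every tunable of the end-to-end pipeline with defaults equal to
#' the reference analysis: the three-filter bank, 2048-sample segments cut
#' into 256-sample blocks, a 25 deg/s velocity screen, ACF to lag 5 and
#' crossing levels -3 / -30 / -40 dB on synthetic 30 s fixation traces at
#' 1000 Hz.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param filters Named list of `lowpass_filter`s.
#' @param seg_len,block_len Segment and block lengths in samples.
#' @param vmax_dps Velocity screen (deg/s).
#' @param acf_lags Number of ACF lags.
#' @param crossing_levels_db Crossing levels (dB).
#' @param n_traces Number of synthetic fixation traces to pool.
#' @param trace_duration_s Length of each synthetic trace (s).
#' @param seed Master RNG seed (each trace uses `seed + trace index`).
#' @param input_csv Optional character vector of gaze CSV paths; when
#'   given, recordings are loaded instead of simulated.
#' @return A list of class `study_config`.
#' @export
study_config <- function(fs_hz = 1000, filters = table1_filters(fs_hz),
                         seg_len = 2048, block_len = 256, vmax_dps = 25,
                         acf_lags = 5, crossing_levels_db = c(-3, -30, -40),
                         n_traces = 2, trace_duration_s = 30,
                         seed = 1, input_csv = NULL) {
  if (seg_len %% block_len != 0) {
    abort("`seg_len` must be divisible by `block_len`.", class = "gazefilt_invalid_parameter")
  }
  structure(
    list(
      fs_hz = fs_hz, filters = filters, seg_len = seg_len,
      block_len = block_len, vmax_dps = vmax_dps, acf_lags = acf_lags,
      crossing_levels_db = crossing_levels_db, n_traces = n_traces,
      trace_duration_s = trace_duration_s, seed = seed, input_csv = input_csv
    ),
    class = "study_config"
  )
}

#' Run the full filter-comparison study
#'
#' Orchestrates the pipeline end to end: load or simulate gaze traces,
#' design and export the filter bank, compute direct and ratio-method
#' frequency responses and their level crossings, select clean fixation
#' segments, build averaged amplitude spectra before and after each
#' filter, run the autocorrelation / Friedman analysis, and score the
#' noisy-saccade velocity exemplar. All numeric outputs are written as CSV
#' under `out_dir` together with a JSON manifest of the configuration;
#' identical configurations and seeds give byte-identical CSVs. Any stage
#' failure removes the partial outputs and aborts with a stage-labelled
#' error.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main result objects (`crossings`,
#'   `acf_table`, `friedman`, `velocity`, `spectra`, paths).
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("gazefilt_study_")) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  note <- function(path) {
    created <<- c(created, path)
    path
  }
  stage <- "setup"
  result <- tryCatch(
    {
      fs <- config$fs_hz
      filters <- config$filters

      stage <- "design"
      for (nm in names(filters)) {
        write_filter(filters[[nm]], note(file.path(out_dir, paste0("filter_", nm, ".txt"))))
        note(file.path(out_dir, paste0("filter_", nm, ".txt.json")))
        if (!is_stable(filters[[nm]])) {
          abort(sprintf("Filter `%s` failed the unit-circle stability test.", nm))
        }
      }

      stage <- "response"
      direct <- purrr::map(filters, response_direct)
      ratio <- purrr::imap(filters, function(f, nm) {
        measured_response(f, n_blocks = 400, block_len = config$block_len,
          seed = config$seed + match(nm, names(filters))
        )
      })
      for (nm in names(filters)) {
        readr::write_csv(as_tibble(direct[[nm]]),
          note(file.path(out_dir, paste0("response_direct_", nm, ".csv")))
        )
        readr::write_csv(as_tibble(ratio[[nm]]),
          note(file.path(out_dir, paste0("response_ratio_", nm, ".csv")))
        )
      }
      crossings <- dplyr::full_join(
        dplyr::rename(crossing_table(direct, config$crossing_levels_db),
          direct_hz = "freq_hz", direct_last_hz = "last_exceedance_hz"
        ),
        dplyr::select(
          dplyr::rename(crossing_table(ratio, config$crossing_levels_db),
            ratio_hz = "freq_hz"
          ),
          "filter", "level_db", "ratio_hz"
        ),
        by = c("filter", "level_db")
      )
      readr::write_csv(crossings, note(file.path(out_dir, "crossings.csv")))

      stage <- "traces"
      traces <- if (!is.null(config$input_csv)) {
        purrr::map(config$input_csv, read_gaze_csv)
      } else {
        purrr::map(seq_len(config$n_traces), function(i) {
          simulate_fixation(fixation_model(
            fs_hz = fs, duration_s = config$trace_duration_s,
            seed = config$seed + i
          ))
        })
      }

      stage <- "segmentation"
      blocks <- do.call(cbind, purrr::map(traces, function(tr) {
        segs <- find_clean_segments(tr, config$seg_len, config$vmax_dps)
        if (nrow(segs) == 0) {
          return(NULL)
        }
        extract_blocks(tr, segs, config$block_len)
      }))
      if (is.null(blocks)) {
        abort("No clean segments found in any trace.")
      }

      stage <- "spectra"
      spectra <- c(
        list(unfiltered = average_spectra(blocks, fs)),
        purrr::map(filters, function(f) {
          average_spectra(
            apply(blocks, 2, function(col) filter_series(col, f, mode = "auto")), fs
          )
        })
      )
      spec_tab <- purrr::imap_dfr(spectra, function(s, nm) {
        tibble(condition = nm, freq_hz = s$freq_hz, mean_magnitude = s$mean_magnitude)
      })
      readr::write_csv(spec_tab, note(file.path(out_dir, "spectra_mean.csv")))

      stage <- "acf"
      acf_tbl <- acf_conditions(blocks, filters, fs, config$acf_lags)
      readr::write_csv(as_tibble(acf_tbl), note(file.path(out_dir, "acf_table.csv")))
      friedman <- purrr::map(seq_len(min(3, config$acf_lags)), function(l) {
        friedman_conditions(acf_tbl, lag = l)
      })
      readr::write_csv(
        purrr::map_dfr(friedman, glance),
        note(file.path(out_dir, "friedman_tests.csv"))
      )
      readr::write_csv(
        purrr::map_dfr(friedman, tidy),
        note(file.path(out_dir, "friedman_pairwise.csv"))
      )

      stage <- "velocity"
      exemplar <- simulate_saccade(saccade_model(seed = config$seed), fs_hz = fs)
      vel <- purrr::imap_dfr(
        c(list(unfiltered = NULL), filters),
        function(f, nm) {
          tr <- if (is.null(f)) exemplar else apply_filter(exemplar, f)
          dplyr::mutate(velocity_metrics(instantaneous_velocity(tr)),
            condition = nm, .before = 1
          )
        }
      )
      readr::write_csv(vel, note(file.path(out_dir, "velocity_metrics.csv")))

      stage <- "manifest"
      manifest <- list(
        package_version = as.character(utils::packageVersion("gazefilt")),
        config = config[setdiff(names(config), "filters")],
        filters = purrr::map(filters, "spec"),
        n_blocks = ncol(blocks)
      )
      jsonlite::write_json(manifest, note(file.path(out_dir, "manifest.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )

      list(
        crossings = crossings, spectra = spectra, acf_table = acf_tbl,
        friedman = friedman, velocity = vel, out_dir = out_dir,
        files = created
      )
    },
    error = function(e) {
      unlink(created)
      abort(sprintf("Study failed at stage `%s`: %s", stage, conditionMessage(e)),
        class = "gazefilt_stage_error", parent = e
      )
    }
  )
  invisible(result)
}
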