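# gazefilt

Design, measure and compare the low-pass filters routinely applied to
1000 Hz video-oculography gaze recordings — and quantify what the
filtering does to the signal that remains.

High-rate eye trackers report gaze position (degrees of visual angle,
dva) with broadband sensor noise on top of the oculomotor signal, whose
useful content for fixation analysis sits below ~75 Hz. Researchers
therefore smooth the position channels before computing velocities or
event statistics, usually with one of three implementable families:

* **Savitzky–Golay** (window 23, order 5): sliding least-squares
  polynomial fit, applied as a single centred (zero-phase) pass;
* **Butterworth IIR** (order 7, cutoff 81 Hz), applied
  forward–backward (`filtfilt`-style), which cancels phase/delay and
  squares the magnitude response, i.e. `gain_dB(two-pass) = 2 ×
  gain_dB(one-pass)`;
* **windowed-sinc FIR** (80 taps, Hamming, cutoff 84 Hz), also
  forward–backward.

The two-pass cutoffs are chosen so all three land their effective
−3 dB point at ≈ 75 Hz. The package provides the designs, direct
(coefficient-based) and empirical (FFT-ratio, `C = B/A`) frequency
responses with interpolated dB-level crossings, the fixation pipeline
(six-point velocity screen at 25 deg/s → 2048-sample segments → eight
256-sample blocks → detrended, Hann-windowed, magnitude-averaged
amplitude spectra on the 3.906 Hz grid), the temporal-autocorrelation
study (ACF to lag 5, Fisher-Z, tie-corrected Friedman test,
Tukey-style pairwise rank comparisons), velocity-noise metrics (SD,
RMS, RMS-S2S), and a seeded synthetic gaze generator so everything runs
without recordings. Functions take data frames first and return
tibbles; results have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(gazefilt)

bank <- table1_filters()                       # sg, iir, fir at 1000 Hz
crossing_table(lapply(bank, response_direct), c(-3, -30, -40))
#> # A tibble: 9 × 5
#>   filter level_db freq_hz last_exceedance_hz pct_power_remaining
#>   <chr>     <dbl>   <dbl>              <dbl>               <dbl>
#> 1 sg           -3    74.3               74.3               50.1
#> 2 sg          -30   106.               500                  0.1
#> 3 sg          -40   107.               500                  0.01
#> 4 iir          -3    76.2               76.2               50.1
#> 5 iir         -30   102.               102.                 0.1
#> 6 iir         -40   110.               110.                 0.01
#> 7 fir          -3    74.8               74.8               50.1
#> 8 fir         -30    92.4               92.4                0.1
#> 9 fir         -40    95.5               95.5                0.01
```

All three designs pass ~75 Hz at −3 dB (50% power retained). The FIR
reaches −30 dB (0.1% of power) by 92 Hz and the IIR by 102 Hz. The SG
stop band *rings*: its theoretical curve only dips below −30 dB in
narrow notches (first crossing 106 Hz) and its lobes stay above −30 dB
to Nyquist (`last_exceedance = 500`), which is why its measured −30 dB
point — `crossing_frequency(measured_response(bank$sg), -30)`, the
FFT-ratio estimate at 3.906 Hz resolution — sits near 204.6 Hz instead.

```r
ex <- simulate_saccade(saccade_model(seed = 1))   # ≈1.25 dva saccade, noisy
purrr::map_dfr(
  c(list(unfiltered = NULL), bank),
  \(f) velocity_metrics(instantaneous_velocity(
    if (is.null(f)) ex else apply_filter(ex, f))),
  .id = "condition"
)
#> # A tibble: 4 × 4
#>   condition  sd_dps rms_signal_dps rms_s2s_dps
#>   <chr>       <dbl>          <dbl>       <dbl>
#> 1 unfiltered  117.           117.       202.
#> 2 sg           17.5           17.6       14.7
#> 3 iir          15.0           15.2        3.95
#> 4 fir          14.9           15.1        3.83
```

Instantaneous-velocity noise drops from the ~120 deg/s regime to
~15 deg/s after any of the filters; the zero-phase IIR and FIR are
near-identical and clearly quieter than the SG, and the sample-to-sample
RMS (the standard precision metric) falls below the SD for the smooth
filtered signals, as expected.

The full study — filter export, direct and ratio responses, crossings,
spectra, ACF/Friedman tables, velocity metrics and a JSON manifest —
runs end to end with

```r
res <- run_study(study_config(seed = 7), "study_out")
```

(or `Rscript inst/scripts/run_study.R --out study_out --seed 7`), and is
byte-reproducible for a given configuration and seed. Real recordings in
the `t_s,x_dva[,y_dva]` CSV dialect can be supplied via
`study_config(input_csv = ...)` in place of the simulator.

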