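# bssrp — bowel-sound stimulus–response analysis

`bssrp` turns abdominal audio recorded around a drinking test into a
cohort-level answer to a physiological question: **does bowel motility
before drinking predict the motor response to drinking?**

It is written for researchers working with bowel sounds (BS) —
gastroenterology groups evaluating non-invasive motility markers,
and biomedical-signal engineers building BS detectors. The package
covers the full chain:

1. **Detection** — recordings (mono PCM16 WAV, 44.1 kHz downsampled to
   4 kHz) are split into 64 ms segments every 16 ms; each segment is
   described by 20 power-normalized cepstral coefficients (PNCC,
   without the power-bias subtraction stage) plus 20 linear-prediction
   cepstral coefficients (LPCC) and classified by a small feed-forward
   network; runs of consecutive positive segments become *BS episodes*.
2. **Feature extraction** — episodes are bandpass-filtered
   (100–1500 Hz, third-order Butterworth, zero phase) and reduced to
   the four classical BS time-domain acoustic features (BSTDAFs):
   episodes/min, sound-to-sound interval, BS power and BS length, over
   analysis intervals anchored at the ingestion time (default 5 min
   before, 10 min after).
3. **Stimulus–response analysis** — per participant, the pre-ingestion
   mean x̄_b and the response ratio = x̄_a / x̄_b form one point of the
   BS stimulus–response plot (BSSRP). The package fits
   ratio = a·e^(b·x̄_b) + c and, on the log–log plot,
   ln ratio = m·ln x̄_b + q (natural logs), reports adjusted R²,
   Pearson's r with a two-sided Student-t test (significance at
   p < 0.05), a log–log plane distance metric for interval-length
   sensitivity, and segment-vs-episode detection-limit diagnostics
   (64/16 ms framing admits at most 3747 segments per minute).
4. **Synthesis** — because clinical BS recordings are rarely shareable,
   a generator renders labelled recordings (Poisson bursts of
   band-limited noise on a Gaussian background) and whole cohorts with
   a prescribed power-law stimulus–response coupling, so every stage is
   testable end to end.

## Worked example

Simulate a 20-participant carbonated-water cohort with a known
power-law coupling, build the log–log BSSRP and fit it:

```r
library(bssrp)

preset <- cohort_preset("carbonated")   # ln ratio = -0.706 ln xb + 3.85
cohort <- synth_cohort(preset, n = 20, seed = 1, log_noise_sd = 0)

srp <- build_bssrp(cohort)
fit <- fit_loglog_linear(srp)
fit
#> Log-log linear fit: ln(ratio) = -0.706 * ln(xb) + 3.85
#>   n = 20, adjusted R-squared = 1.0000

pearson_cor(srp$points$ln_xb_bar, srp$points$ln_ratio)
#> Pearson r = -1.0000 (n = 20), t = -Inf, p = 0 *
```

With `log_noise_sd = 0` the cohort lies exactly on the preset line, so
the ordinary-least-squares fit returns the generating slope −0.706 and
intercept 3.85 with adjusted R² = 1: the negative slope means that the
higher a participant's baseline motility, the smaller their relative
response to the stimulus. The matching exponential response curve is
recovered the same way:

```r
x <- seq(5, 150, by = 5)
fit_exponential(x, preset_exponential(preset, x))
#> Exponential fit: ratio = 16.4 * exp(-0.0412 x) + 1.2
#>   n = 30, adjusted R-squared = 1.0000
```

To run the whole audio pipeline (render recordings, train the detector,
detect episodes, extract BSTDAFs, build and fit the BSSRP, write all
artifacts):

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_out"))
res$report$loglog      # slope / intercept / adjusted R^2
res$correlations       # per-feature r and p at the 5/10-min intervals
```

A thin command-line front end with `simulate-recording`,
`simulate-cohort`, `train`, `detect` and `run` subcommands is installed
at `inst/cli/bssrp-tool.R`.

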