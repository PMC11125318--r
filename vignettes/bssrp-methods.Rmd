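---
title: "Bowel-sound stimulus-response analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bowel-sound stimulus-response analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bssrp)
```

## The scientific question

Bowel sounds (BS) are the audible signature of gastrointestinal
contractions. Counting and characterizing them from an abdominal
microphone gives a cheap, non-invasive window on bowel motility.
The question this package addresses is a *stimulus-response* one: does
the motility level a person shows **before** drinking predict the size
of their motor response **after** drinking?

The analysis object is the BS-based stimulus-response plot (BSSRP).
For each participant, a feature $x$ (typically BS episodes per minute)
is averaged over an analysis interval before ingestion
($\bar{x}_b$, 5 min by default) and after ingestion ($\bar{x}_a$,
10 min by default), and the response is summarized as

$$\mathrm{ratio} = \bar{x}_a / \bar{x}_b .$$

The cohort-level plot of $\mathrm{ratio}$ against $\bar{x}_b$, and its
double-logarithmic version, are fitted with

* a three-parameter exponential, $\mathrm{ratio} = a\,e^{b \bar{x}_b} + c$, and
* an ordinary least-squares line in log-log space,
  $\ln \mathrm{ratio} = m \ln \bar{x}_b + q$,

and the association is tested with Pearson's correlation coefficient and
a two-sided Student-t test ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, $n-2$ df,
significance at $p < 0.05$). For a strongly stimulating drink
(carbonated water) the published pattern is a strong negative power-law
coupling; for plain water no coupling is detectable. All logarithms in
the package are natural logarithms.

## Detection pipeline

1. **Audio**: mono PCM16 recordings at 44.1 kHz are downsampled to the
   4 kHz working rate. Rate reduction is done in the Fourier domain
   (spectrum truncation at the new Nyquist). We chose this over
   polyphase FIR resampling because it is exactly duration-preserving
   and its anti-aliasing is ideal; the `signal::resample` polyphase
   implementation available to us left tens of percent of an
   out-of-band tone's power as aliases, failing our own acceptance
   oracle of < 1% residual power.
2. **Framing**: 64 ms segments every 16 ms; trailing partial windows are
   dropped. One minute therefore admits at most
   `floor((60 - 0.064)/0.016) + 1 = 3747` segments — the *detection
   limit* of the system and a useful analytic anchor for tests.
3. **Features**: each segment yields 20 power-normalized cepstral
   coefficients (PNCC) and 20 linear-prediction cepstral coefficients
   (LPCC). The PNCC chain is pre-emphasis (0.97), Hamming window,
   256-point power spectrum, 24 gammatone channels spanning
   100–2000 Hz (ERB-spaced, fourth-order magnitude responses,
   row-normalized), per-frame mean-power normalization, power-law
   compression with exponent 1/15, and a DCT. There is **no power-bias
   subtraction / asymmetric noise suppression stage**, and because
   classification is per-segment the usual medium-time running-power
   normalizer degenerates to the per-frame mean — which also makes the
   coefficients invariant to a global gain. LPCCs come from order-20
   autocorrelation LPC solved by Levinson–Durbin and the standard
   LPC-to-cepstrum recursion; the gain term $c_0$ is excluded so the
   LPCC block is gain-invariant like the PNCC block.
4. **Classifier**: a feed-forward network (40 inputs, one hidden layer
   of 32 logistic units, logistic output) trained full-batch with
   momentum on cross-entropy. Full-batch training with a fixed seed
   makes retraining bit-reproducible, which the tests rely on. Features
   are z-scored with training-set statistics stored in the model.
5. **Episodes**: segments at or above the 0.5 output threshold are
   positive; maximal runs of positive segments become BS episodes
   (a single positive segment is an episode; no gap bridging).
6. **BSTDAFs**: episodes are selected per analysis interval by onset
   time (half-open intervals, so an onset exactly at ingestion belongs
   to the "after" side), audio is bandpass-filtered once at
   100–1500 Hz (third-order Butterworth prototype, i.e. six poles,
   applied forward–backward for zero phase) and sliced afterwards to
   avoid short-signal edge transients. The four features are episodes
   per minute, mean onset-to-onset sound-to-sound interval (SSI), mean
   per-episode mean-squared filtered amplitude (BS power, dimensionless
   normalized units), and mean episode length in seconds. SSI is
   defined onset-to-onset and BS power as a per-episode mean; neither
   convention is forced by prior art, so both are recorded in the
   output metadata.

Participants for whom no BS is detected in one of the intervals have an
undefined $\bar{x}_b$ or ratio and are excluded from the affected
analysis only, with a warning that propagates into the run log — a
participant missing at 1-minute intervals still contributes to the
5/10-minute analyses.

## The synthetic generator

The clinical recordings behind the original analysis are not publicly
available, so the package ships a generator that reproduces the
*statistical* structure the analysis consumes:

* **Events**: homogeneous Poisson onsets per side of the ingestion
  instant, at a prescribed rate in events/min.
* **Waveforms**: each event is white noise bandpass-filtered to
  100–1500 Hz with an exponentially decaying envelope (decay to
  $e^{-3}$ over the event), 30–100 ms long, scaled to a burst
  signal-to-noise ratio of 20 dB over a white Gaussian background.
  The timbre of real borborygmi is *not* modelled: feature extraction
  only needs correct timing, band and energy.
* **Cohorts**: pre-ingestion rates $\bar{x}_b$ are drawn log-uniformly
  over 5–150 events/min and responses follow
  $\ln \mathrm{ratio} = m \ln \bar{x}_b + q + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$. The `carbonated` preset uses
  $(m, q) = (-0.706,\ 3.85)$ together with the matching exponential
  response curve $16.4\,e^{-0.0412 x} + 1.20$; the `water` preset has
  $m = 0$ with independent lognormal ratios around a mild response.
  The default cohort size is 20 and the default log-domain noise is
  $\sigma = 0.3$, which puts the carbonated preset's correlation near
  the strongly negative values reported for real carbonated-water
  cohorts.

Passing tests on these cohorts shows the *pipeline* is sound — that
detection, feature reduction, fitting and testing recover a known
generating law from raw audio. It does not show that real abdominal
recordings are as clean: clinical audio has non-white backgrounds
(rumble, cloth noise, heartbeat), overlapping physiological sources and
annotation ambiguity that the generator deliberately omits, so
detection scores on synthetic audio are upper bounds.

### Ground-truth labels

Early in development, frame truth was defined by time overlap with the
event interval (positive if a frame overlapped at least half the
event). That convention mislabels frames: with a decaying envelope, a
frame can cover half an event yet contain almost no burst energy, and
conversely. The adopted convention is energy-based and exact: the
generator keeps the burst-only waveform and labels a frame positive
when its in-frame burst energy is at least the expected background
energy (in-frame SNR ≥ 0 dB). Frames below that bound carry no usable
acoustic evidence, so no detector — human or machine — should be
penalized for calling them background. For *external* annotation files
(CSV intervals), where no burst-only signal exists, a minimum-overlap
rule is used instead (positive at ≥ half a hop, 8 ms, of overlap).

### The detector's operating point

The framing admits 3747 frames per minute, so even a 0.2% background
false-positive rate creates roughly eight spurious one-frame episodes
per minute — enough to swamp the true episode rate of a low-motility
participant (we measured a participant with 11.8 true episodes/min
being reported at 73.5/min). Episode-rate fidelity therefore demands a
high-precision operating point. Rather than moving the published 0.5
decision threshold, the default training weights positive-class errors
at 0.2, which shifts the learned boundary toward precision: at that
point detected episode rates track true rates to within a few percent
and the background false-episode rate drops below one per minute,
while segment-level F1 stays above 90% on synthetic audio. The weight
is exposed (`ann$pos_weight` in `pipeline_config()`, `pos_weight` in
`train_ann()`, neutral 1 by default in the latter).

## Numerical choices

* **Exponential fit**: Levenberg–Marquardt (via `minpack.lm`) with
  multi-start initialization — $c_0$ slightly below $\min y$,
  $a_0 = \max y - \min y$, $b_0$ from a log-linear pre-fit, plus
  sign-flipped and rescaled variants; the converged start with the
  lowest residual sum of squares wins. Constant-response data are
  flagged unidentifiable (only $a + c$ is determined) and returned
  with $b = 0$ rather than failing.
* **Adjusted $R^2$**: $1 - (1 - R^2)(n-1)/(n-k-1)$ with $k = 1$ for
  the log-log line and $k = 2$ predictors-equivalent for the
  three-parameter exponential.
* **Degenerate inputs**: silent frames clamp channel powers at a small
  floor (finite PNCCs, zero LPCs); zero-variance predictors and
  sub-minimal cohorts (< 3 retained points) error out early; segments
  counts use integer sample arithmetic so the 3747/min limit is exact.
* **Sub-interval statistics**: 1-minute bins with zero counts are
  dropped from log-scale correlations (log of zero) and reported in
  the scan metadata.
* **Determinism**: every stochastic step takes a seed; cohort rendering
  derives per-participant seeds from the master seed so a run is
  reproducible end to end, and the pipeline writes byte-identical
  artifacts for identical configuration and seed.

## Problem sizes used in the shipped tests

The flagship integration test renders a 20-participant carbonated
cohort ($\sigma = 0.15$) as full 15-minute recordings (5 min before,
10 min after ingestion, 4 kHz), trains the detector on 20,000 labelled
synthetic frames, and checks that the refitted log-log slope lands
within three standard errors of the generating slope with a
significantly negative correlation and mean segment F1 ≥ 90%.
Statistical calibration uses 1000 independent water-preset cohorts
(type-I error of the correlation test within 3–7% at the nominal 5%),
and the Monte-Carlo bias check uses 200 replicates. These sizes were
chosen so each property is tested at meaningful power while the whole
suite stays comfortably runnable on a laptop.

## Known limitations

* The acoustic burst model is generic band-limited noise; classifiers
  trained on it will not transfer to real stethoscope audio without
  retraining on annotated recordings.
* The background is white; real wards are not. The package maps the
  original "about 50 dB SPL ambient noise" description onto a relative
  SNR knob because absolute sound-pressure calibration is impossible
  in normalized units.
* Detection of very weak bowel sounds (in-frame SNR below 0 dB) is by
  definition out of reach of the gain-invariant front end.
* `fit_exponential` assumes a monotone saturating response; cohorts
  with non-monotone responses will fit but the parameters lose their
  interpretation.
* Only segment-synchronous labels are supported; onset/offset timing
  error of episodes is bounded by the 16 ms hop and is not modelled
  further.
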