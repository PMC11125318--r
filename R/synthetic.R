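# Synthetic recordings and cohorts.  Bowel-sound events are rendered as
# band-limited noise bursts with a decaying envelope on a Gaussian
# background; event onsets follow a homogeneous Poisson process on each
# side of the ingestion instant.  Cohort presets tie the pre-ingestion
# event rate to the post/pre response ratio through a log-log linear
# (power-law) stimulus-response relation.

#' Burst-process parameters for one side of a synthetic recording
#'
#' @param rate Event rate in events/min (>= 0).
#' @param duration_range Burst duration range in seconds (default
#'   0.03--0.10, typical bowel-sound lengths).
#' @param band Burst frequency band in Hz (default 100--1500, the main
#'   bowel-sound band).
#' @param snr_db Burst RMS over background RMS, in dB (default 20;
#'   synthetic recordings are deliberately cleaner than clinical ones).
#' @param envelope `"exp"` (exponential decay, default) or `"cosine"`
#'   (raised cosine).
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(rate, duration_range = c(0.03, 0.10),
                         band = c(100, 1500), snr_db = 20,
                         envelope = c("exp", "cosine")) {
  envelope <- match.arg(envelope)
  stopifnot(rate >= 0, length(duration_range) == 2,
            duration_range[1] > 0, duration_range[2] >= duration_range[1],
            length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(list(rate = rate, duration_range = duration_range,
                 band = band, snr_db = snr_db, envelope = envelope),
            class = "burst_params")
}

# One band-limited noise burst of `n` samples at unit RMS.
render_burst <- function(n, band, envelope, sample_rate) {
  pad <- 128L
  raw <- stats::rnorm(n + 2L * pad)
  filt <- bs_bandpass(raw, sample_rate, band[1], band[2])
  x <- filt[(pad + 1L):(pad + n)]
  env <- if (envelope == "exp") {
    exp(-3 * (seq_len(n) - 1) / n)
  } else {
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  }
  x <- x * env
  rms <- sqrt(mean(x^2))
  if (rms > 0) x / rms else x
}

#' Generate one labelled synthetic recording
#'
#' A pre-ingestion and a post-ingestion Poisson burst process (rates in
#' events/min) are rendered on a white Gaussian background.  Each event
#' is a band-limited noise burst with the configured envelope, scaled to
#' `snr_db` above the background RMS.  The ingestion time is the end of
#' the pre side.  Output is bit-identical for identical arguments and
#' seed.
#'
#' @param pre,post [burst_params()] for the two sides.
#' @param durations_min `c(before, after)` side lengths in minutes
#'   (default `c(5, 10)`, the standard drinking-test protocol).
#' @param sample_rate Hz (default 4000).
#' @param noise_floor Background RMS in normalized amplitude units
#'   (default 0.01).
#' @param seed RNG seed.
#' @param participant_id Identifier for the returned recording.
#' @param segment_length,shift Framing parameters (seconds) used for the
#'   exact per-frame ground truth.
#' @return List with `recording` (a [bs_recording()] with
#'   `ingestion_time` set), `labels` (merged ground-truth event
#'   intervals, `start_s`/`end_s`) and `frame_labels` (exact per-frame
#'   ground truth for the given framing: a frame is positive when it
#'   contains at least as much burst energy as the expected background
#'   energy, i.e. an in-frame SNR of 0 dB or better -- frames below
#'   that carry no usable acoustic evidence).
#' @export
synth_recording <- function(pre, post, durations_min = c(5, 10),
                            sample_rate = 4000, noise_floor = 0.01,
                            seed = 1, participant_id = "synthetic",
                            segment_length = 0.064, shift = 0.016) {
  stopifnot(inherits(pre, "burst_params"), inherits(post, "burst_params"))
  nyq <- sample_rate / 2
  if (pre$band[2] >= nyq || post$band[2] >= nyq) {
    stop("burst band upper edge must be below Nyquist")
  }
  set.seed(as.integer(seed))
  dur_s <- durations_min * 60
  total <- sum(dur_s)
  n <- as.integer(round(total * sample_rate))
  x <- stats::rnorm(n, sd = noise_floor)
  burst_sig <- numeric(n) # burst-only waveform for the exact frame truth

  starts <- numeric(0)
  ends <- numeric(0)
  sides <- list(list(p = pre, t0 = 0, t1 = dur_s[1]),
                list(p = post, t0 = dur_s[1], t1 = total))
  for (s in sides) {
    p <- s$p
    n_ev <- stats::rpois(1, p$rate * (s$t1 - s$t0) / 60)
    if (n_ev == 0) next
    onset <- sort(stats::runif(n_ev, s$t0, s$t1))
    dur <- stats::runif(n_ev, p$duration_range[1], p$duration_range[2])
    amp <- noise_floor * 10^(p$snr_db / 20)
    for (i in seq_len(n_ev)) {
      i0 <- floor(onset[i] * sample_rate) + 1L
      i1 <- min(n, i0 + as.integer(round(dur[i] * sample_rate)) - 1L)
      if (i1 < i0) next
      nb <- i1 - i0 + 1L
      b <- amp * render_burst(nb, p$band, p$envelope, sample_rate)
      x[i0:i1] <- x[i0:i1] + b
      burst_sig[i0:i1] <- burst_sig[i0:i1] + b
      starts <- c(starts, (i0 - 1L) / sample_rate)
      ends <- c(ends, i1 / sample_rate)
    }
  }
  labels <- merge_intervals(data.frame(start_s = starts, end_s = ends))

  # exact per-frame truth: burst energy >= expected background energy
  win <- as.integer(round(segment_length * sample_rate))
  hop <- as.integer(round(shift * sample_rate))
  frame_labels <- integer(0)
  if (n >= win) {
    nfr <- (n - win) %/% hop + 1L
    i0s <- (seq_len(nfr) - 1L) * hop
    cs <- c(0, cumsum(burst_sig^2))
    energy <- cs[i0s + win + 1L] - cs[i0s + 1L]
    frame_labels <- as.integer(energy >= noise_floor^2 * win)
  }

  rec <- bs_recording(x, sample_rate, ingestion_time = dur_s[1],
                      participant_id = participant_id)
  list(recording = rec, labels = labels, frame_labels = frame_labels)
}

#' Cohort preset for the stimulus-response generator
#'
#' Encodes the power-law coupling `ln(ratio) = m * ln(xb_bar) + q`
#' between the pre-ingestion episode rate and the post/pre response
#' ratio.  The carbonated-water preset uses the coupling
#' `m = -0.706`, `q = 3.85` (strong stimulus; higher baseline motility
#' leaves less headroom for a response) and carries the matching
#' exponential-decay response curve `ratio = 16.4 exp(-0.0412 x) + 1.20`
#' as `exp_a/exp_b/exp_c`.  The cold-water preset has no coupling
#' (`m = 0`): the response ratio is independent lognormal noise around a
#' mild stimulus level.
#'
#' @param name `"carbonated"` or `"water"`.
#' @param m,q Slope and intercept of the log-log coupling; preset
#'   defaults can be overridden.
#' @param log_noise_sd SD of the participant-level noise on
#'   `ln(ratio)` (default 0.3).
#' @param xb_range Range of pre-ingestion rates, events/min, sampled
#'   log-uniformly (default 5--150).
#' @param n_participants Default cohort size (20).
#' @return A list of class `cohort_preset`.
#' @export
cohort_preset <- function(name = c("carbonated", "water"), m = NULL,
                          q = NULL, log_noise_sd = 0.3,
                          xb_range = c(5, 150), n_participants = 20) {
  name <- match.arg(name)
  if (log_noise_sd < 0) stop("log_noise_sd must be non-negative")
  if (name == "carbonated") {
    if (is.null(m)) m <- -0.706
    if (is.null(q)) q <- 3.85
    exp_pars <- c(a = 16.4, b = -0.0412, c = 1.20)
  } else {
    if (is.null(m)) m <- 0
    if (is.null(q)) q <- log(1.5)
    exp_pars <- NULL
  }
  structure(list(name = name, m = m, q = q, log_noise_sd = log_noise_sd,
                 xb_range = xb_range, n_participants = n_participants,
                 exp_pars = exp_pars),
            class = "cohort_preset")
}

#' Evaluate a preset's exponential response curve
#'
#' `ratio = a * exp(b * x) + c` with the preset's `exp_a/exp_b/exp_c`.
#'
#' @param preset A [cohort_preset()] carrying exponential parameters.
#' @param x Pre-ingestion feature values.
#' @return Response ratios.
#' @export
preset_exponential <- function(preset, x) {
  if (is.null(preset$exp_pars)) {
    stop("preset '", preset$name, "' has no exponential response curve")
  }
  p <- preset$exp_pars
  unname(p["a"]) * exp(unname(p["b"]) * x) + unname(p["c"])
}

#' Generate a synthetic stimulus-response cohort
#'
#' Pre-ingestion rates `xb_bar` are drawn log-uniformly over the preset
#' range and response ratios from
#' `ln(ratio) = m ln(xb_bar) + q + N(0, sigma)`.  With `sigma = 0` the
#' points lie exactly on the preset line (seed-independent).  With
#' `render_audio = TRUE` each participant is additionally rendered as a
#' full labelled recording whose post-ingestion rate is
#' `ratio * xb_bar`.
#'
#' @param preset A [cohort_preset()].
#' @param n Cohort size (default `preset$n_participants`; >= 3).
#' @param seed RNG seed.
#' @param log_noise_sd Override of the preset noise SD.
#' @param render_audio Also render full recordings (default FALSE).
#' @param durations_min,sample_rate,noise_floor,snr_db,duration_range
#'   Recording-rendering parameters (see [synth_recording()]).
#' @return A data frame `participant_id, xb_bar, ratio, xa_rate` of
#'   class `synth_cohort`; when `render_audio = TRUE` the attribute
#'   `recordings` holds one `synth_recording()` result per participant.
#' @export
synth_cohort <- function(preset, n = preset$n_participants, seed = 1,
                         log_noise_sd = preset$log_noise_sd,
                         render_audio = FALSE, durations_min = c(5, 10),
                         sample_rate = 4000, noise_floor = 0.01,
                         snr_db = 20, duration_range = c(0.03, 0.10)) {
  stopifnot(inherits(preset, "cohort_preset"))
  if (n < 3) stop("cohort needs at least 3 participants")
  if (log_noise_sd < 0) stop("log_noise_sd must be non-negative")
  set.seed(as.integer(seed))
  xb <- exp(stats::runif(n, log(preset$xb_range[1]),
                         log(preset$xb_range[2])))
  ln_ratio <- preset$m * log(xb) + preset$q +
    stats::rnorm(n, 0, log_noise_sd)
  ratio <- exp(ln_ratio)
  tab <- data.frame(participant_id = sprintf("S%02d", seq_len(n)),
                    xb_bar = xb, ratio = ratio, xa_rate = ratio * xb)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  class(tab) <- c("synth_cohort", "data.frame")
  attr(tab, "preset") <- preset
  if (render_audio) {
    recs <- lapply(seq_len(n), function(i) {
      synth_recording(
        pre = burst_params(xb[i], duration_range = duration_range,
                           snr_db = snr_db),
        post = burst_params(tab$xa_rate[i],
                            duration_range = duration_range,
                            snr_db = snr_db),
        durations_min = durations_min, sample_rate = sample_rate,
        noise_floor = noise_floor, seed = rec_seeds[i],
        participant_id = tab$participant_id[i])
    })
    attr(tab, "recordings") <- recs
  }
  tab
}

#' Labelled feature set for training the segment classifier
#'
#' Renders synthetic recording chunks at a moderate burst rate, labels
#' every frame with the generator's exact energy-based ground truth,
#' extracts PNCC+LPCC features, and samples
#' the requested numbers of positive (burst) and negative (background)
#' frames.  Deterministic for a given seed.
#'
#' @param n_pos,n_neg Numbers of positive and negative frames (> 0).
#' @param snr_db Burst SNR in dB (default 20).
#' @param seed RNG seed.
#' @param cfg [feature_config()].
#' @param sample_rate,noise_floor,duration_range As in
#'   [synth_recording()].
#' @return List with `features` (n x 40 matrix) and `labels`
#'   (0/1 vector).
#' @export
synth_feature_training_set <- function(n_pos, n_neg, snr_db = 20, seed = 1,
                                       cfg = feature_config(),
                                       sample_rate = 4000,
                                       noise_floor = 0.01,
                                       duration_range = c(0.03, 0.10)) {
  if (n_pos <= 0 || n_neg <= 0) stop("n_pos and n_neg must be positive")
  rate <- 60 # events/min in the rendered chunks
  feats <- list()
  labs <- list()
  got_pos <- 0L
  got_neg <- 0L
  chunk <- 0L
  while ((got_pos < n_pos || got_neg < n_neg) && chunk < 50L) {
    chunk <- chunk + 1L
    sr <- synth_recording(
      pre = burst_params(rate, duration_range = duration_range,
                         snr_db = snr_db),
      post = burst_params(rate, duration_range = duration_range,
                          snr_db = snr_db),
      durations_min = c(0.5, 0.5), sample_rate = sample_rate,
      noise_floor = noise_floor, seed = seed + 7919L * chunk)
    fr <- segment_frames(sr$recording)
    y <- sr$frame_labels
    if (!any(y == 1) && nrow(sr$labels) > 0) {
      # no event is audible (very low SNR): fall back to the nominal
      # event positions so both classes exist for calibration studies
      y <- intervals_to_labels(sr$labels, fr$n, fr$segment_length, fr$shift)
    }
    X <- feature_matrix(fr, cfg)
    feats[[chunk]] <- X
    labs[[chunk]] <- y
    got_pos <- got_pos + sum(y == 1)
    got_neg <- got_neg + sum(y == 0)
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  if (sum(y == 1) < n_pos || sum(y == 0) < n_neg) {
    stop("could not render enough labelled frames")
  }
  set.seed(as.integer(seed))
  ip <- sample(which(y == 1), n_pos)
  im <- sample(which(y == 0), n_neg)
  idx <- c(ip, im)
  list(features = X[idx, , drop = FALSE],
       labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}
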