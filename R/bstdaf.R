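# Bandpass filtering and the four BS time-domain acoustic features
# (BSTDAFs): episodes/min, sound-to-sound interval, power, length.

#' Butterworth bandpass for bowel-sound energy
#'
#' Third-order Butterworth bandpass (3rd-order analog low-pass prototype
#' transformed to bandpass, i.e. six poles) with 100--1500 Hz passband,
#' applied forward-backward (zero phase) so episode timing is not
#' shifted.  Set `zero_phase = FALSE` for a single causal pass.
#'
#' @param x Numeric samples (or a [bs_recording()]).
#' @param sample_rate Hz; taken from `x` when it is a recording.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Analog prototype order (default 3).
#' @param zero_phase Apply filtfilt (default) instead of a single pass.
#' @return Filtered samples (numeric vector), or a filtered recording if
#'   `x` was one.
#' @export
bs_bandpass <- function(x, sample_rate = NULL, low = 100, high = 1500,
                        order = 3, zero_phase = TRUE) {
  rec <- NULL
  if (inherits(x, "bs_recording")) {
    rec <- x
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  nyq <- sample_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    stop("invalid band edges: need 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
  if (!is.null(rec)) {
    rec$samples <- y
    rec
  } else {
    y
  }
}

#' Define a pre- or post-ingestion analysis interval
#'
#' Intervals are anchored at the ingestion time: `before` counts
#' backward from the instant immediately before ingestion
#' (`[t_ing - width, t_ing)`), `after` counts forward from ingestion
#' (`[t_ing, t_ing + width)`).  Both are half-open so an episode whose
#' onset falls exactly at the ingestion instant belongs to `after`.
#'
#' @param side `"before"` or `"after"`.
#' @param width Interval width in minutes (> 0).
#' @return A list of class `analysis_interval`.
#' @export
analysis_interval <- function(side = c("before", "after"), width) {
  side <- match.arg(side)
  if (!is.numeric(width) || width <= 0) stop("width must be positive (minutes)")
  structure(list(side = side, width = width), class = "analysis_interval")
}

interval_bounds <- function(interval, ingestion_time) {
  w <- interval$width * 60
  if (interval$side == "before") {
    c(ingestion_time - w, ingestion_time)
  } else {
    c(ingestion_time, ingestion_time + w)
  }
}

#' Select the episodes whose onset falls in an analysis interval
#'
#' Episode membership is decided by the onset time (an episode
#' straddling the ingestion instant is credited to its onset side).
#' Onset/offset times in the result are re-expressed relative to the
#' interval start.
#'
#' @param episodes An `episode_set` from [form_episodes()].
#' @param interval An [analysis_interval()].
#' @param ingestion_time Ingestion timestamp in seconds.
#' @param duration Recording duration in seconds; used to check that the
#'   interval lies within the recording.
#' @return The selected episodes as an `episode_set` with times relative
#'   to the interval start (empty set when no episode falls inside).
#' @export
select_episodes <- function(episodes, interval, ingestion_time,
                            duration = NULL) {
  if (is.null(ingestion_time)) stop("ingestion_time must be set")
  b <- interval_bounds(interval, ingestion_time)
  if (b[1] < -1e-9 || (!is.null(duration) && b[2] > duration + 1e-9)) {
    stop("analysis interval [", signif(b[1], 6), ", ", signif(b[2], 6),
         ") exceeds the recording bounds")
  }
  keep <- episodes$onset_s >= b[1] & episodes$onset_s < b[2]
  out <- episodes[keep, , drop = FALSE]
  out$onset_s <- out$onset_s - b[1]
  out$offset_s <- out$offset_s - b[1]
  rownames(out) <- NULL
  structure(out, class = c("episode_set", "data.frame"),
            shift = attr(episodes, "shift"),
            segment_length = attr(episodes, "segment_length"),
            recording_id = attr(episodes, "recording_id"),
            interval = interval)
}

#' Extract the four BSTDAFs over an analysis interval
#'
#' Given the episodes already selected for the interval and the
#' bandpass-filtered audio of the interval:
#' \describe{
#'   \item{episodes_per_min}{episode count divided by the interval width.}
#'   \item{ssi_mean}{mean onset-to-onset gap between consecutive
#'     episodes (seconds); defined only with at least two episodes.}
#'   \item{power_mean}{mean over episodes of the mean squared filtered
#'     amplitude inside the episode (dimensionless, normalized units).}
#'   \item{length_mean}{mean episode duration (seconds).}
#' }
#' With zero episodes every feature except the (zero) rate is `NA` and
#' the result is flagged `undefined`; such participants are excluded
#' from downstream stimulus-response analyses.
#'
#' @param episodes Episodes with times relative to the interval start
#'   (see [select_episodes()]).
#' @param filtered Bandpass-filtered samples of the interval (first
#'   sample = interval start); optional, but required for `power_mean`.
#' @param interval The [analysis_interval()].
#' @param sample_rate Hz (needed with `filtered`).
#' @return A list of class `bstdaf` with the four features plus
#'   `segments_per_min`, `n_episodes`, `side`, `width_min`, `undefined`.
#' @export
extract_bstdafs <- function(episodes, filtered = NULL, interval,
                            sample_rate = 4000) {
  n <- nrow(episodes)
  width_min <- interval$width
  eps_per_min <- n / width_min
  seg_per_min <- if (n > 0) sum(episodes$n_segments) / width_min else 0
  ssi <- if (n >= 2) mean(diff(sort(episodes$onset_s))) else NA_real_
  len <- if (n >= 1) mean(episodes$offset_s - episodes$onset_s) else NA_real_
  pow <- NA_real_
  if (n >= 1 && !is.null(filtered)) {
    per_ep <- vapply(seq_len(n), function(i) {
      i0 <- max(1L, floor(episodes$onset_s[i] * sample_rate) + 1L)
      i1 <- min(length(filtered), ceiling(episodes$offset_s[i] * sample_rate))
      if (i1 < i0) return(NA_real_)
      mean(filtered[i0:i1]^2)
    }, numeric(1))
    pow <- mean(per_ep, na.rm = TRUE)
  }
  structure(
    list(episodes_per_min = eps_per_min,
         segments_per_min = seg_per_min,
         ssi_mean = ssi, power_mean = pow, length_mean = len,
         n_episodes = n, side = interval$side, width_min = width_min,
         undefined = n == 0),
    class = "bstdaf"
  )
}

#' @export
print.bstdaf <- function(x, ...) {
  cat(sprintf("BSTDAFs (%s, %g min): %g episodes\n", x$side, x$width_min,
              x$n_episodes))
  cat(sprintf("  episodes/min %.3f | SSI %.3f s | power %.3g | length %.3f s\n",
              x$episodes_per_min, x$ssi_mean, x$power_mean, x$length_mean))
  invisible(x)
}

#' BSTDAFs of one participant's recording, both sides of ingestion
#'
#' Convenience wrapper: bandpass-filters the whole recording once,
#' selects episodes for the `before` and `after` intervals, and extracts
#' the features on each side.
#'
#' @param rec A [bs_recording()] with `ingestion_time` set.
#' @param episodes Detected `episode_set` in recording time.
#' @param before_width,after_width Interval widths in minutes.
#' @param low,high,order Bandpass parameters (see [bs_bandpass()]).
#' @return Data frame with one row per side in the layout of the BSTDAF
#'   table: `participant_id, side, width_min, episodes_per_min,
#'   segments_per_min, ssi_s, power, length_s, n_episodes`.
#' @export
bstdaf_table <- function(rec, episodes, before_width = 5, after_width = 10,
                         low = 100, high = 1500, order = 3) {
  stopifnot(inherits(rec, "bs_recording"))
  filtered <- bs_bandpass(rec$samples, rec$sample_rate, low, high, order)
  rows <- lapply(list(analysis_interval("before", before_width),
                      analysis_interval("after", after_width)),
                 function(iv) {
    b <- interval_bounds(iv, rec$ingestion_time)
    sel <- select_episodes(episodes, iv, rec$ingestion_time, rec$duration)
    i0 <- max(1L, floor(b[1] * rec$sample_rate) + 1L)
    i1 <- min(length(filtered), ceiling(b[2] * rec$sample_rate))
    f <- extract_bstdafs(sel, filtered[i0:i1], iv, rec$sample_rate)
    data.frame(participant_id = rec$participant_id, side = iv$side,
               width_min = iv$width,
               episodes_per_min = f$episodes_per_min,
               segments_per_min = f$segments_per_min,
               ssi_s = f$ssi_mean, power = f$power_mean,
               length_s = f$length_mean, n_episodes = f$n_episodes)
  })
  do.call(rbind, rows)
}
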