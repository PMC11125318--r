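# Recording container, resampling and framing.

#' Construct an abdominal-audio recording
#'
#' @param samples Numeric vector of normalized amplitudes (dimensionless,
#'   nominally in `[-1, 1]`).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param ingestion_time Optional drink-ingestion timestamp in seconds
#'   from the start of the recording; must lie within the recording.
#' @param participant_id Opaque participant identifier.
#' @return An object of class `bs_recording`: a list with elements
#'   `samples`, `sample_rate`, `ingestion_time`, `participant_id` and
#'   `duration` (seconds).
#' @export
bs_recording <- function(samples, sample_rate, ingestion_time = NULL,
                         participant_id = "P1") {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  duration <- length(samples) / sample_rate
  if (!is.null(ingestion_time)) {
    if (ingestion_time < 0 || ingestion_time > duration) {
      stop("ingestion_time must lie within the recording (0..",
           signif(duration, 6), " s)")
    }
  }
  structure(
    list(samples = samples, sample_rate = sample_rate,
         ingestion_time = ingestion_time,
         participant_id = participant_id, duration = duration),
    class = "bs_recording"
  )
}

#' @export
print.bs_recording <- function(x, ...) {
  cat("bs_recording:", x$participant_id, "\n")
  cat("  ", length(x$samples), " samples @ ", x$sample_rate, " Hz (",
      sprintf("%.3f", x$duration), " s)\n", sep = "")
  if (!is.null(x$ingestion_time)) {
    cat("  ingestion at ", sprintf("%.3f", x$ingestion_time), " s\n", sep = "")
  }
  invisible(x)
}

#' Downsample a recording
#'
#' Rate reduction is performed in the Fourier domain: the spectrum of the
#' full signal is truncated at the new Nyquist frequency and inverted at
#' the new length.  This applies an ideal (brick-wall) anti-aliasing
#' low-pass, preserves the duration to within one output sample period,
#' and leaves the signal untouched when `target_rate == sample_rate`.
#' Upsampling is out of scope and rejected.
#'
#' @param rec A [bs_recording()].
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   current rate.
#' @return A [bs_recording()] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "bs_recording"))
  if (target_rate > rec$sample_rate) {
    stop("upsampling not supported (target_rate > sample_rate)")
  }
  if (target_rate == rec$sample_rate) {
    return(rec)
  }
  n_in <- length(rec$samples)
  n_out <- floor(n_in * target_rate / rec$sample_rate)
  if (n_out < 1) stop("recording too short to resample")

  spec <- stats::fft(rec$samples)
  # keep bins up to the new Nyquist; build a conjugate-symmetric spectrum
  half <- floor(n_out / 2)
  out_spec <- complex(n_out)
  out_spec[1] <- spec[1]
  if (half >= 1) {
    out_spec[2:(half + 1)] <- spec[2:(half + 1)]
    hi <- n_out - (1:half) + 1
    out_spec[hi] <- Conj(spec[2:(half + 1)])
    if (n_out %% 2 == 0) {
      # shared Nyquist bin must be real for a real output signal
      out_spec[half + 1] <- Re(spec[half + 1])
    }
  }
  y <- Re(stats::fft(out_spec, inverse = TRUE)) / n_in
  bs_recording(y, target_rate,
               ingestion_time = rec$ingestion_time,
               participant_id = rec$participant_id)
}

#' Split a recording into fixed-length overlapping frames
#'
#' Frames ("BS segments") of `segment_length` seconds are taken every
#' `shift` seconds; only fully contained windows are emitted, so the
#' frame count is `floor((n - win) / hop) + 1` in samples.  At the 4 kHz
#' working rate and the 64 ms / 16 ms defaults one minute of audio gives
#' 3747 frames, which is also the per-minute detection limit of the
#' segment classifier.
#'
#' @param rec A [bs_recording()] (or numeric vector plus `sample_rate`).
#' @param segment_length Frame length in seconds (default 0.064).
#' @param shift Hop between frame starts in seconds (default 0.016).
#' @param sample_rate Required when `rec` is a plain numeric vector.
#' @return An object of class `bs_frames`: list with `frames` (matrix,
#'   one column per frame), `start_time` (seconds), `segment_length`,
#'   `shift`, `sample_rate` and `n` (frame count).  A recording shorter
#'   than one frame yields zero frames with a warning.
#' @export
segment_frames <- function(rec, segment_length = 0.064, shift = 0.016,
                           sample_rate = NULL) {
  if (inherits(rec, "bs_recording")) {
    x <- rec$samples
    fs <- rec$sample_rate
  } else {
    x <- as.numeric(rec)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for raw samples")
  }
  win <- as.integer(round(segment_length * fs))
  hop <- as.integer(round(shift * fs))
  if (win < 1 || hop < 1) stop("segment_length and shift too small for sample rate")
  n <- length(x)
  if (n < win) {
    warning("recording shorter than one segment; returning zero frames")
    frames <- matrix(numeric(0), nrow = win, ncol = 0)
    starts <- numeric(0)
  } else {
    n_frames <- (n - win) %/% hop + 1L
    starts0 <- (seq_len(n_frames) - 1L) * hop
    idx <- outer(seq_len(win), starts0, `+`)
    frames <- matrix(x[idx], nrow = win)
    starts <- starts0 / fs
  }
  structure(
    list(frames = frames, start_time = starts,
         segment_length = segment_length, shift = shift,
         sample_rate = fs, n = ncol(frames)),
    class = "bs_frames"
  )
}

#' @export
print.bs_frames <- function(x, ...) {
  cat("bs_frames:", x$n, "frames of", nrow(x$frames), "samples @",
      x$sample_rate, "Hz\n")
  cat("  segment_length =", x$segment_length, "s, shift =", x$shift, "s\n")
  invisible(x)
}
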