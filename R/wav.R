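# Minimal RIFF/WAVE (PCM16) reader and writer.  Recordings are mono
# integer PCM; samples are exchanged as doubles in [-1, 1] by dividing
# the 16-bit integers by 32768.

#' Read a mono PCM16 WAV file
#'
#' Parses a RIFF/WAVE file containing 16-bit integer PCM and returns a
#' [bs_recording()].  Amplitudes are scaled to `[-1, 1]` by dividing by
#' 32768.  Unknown RIFF chunks (e.g. `LIST`) are skipped.
#'
#' @param path Path to the WAV file.
#' @param channels How to treat multi-channel files: `"error"` (default)
#'   rejects them, `"first"` keeps channel 1 and drops the rest.
#' @param ingestion_time Optional ingestion timestamp (seconds from the
#'   start of the recording) attached to the returned recording.
#' @param participant_id Optional participant identifier; defaults to the
#'   file name without extension.
#' @return A [bs_recording()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, channels = c("error", "first"),
                     ingestion_time = NULL, participant_id = NULL) {
  channels <- match.arg(channels)
  if (!file.exists(path)) {
    stop("WAV file not found: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little") # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1) # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV file (missing fmt/data chunk): ", path)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop("unsupported WAV encoding: only integer PCM16 is supported")
  }
  if (fmt$n_channels != 1L && channels == "error") {
    stop("multi-channel WAV rejected (", fmt$n_channels,
         " channels); use channels = \"first\" to keep channel 1")
  }

  ints <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                  size = 2, signed = TRUE, endian = "little")
  if (fmt$n_channels > 1L) {
    ints <- ints[seq(1L, length(ints), by = fmt$n_channels)]
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  bs_recording(ints / 32768, fmt$sample_rate,
               ingestion_time = ingestion_time,
               participant_id = participant_id)
}

#' Write a recording to a mono PCM16 WAV file
#'
#' Amplitudes are clipped to `[-1, 1 - 2^-15]` and quantized to 16-bit
#' integers (multiplication by 32768 with rounding).
#'
#' @param rec A [bs_recording()] or a numeric vector of samples.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz; taken from `rec` when it is a
#'   recording.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate = NULL) {
  if (inherits(rec, "bs_recording")) {
    samples <- rec$samples
    sample_rate <- rec$sample_rate
  } else {
    samples <- as.numeric(rec)
    if (is.null(sample_rate)) stop("sample_rate required for raw samples")
  }
  ints <- as.integer(round(pmin(pmax(samples, -1), 1 - 2^-15) * 32768))
  n_bytes <- length(ints) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
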