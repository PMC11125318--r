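# Cepstral features: PNCC (power-bias subtraction stage removed) and
# LPCC.  All heavy lifting is vectorized across frames so a 15-minute
# recording (~56k frames) is processed in a few seconds.

#' Feature-extraction configuration
#'
#' Bundles every tunable of the per-segment feature extractor.  Defaults
#' follow common PNCC practice at a 4 kHz sampling rate: 24 gammatone
#' channels spanning 100--2000 Hz, power-law compression with exponent
#' 1/15, Hamming window, 256-point FFT.  Because classification is done
#' independently per 64 ms segment, the usual medium-time running-power
#' normalizer reduces to a per-frame mean-power normalization, which is
#' what is implemented; no power-bias subtraction / asymmetric noise
#' suppression stage is applied.
#'
#' @param pncc_dims Number of PNCC coefficients (default 20).
#' @param lpcc_dims Number of LPCC coefficients (default 20).
#' @param lpc_order LPC model order (default 20).
#' @param gammatone_channels Number of gammatone channels (default 24).
#' @param gammatone_band Channel centre-frequency range in Hz
#'   (default `c(100, 2000)`); the upper edge must not exceed Nyquist.
#' @param power_law_exponent Compression exponent (default 1/15).
#' @param fft_size FFT length in samples (default 256); frames shorter
#'   than this are zero-padded.
#' @param window Analysis taper, `"hamming"` (default) or `"hann"`.
#' @param power_floor Clamp for channel powers and silent-frame gains.
#' @param preemphasis First-order pre-emphasis coefficient (default 0.97).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(pncc_dims = 20, lpcc_dims = 20, lpc_order = 20,
                           gammatone_channels = 24,
                           gammatone_band = c(100, 2000),
                           power_law_exponent = 1 / 15,
                           fft_size = 256, window = "hamming",
                           power_floor = 1e-12, preemphasis = 0.97) {
  stopifnot(pncc_dims <= gammatone_channels,
            length(gammatone_band) == 2,
            gammatone_band[1] > 0, gammatone_band[2] > gammatone_band[1],
            power_law_exponent > 0, fft_size > 0, power_floor > 0)
  structure(
    list(pncc_dims = pncc_dims, lpcc_dims = lpcc_dims,
         lpc_order = lpc_order,
         gammatone_channels = gammatone_channels,
         gammatone_band = gammatone_band,
         power_law_exponent = power_law_exponent,
         fft_size = fft_size, window = window,
         power_floor = power_floor, preemphasis = preemphasis),
    class = "feature_config"
  )
}

window_taper <- function(n, type) {
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         stop("unknown window type: ", type))
}

# ERB scale (Glasberg & Moore): channel centres equally spaced in ERB
# number between the band edges.
erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_number_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (1 + 4.37 * f / 1000)

# Squared-magnitude gammatone (order 4) responses sampled at the FFT bin
# frequencies; each channel row is normalized to unit sum so a flat
# spectrum gives equal channel powers.
gammatone_weights <- function(cfg, sample_rate) {
  if (cfg$gammatone_band[2] > sample_rate / 2 + 1e-9) {
    stop("gammatone band upper edge exceeds Nyquist")
  }
  n_bins <- cfg$fft_size %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sample_rate / cfg$fft_size
  cfs <- erb_number_inv(seq(erb_number(cfg$gammatone_band[1]),
                            erb_number(cfg$gammatone_band[2]),
                            length.out = cfg$gammatone_channels))
  W <- matrix(0, cfg$gammatone_channels, n_bins)
  for (c in seq_along(cfs)) {
    b <- 1.019 * erb_bandwidth(cfs[c])
    W[c, ] <- (1 + ((freqs - cfs[c]) / b)^2)^(-4)
  }
  W / rowSums(W)
}

# Orthonormal DCT-II matrix rows 0..(n_out-1) applied to n_in channels.
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1)
  j <- seq_len(n_in)
  D <- sqrt(2 / n_in) *
    cos(outer(k, 2 * j - 1, function(k, m) pi * k * m / (2 * n_in)))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

# Pre-emphasize and taper a frame matrix (frames in columns).
condition_frames <- function(frames, cfg) {
  win <- nrow(frames)
  if (cfg$preemphasis > 0) {
    frames <- frames - cfg$preemphasis * rbind(0, frames[-win, , drop = FALSE])
  }
  frames * window_taper(win, cfg$window)
}

# Windowed power spectrum of every frame: (fft_size/2 + 1) x n matrix.
power_spectrum <- function(frames, cfg) {
  win <- nrow(frames)
  if (win < cfg$fft_size) {
    frames <- rbind(frames,
                    matrix(0, cfg$fft_size - win, ncol(frames)))
  } else if (win > cfg$fft_size) {
    stop("frame longer than fft_size")
  }
  spec <- stats::mvfft(frames)
  n_bins <- cfg$fft_size %/% 2 + 1
  Mod(spec[seq_len(n_bins), , drop = FALSE])^2
}

#' Power-normalized cepstral coefficients for a batch of frames
#'
#' Pipeline: pre-emphasis, Hamming window, power spectrum, gammatone
#' channel powers, per-frame mean-power normalization, power-law
#' compression, DCT; the first `pncc_dims` coefficients are returned.
#' There is no power-bias subtraction stage.  Because the channel powers
#' are divided by their per-frame mean before compression, the
#' coefficients are invariant to a global gain (up to the power floor on
#' silent frames).
#'
#' @param frames Numeric matrix, one frame per column (or a `bs_frames`
#'   object).
#' @param cfg A [feature_config()].
#' @param sample_rate Sampling rate in Hz (taken from `frames` when it
#'   is a `bs_frames` object).
#' @return `pncc_dims` x n matrix of coefficients.
#' @export
pncc_batch <- function(frames, cfg = feature_config(), sample_rate = NULL) {
  if (inherits(frames, "bs_frames")) {
    sample_rate <- frames$sample_rate
    frames <- frames$frames
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  if (ncol(frames) == 0) return(matrix(numeric(0), cfg$pncc_dims, 0))
  P <- power_spectrum(condition_frames(frames, cfg), cfg)
  W <- gammatone_weights(cfg, sample_rate)
  C <- pmax(W %*% P, cfg$power_floor)
  U <- sweep(C, 2, colMeans(C), "/")
  V <- U^cfg$power_law_exponent
  D <- dct_matrix(cfg$pncc_dims, cfg$gammatone_channels)
  D %*% V
}

#' PNCC of a single frame
#'
#' @inheritParams pncc_batch
#' @param frame Numeric vector of samples.
#' @return Numeric vector of `pncc_dims` coefficients.
#' @export
pncc <- function(frame, cfg = feature_config(), sample_rate = 4000) {
  drop(pncc_batch(matrix(frame, ncol = 1), cfg, sample_rate))
}

# Levinson-Durbin solution of the Toeplitz normal equations, vectorized
# across frames.  `r` is a (order+1) x n matrix of autocorrelations
# (lags 0..order).  Prediction convention x[t] ~ sum_k a_k x[t-k], i.e.
# A(z) = 1 - sum a_k z^-k.  Frames with r0 <= floor get zero
# coefficients and gain = floor.
levinson_batch <- function(r, order, power_floor = 1e-12) {
  n <- ncol(r)
  a <- matrix(0, order, n)
  live <- r[1, ] > power_floor
  E <- ifelse(live, r[1, ], 1) # dummy 1 avoids 0/0 on dead frames
  for (m in seq_len(order)) {
    if (m == 1) {
      acc <- r[2, ]
    } else {
      acc <- r[m + 1, ] -
        colSums(a[1:(m - 1), , drop = FALSE] * r[m:2, , drop = FALSE])
    }
    k <- ifelse(E > 0, acc / E, 0)
    if (m > 1) {
      a_prev <- a[1:(m - 1), , drop = FALSE]
      a[1:(m - 1), ] <- a_prev -
        rep(k, each = m - 1) * a_prev[(m - 1):1, , drop = FALSE]
    }
    a[m, ] <- k
    E <- E * (1 - k^2)
    E[E < 0] <- 0
  }
  a[, !live] <- 0
  gain <- ifelse(live, pmax(E, power_floor), power_floor)
  list(coefficients = a, gain = gain)
}

#' Linear-prediction coefficients of a batch of frames
#'
#' Autocorrelation method: frames are pre-emphasized and windowed, the
#' biased autocorrelation is taken to lag `order`, and the Toeplitz
#' normal equations are solved by Levinson-Durbin recursion (vectorized
#' across frames).  Convention: `A(z) = 1 - sum_k a_k z^-k`, so an AR(1)
#' process `x[t] = 0.9 x[t-1] + e[t]` yields `a1` near +0.9.  Silent
#' frames give all-zero coefficients and gain = `power_floor`.
#'
#' @inheritParams pncc_batch
#' @param order LPC order (defaults to `cfg$lpc_order`); must be smaller
#'   than the frame length.
#' @return List with `coefficients` (order x n matrix) and `gain`
#'   (length-n vector of residual powers).
#' @export
lpc_batch <- function(frames, cfg = feature_config(), order = cfg$lpc_order) {
  if (inherits(frames, "bs_frames")) frames <- frames$frames
  win <- nrow(frames)
  if (order >= win) stop("LPC order must be smaller than the frame length")
  if (ncol(frames) == 0) {
    return(list(coefficients = matrix(numeric(0), order, 0), gain = numeric(0)))
  }
  z <- condition_frames(frames, cfg)
  r <- matrix(0, order + 1, ncol(z))
  for (kk in 0:order) {
    r[kk + 1, ] <- colSums(z[seq_len(win - kk), , drop = FALSE] *
                           z[(kk + 1):win, , drop = FALSE])
  }
  levinson_batch(r, order, cfg$power_floor)
}

#' LPC of a single frame
#'
#' @inheritParams lpc_batch
#' @param frame Numeric vector of samples.
#' @return List with `coefficients` (length `order`) and `gain`.
#' @export
lpc <- function(frame, order = 20, cfg = feature_config(lpc_order = order)) {
  out <- lpc_batch(matrix(frame, ncol = 1), cfg, order)
  list(coefficients = drop(out$coefficients), gain = out$gain)
}

# Cepstrum recursion from LPC coefficients, vectorized across frames.
# a: order x n; returns n_cep x n (c_1..c_n_cep; the gain/energy term
# c_0 is excluded so the LPCC block is gain-invariant).
lpcc_batch <- function(a, n_cep = 20) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  p <- nrow(a)
  n <- ncol(a)
  cc <- matrix(0, n_cep, n)
  for (m in seq_len(n_cep)) {
    acc <- if (m <= p) a[m, ] else numeric(n)
    k_lo <- max(1L, m - p)
    if (m > 1) {
      for (k in k_lo:(m - 1)) {
        acc <- acc + (k / m) * cc[k, ] * a[m - k, ]
      }
    }
    cc[m, ] <- acc
  }
  cc
}

#' Linear-prediction cepstral coefficients
#'
#' Standard recursion from LPC coefficients (`A(z) = 1 - sum a_k z^-k`):
#' `c_1 = a_1`; for `n <= order`,
#' `c_n = a_n + sum_{k=1}^{n-1} (k/n) c_k a_{n-k}`; beyond the order the
#' `a_n` term drops and the sum starts at `n - order`.  The gain term
#' `c_0 = log(gain)` is excluded from the returned coefficients so the
#' feature block does not depend on the absolute signal level.
#'
#' @param lpc_coeffs Numeric vector of LPC coefficients (or an
#'   order x n matrix for a batch).
#' @param gain LPC residual gain (unused by the recursion; kept in the
#'   signature because it defines the omitted `c_0` term).
#' @param n_cep Number of cepstral coefficients to return (default 20).
#' @return Numeric vector (or `n_cep` x n matrix) of coefficients
#'   `c_1..c_{n_cep}`.
#' @export
lpcc <- function(lpc_coeffs, gain = 1, n_cep = 20) {
  out <- lpcc_batch(lpc_coeffs, n_cep)
  if (ncol(out) == 1) drop(out) else out
}

#' Full 40-dimensional feature matrix for a recording's frames
#'
#' Concatenates `pncc_dims` PNCCs and `lpcc_dims` LPCCs per frame.
#'
#' @param frames A `bs_frames` object from [segment_frames()], or a
#'   numeric matrix with one frame per column.
#' @param cfg A [feature_config()].
#' @param sample_rate Required when `frames` is a plain matrix.
#' @return n x (pncc_dims + lpcc_dims) numeric matrix, one row per
#'   segment, columns named `pncc1.. lpcc1..`.  All entries finite.
#' @export
feature_matrix <- function(frames, cfg = feature_config(), sample_rate = NULL) {
  if (inherits(frames, "bs_frames")) {
    sample_rate <- frames$sample_rate
    fr <- frames$frames
  } else {
    fr <- frames
    if (is.null(sample_rate)) stop("sample_rate required")
  }
  pn <- pncc_batch(fr, cfg, sample_rate)
  lp <- lpc_batch(fr, cfg)
  ce <- lpcc_batch(lp$coefficients, cfg$lpcc_dims)
  out <- t(rbind(pn, ce))
  colnames(out) <- c(paste0("pncc", seq_len(cfg$pncc_dims)),
                     paste0("lpcc", seq_len(cfg$lpcc_dims)))
  if (any(!is.finite(out))) stop("non-finite feature values produced")
  out
}

#' Feature vector of a single segment
#'
#' @inheritParams feature_matrix
#' @param frame Numeric vector of samples.
#' @return Named numeric vector of length `pncc_dims + lpcc_dims`.
#' @export
feature_vector <- function(frame, cfg = feature_config(), sample_rate = 4000) {
  drop(feature_matrix(matrix(frame, ncol = 1), cfg, sample_rate))
}

#' Write a per-segment feature dump
#'
#' CSV layout: `segment_index,start_s,f1..f40` (0-based segment index).
#'
#' @param features n x d feature matrix.
#' @param start_times Segment start times in seconds.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, start_times, path) {
  df <- data.frame(segment_index = seq_len(nrow(features)) - 1L,
                   start_s = start_times)
  feat <- as.data.frame(features)
  names(feat) <- paste0("f", seq_len(ncol(features)))
  utils::write.csv(cbind(df, feat), path, row.names = FALSE)
  invisible(path)
}
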