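# Shared fixtures built in code.

# A deterministic sine recording.
sine_recording <- function(freq, fs = 4000, dur = 1, amp = 1) {
  bs_recording(amp * sin(2 * pi * freq * (0:(fs * dur - 1)) / fs), fs)
}

# Peak amplitude of x after dropping edge transients.
steady_peak <- function(x, frac = 0.2) {
  n <- length(x)
  i <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  max(abs(x[i]))
}
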