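#' Hamming window
#'
#' Periodic-symmetric hamming taper, `0.54 - 0.46 cos(2*pi*k/(n-1))`.
#'
#' @param n window length in samples (or frames).
#' @return numeric vector of length `n`.
#' @keywords internal
hamming_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

# Smoother lengths in frames, round-half-up so the canonical durations map
# to {0.1 s -> 6, 0.25 s -> 16, 1.0 s -> 63} at 62.5 frames/s.
smoother_length <- function(duration_s, frame_rate) {
  max(1L, as.integer(floor(duration_s * frame_rate + 0.5)))
}

# y[t] = sum_j k[j] * x[t - L + j]  (FIR sliding sum, causal).
# Frames with an incomplete window (t < L) are returned as 0.
fir_sliding_sum <- function(x, k) {
  L <- length(k)
  if (L == 1) return(x * k)
  y <- as.numeric(stats::filter(x, rev(k), method = "convolution", sides = 1))
  y[seq_len(min(L - 1L, length(y)))] <- 0
  y
}

#' Causal hamming smoothing
#'
#' Unit-sum hamming-weighted causal FIR. The first `n - 1` output frames use
#' a renormalized partial kernel (only past samples), so the output at frame
#' t depends on input frames <= t only.
#'
#' @param x numeric series.
#' @param n kernel length in frames.
#' @return smoothed series, same length as `x`.
#' @keywords internal
causal_smooth <- function(x, n) {
  if (n <= 1) return(x)
  h <- hamming_window(n)
  h <- h / sum(h)
  xp <- c(rep(0, n - 1L), x)
  num <- as.numeric(stats::filter(xp, rev(h), method = "convolution", sides = 1))
  num <- num[n:(n - 1L + length(x))]
  cs <- cumsum(h)
  den <- rep(1, length(x))
  head_idx <- seq_len(min(n - 1L, length(x)))
  den[head_idx] <- cs[n] - cs[n - head_idx]
  num / den
}

# Zero-phase (symmetric, edge-renormalized) hamming smoothing; used for
# offline template denoising only, never on streaming outputs.
symmetric_smooth <- function(x, n) {
  if (n <= 1) return(x)
  h <- hamming_window(n)
  nx <- length(x)
  half_lo <- (n - 1L) %/% 2L
  half_hi <- n - 1L - half_lo
  xp <- c(rep(0, half_lo), x, rep(0, half_hi))
  ones <- c(rep(0, half_lo), rep(1, nx), rep(0, half_hi))
  num <- as.numeric(stats::filter(xp, h, method = "convolution", sides = 2))
  den <- as.numeric(stats::filter(ones, h, method = "convolution", sides = 2))
  (num / den)[half_lo + seq_len(nx)]
}

# Short-time log-power spectrogram of one channel: hamming-tapered
# magnitude-squared FFT per sliding window, restricted to the requested
# bins. Returns a length(bins) x n_frames matrix.
stft_logpower <- function(x, grid, win, bins, taper = hamming_window(win)) {
  idx <- outer(seq_len(win) - 1L, grid$starts, `+`)
  frames <- matrix(x[idx], nrow = win) * taper
  spec <- stats::mvfft(frames)[bins, , drop = FALSE]
  p <- Re(spec)^2 + Im(spec)^2
  log(pmax(p, .Machine$double.xmin))
}

# FFT bin center frequencies for an n-point transform at `rate` Hz
# (non-negative half only).
fft_bin_freqs <- function(n, rate) {
  (seq_len(n %/% 2 + 1) - 1) * rate / n
}

# Tiny FNV-1a hash for config/session fingerprints (no external digest
# dependency; not cryptographic).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) %% 2^31
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
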