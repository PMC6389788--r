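# Pooled baseline frames: frames whose analysis window lies entirely inside
# [stimulus_onset - 1 s, stimulus_onset) of some trial.
baseline_frame_idx <- function(grid, stimulus_onsets) {
  eps <- 1e-9
  idx <- lapply(stimulus_onsets, function(o) {
    which(grid$start_times >= o - 1 - eps & grid$times <= o - eps)
  })
  sort(unique(unlist(idx)))
}

#' Causal high-gamma feature extraction
#'
#' Slides a 128 ms hamming-tapered FFT window by 16 ms increments over every
#' channel, log-transforms the magnitude-squared spectrum, z-scores each
#' frequency bin per channel against the pooled pre-stimulus baseline (the
#' union of frames whose window lies in the 1 s before each stimulus onset),
#' averages the bins whose center frequency falls in the high-gamma band
#' (70-110 Hz inclusive), and re-z-scores the band-averaged feature per
#' channel against the same baseline frames. The frame time of each output
#' frame is the time of the last sample in its window, so the stream is
#' strictly causal.
#'
#' @param recording an [ecog_recording()] (typically after
#'   [common_average_reference()] and [select_channels()]).
#' @param events an [event_table()]; stimulus onsets define the baseline.
#' @param band band edges in Hz (bin membership by center frequency,
#'   inclusive).
#' @param win_s,hop_s analysis window and hop, seconds.
#' @return list of class `feature_stream`: `z` (channels x frames),
#'   `frame_rate` (62.5 Hz at the defaults), `frame_times`,
#'   `baseline_frames` (indices of pooled-baseline frames), `channels`,
#'   and `baseline_stats` (per-channel-per-bin and band mean/SD).
#' @export
extract_high_gamma <- function(recording, events, band = c(70, 110),
                               win_s = 0.128, hop_s = 0.016) {
  stopifnot(inherits(recording, "ecog_recording"))
  rate <- recording$rate
  if (rate < 256) stop("rate must be >= 256 Hz for the 70-110 Hz band")
  win <- round(rate * win_s)
  hop <- round(rate * hop_s)
  grid <- frame_grid(ncol(recording$signal), rate, win, hop)
  taper <- hamming_window(win)
  freqs <- fft_bin_freqs(win, rate)
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("no FFT bins fall inside the requested band")
  bl <- baseline_frame_idx(grid, events$stimulus_onset)
  if (!length(bl)) stop("no baseline frames: events start too early in the recording")

  n_ch <- nrow(recording$signal)
  z <- matrix(NA_real_, n_ch, grid$n)
  bin_mean <- matrix(NA_real_, n_ch, length(bins))
  bin_sd <- matrix(NA_real_, n_ch, length(bins))
  band_mean <- numeric(n_ch)
  band_sd <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    lp <- stft_logpower(recording$signal[ch, ], grid, win, bins, taper)
    mu <- rowMeans(lp[, bl, drop = FALSE])
    s <- apply(lp[, bl, drop = FALSE], 1, stats::sd)
    if (any(s <= 0)) {
      stop("zero baseline SD on channel ", recording$channels$label[ch])
    }
    bin_mean[ch, ] <- mu
    bin_sd[ch, ] <- s
    hb <- colMeans((lp - mu) / s)
    band_mean[ch] <- mean(hb[bl])
    band_sd[ch] <- stats::sd(hb[bl])
    if (band_sd[ch] <= 0) {
      stop("zero baseline SD on channel ", recording$channels$label[ch])
    }
    z[ch, ] <- (hb - band_mean[ch]) / band_sd[ch]
  }
  rownames(z) <- recording$channels$label
  structure(
    list(
      z = z, frame_rate = rate / hop, frame_times = grid$times,
      baseline_frames = bl, channels = recording$channels,
      baseline_stats = list(
        bin_freqs = freqs[bins], bin_mean = bin_mean, bin_sd = bin_sd,
        band_mean = band_mean, band_sd = band_sd,
        # baseline stats of the final (re-z-scored) feature; 0/1 by
        # construction, kept explicit so downstream significance masks are
        # on the right scale
        feature_mean = rep(0, n_ch), feature_sd = rep(1, n_ch),
        n_baseline_frames = length(bl)
      )
    ),
    class = "feature_stream"
  )
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("<feature_stream> %d channels x %d frames @ %g frames/s (%d baseline frames)\n",
              nrow(x$z), ncol(x$z), x$frame_rate, length(x$baseline_frames)))
  invisible(x)
}

#' Microphone voice-onset detection
#'
#' Per trial, finds the first time after stimulus onset (and before the next
#' trial) at which the smoothed 250-450 Hz microphone band-power, z-scored
#' to the pooled pre-stimulus mic baseline, exceeds `threshold_sd`, then
#' backtracks along the contiguous super-threshold run of the unsmoothed
#' series to report the earliest frame whose window touches the burst.
#' Trials with no crossing get a missing voice onset (that is data, not an
#' error: synchronized microphone recordings do fail).
#'
#' @param recording an [ecog_recording()] with a mic track.
#' @param events an [event_table()].
#' @param band mic speech band, Hz.
#' @param threshold_sd detection threshold in baseline SD units.
#' @param smooth_s causal smoothing applied before thresholding, seconds.
#' @param win_s,hop_s analysis window and hop, seconds (kept identical to
#'   the neural feature grid so mic onsets live on the same frame raster).
#' @return `events` with the `voice_onset` column filled (NA where no
#'   crossing occurred).
#' @export
mic_voice_onsets <- function(recording, events, band = c(250, 450),
                             threshold_sd = 5, smooth_s = 0.05,
                             win_s = 0.128, hop_s = 0.016) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (is.null(recording$mic)) stop("recording has no mic track")
  rate <- recording$rate
  win <- round(rate * win_s)
  hop <- round(rate * hop_s)
  grid <- frame_grid(length(recording$mic), rate, win, hop)
  freqs <- fft_bin_freqs(win, rate)
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("mic band has no FFT bins below Nyquist")
  # rectangular window: burst energy arriving at the causal window edge
  # must register immediately, and band-power detection needs no leakage
  # control
  p <- colSums(exp(stft_logpower(recording$mic, grid, win, bins,
                                 taper = rep(1, win))))
  bl <- baseline_frame_idx(grid, events$stimulus_onset)
  if (!length(bl)) stop("no baseline frames for the mic track")
  z_raw <- (p - mean(p[bl])) / stats::sd(p[bl])
  z <- causal_smooth(z_raw, smoother_length(smooth_s, rate / hop))

  n_trials <- nrow(events)
  onset_out <- rep(NA_real_, n_trials)
  ends <- c(events$stimulus_onset[-1], max(grid$times) + 1)
  for (tr in seq_len(n_trials)) {
    in_win <- which(grid$times > events$stimulus_onset[tr] &
                      grid$times < ends[tr])
    if (!length(in_win)) next
    cross <- in_win[which(z[in_win] > threshold_sd)[1]]
    if (is.na(cross)) next
    g <- cross
    lo <- in_win[1]
    while (g > lo && z_raw[g - 1] > threshold_sd) g <- g - 1L
    # the burst started somewhere inside frame g's trailing hop; report the
    # midpoint of that uncertainty interval (unbiased to +/- half a hop)
    onset_out[tr] <- grid$times[g] - hop / (2 * rate)
  }
  events$voice_onset <- onset_out
  events
}

#' Epoch a feature stream around alignment times
#'
#' Cuts fixed-length response windows out of a feature stream: the frame
#' whose frame time is nearest each alignment time becomes the center
#' (offset 0), flanked by `halfwidth` frames on each side (63 frames
#' total at the default, ~1 s at 62.5 frames/s). Trials with a missing
#' alignment time, or whose window exceeds the stream bounds, are dropped
#' with a warning.
#'
#' @param stream a `feature_stream`.
#' @param align_times alignment times in seconds (NA allowed).
#' @param halfwidth frames on each side of the center frame.
#' @return array trials x channels x (2*halfwidth+1), with attributes
#'   `kept` (indices into `align_times`) and `center_frames`.
#' @export
epoch_stream <- function(stream, align_times, halfwidth = 31L) {
  stopifnot(inherits(stream, "feature_stream"))
  n_frames <- ncol(stream$z)
  centers <- rep(NA_integer_, length(align_times))
  ok_time <- !is.na(align_times)
  centers[ok_time] <- vapply(align_times[ok_time], function(s) {
    which.min(abs(stream$frame_times - s))
  }, integer(1))
  keep <- ok_time & !is.na(centers) &
    centers - halfwidth >= 1L & centers + halfwidth <= n_frames
  if (!all(keep)) {
    warning(sum(!keep), " trial(s) dropped (missing alignment time or window out of bounds)")
  }
  kept <- which(keep)
  L <- 2L * halfwidth + 1L
  out <- array(NA_real_, c(length(kept), nrow(stream$z), L),
               dimnames = list(NULL, rownames(stream$z), NULL))
  for (i in seq_along(kept)) {
    c0 <- centers[kept[i]]
    out[i, , ] <- stream$z[, (c0 - halfwidth):(c0 + halfwidth), drop = FALSE]
  }
  attr(out, "kept") <- kept
  attr(out, "center_frames") <- centers[kept]
  attr(out, "halfwidth") <- halfwidth
  out
}

# Map an event time (seconds) to the filter-output frame that carries it:
# nearest feature frame plus the window-center offset of the filter outputs.
event_time_to_output_frame <- function(frame_times, s, center_offset) {
  vapply(s, function(si) {
    if (is.na(si)) return(NA_integer_)
    as.integer(which.min(abs(frame_times - si)) + center_offset)
  }, integer(1))
}
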