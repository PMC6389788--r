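#' Causal peak-picking on the VAD series
#'
#' Standardizes the VAD series against its values over the pooled baseline
#' frames using robust statistics (median, and IQR/1.349 as the SD
#' estimate: a baseline frame's trailing 1 s window can brush the previous
#' trial's response tail, and a plain SD is dominated by how often that
#' happens in a given session), then walks the series causally: after the z-scored signal
#' crosses `threshold_sd` upward, the next sign change of the first
#' difference from positive to negative (a local maximum) marks a
#' detection; the detector re-arms only once the signal has fallen back
#' below the threshold. Detection times are reported `event_offset` frames
#' before the peak frame (window center plus smoother group delay, ~1 s).
#'
#' When the input is a `filter_outputs` object, the reported event time is
#' additionally refined: within the trailing smoother window of the
#' smoothed peak (past frames only, so still causal), the argmax of the
#' unsmoothed squared correlation locates the peak without the smoothing
#' kernel's localization jitter, and the 31-frame window-center offset
#' maps it to the event time.
#'
#' @param v_series a `filter_outputs` object, or a numeric VAD series (in
#'   which case `frame_times` and `baseline_frames` must be supplied).
#' @param threshold_sd detection threshold, baseline SD units (>= 0).
#' @param baseline_frames frame indices defining the baseline.
#' @param frame_times frame times, seconds.
#' @param event_offset frames subtracted from the peak frame when reporting
#'   the event time; defaults to the `vad_event_offset` attribute.
#' @return data.frame of class `detection_list` with columns `time`
#'   (seconds, strictly increasing), `frame` (peak frame index), `score`
#'   (z-scored VAD at the peak); attribute `threshold_sd`.
#' @export
causal_peak_pick <- function(v_series, threshold_sd, baseline_frames = NULL,
                             frame_times = NULL, event_offset = NULL) {
  v_raw <- NULL
  center_offset <- 0L
  smoother_len <- 1L
  if (inherits(v_series, "filter_outputs")) {
    if (is.null(baseline_frames)) baseline_frames <- v_series$baseline_frames
    if (is.null(frame_times)) frame_times <- v_series$frame_times
    if (is.null(event_offset)) event_offset <- attr(v_series, "vad_event_offset")
    v_raw <- v_series$v_raw
    center_offset <- attr(v_series, "center_offset")
    smoother_len <- attr(v_series, "v_smoother_len")
    v <- v_series$v
  } else {
    v <- as.numeric(v_series)
    if (is.null(event_offset)) event_offset <- 0L
  }
  if (threshold_sd < 0) stop("threshold_sd must be >= 0")
  if (is.null(baseline_frames) || !length(baseline_frames)) {
    stop("empty baseline_frames")
  }
  if (is.null(frame_times)) frame_times <- seq_along(v)
  mu <- stats::median(v[baseline_frames])
  sigma <- stats::IQR(v[baseline_frames]) / 1.349
  if (sigma <= 0) sigma <- stats::sd(v[baseline_frames])
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate baseline for the VAD series")
  z <- (v - mu) / sigma
  n <- length(z)
  # upward threshold crossings and local maxima, then the state machine:
  # each crossing arms the detector; the first local max at/after it fires;
  # re-arming requires a fresh upward crossing (i.e. a dip below threshold)
  up <- which(z[-1] >= threshold_sd & z[-n] < threshold_sd) + 1L
  if (length(z) && z[1] >= threshold_sd) up <- unique(c(1L, up))
  d <- diff(z)
  peaks_all <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(up) || !length(peaks_all)) {
    frames <- integer(0)
  } else {
    hit <- peaks_all[findInterval(up - 1L, peaks_all) + 1L]
    frames <- sort(unique(hit[!is.na(hit)]))
  }
  frames <- frames[frames > event_offset]
  if (!is.null(v_raw) && length(frames)) {
    # causal refinement: raw-correlation argmax in the trailing smoother
    # window of each smoothed peak
    raw_frames <- vapply(frames, function(t) {
      w <- max(1L, t - smoother_len + 1L):t
      w[which.max(v_raw[w])]
    }, integer(1))
    keep <- raw_frames > center_offset
    frames <- frames[keep]
    raw_frames <- raw_frames[keep]
    out <- data.frame(
      time = frame_times[raw_frames - center_offset],
      frame = frames,
      raw_frame = raw_frames,
      score = z[frames]
    )
    ord <- order(out$time)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$time), , drop = FALSE]
  } else {
    out <- data.frame(
      time = frame_times[frames - event_offset],
      frame = frames,
      raw_frame = frames - event_offset + center_offset,
      score = z[frames]
    )
  }
  rownames(out) <- NULL
  attr(out, "threshold_sd") <- threshold_sd
  class(out) <- c("detection_list", "data.frame")
  out
}

# Injective greedy matching of detections to true onsets: each onset takes
# the earliest unused detection within +/- tol; everything else is a false
# positive.
match_detections <- function(det_times, true_onsets, tol = 0.1) {
  used <- rep(FALSE, length(det_times))
  matched_det <- rep(NA_integer_, length(true_onsets))
  for (i in seq_along(true_onsets)) {
    cand <- which(!used & abs(det_times - true_onsets[i]) <= tol + 1e-9)
    if (length(cand)) {
      j <- cand[which.min(det_times[cand])]
      used[j] <- TRUE
      matched_det[i] <- j
    }
  }
  data.frame(
    onset = true_onsets,
    detection = ifelse(is.na(matched_det), NA_real_, det_times[matched_det]),
    error = ifelse(is.na(matched_det), NA_real_,
                   det_times[matched_det] - true_onsets)
  )
}

#' VAD performance over a threshold sweep
#'
#' For each threshold, detections within +/- `tol` seconds of a true onset
#' are true positives (each onset matched at most once, to the earliest
#' such detection); every other detection -- including extra detections
#' around an already-matched onset -- is a false positive. The false
#' positive count is normalized per utterance.
#'
#' @param v_series a `filter_outputs` object (or numeric VAD series; see
#'   [causal_peak_pick()]).
#' @param true_onsets ground-truth utterance onset times, seconds.
#' @param thresholds threshold sweep grid, baseline SD units.
#' @param tol matching tolerance, seconds.
#' @param ... passed on to [causal_peak_pick()].
#' @return data.frame of class `vad_curve`: `threshold`, `sensitivity`,
#'   `fp_per_utterance`, `n_detections`.
#' @export
vad_performance <- function(v_series, true_onsets,
                            thresholds = seq(0, 20, by = 0.25),
                            tol = 0.1, ...) {
  if (!length(true_onsets)) stop("true_onsets must be non-empty")
  rows <- lapply(thresholds, function(th) {
    det <- causal_peak_pick(v_series, th, ...)
    m <- match_detections(det$time, true_onsets, tol)
    tp <- sum(!is.na(m$detection))
    data.frame(
      threshold = th,
      sensitivity = tp / length(true_onsets),
      fp_per_utterance = (nrow(det) - tp) / length(true_onsets),
      n_detections = nrow(det)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vad_curve", "data.frame")
  out
}

#' Equal-error-rate operating threshold
#'
#' Returns the swept threshold minimizing |miss rate - false positives per
#' utterance|; ties are broken toward the higher (more specific)
#' threshold.
#'
#' @param curve a [vad_performance()] result.
#' @return the selected threshold (scalar).
#' @export
select_threshold_eer <- function(curve) {
  if (!nrow(curve)) stop("empty VAD curve")
  gap <- abs((1 - curve$sensitivity) - curve$fp_per_utterance)
  best <- which(gap <= min(gap) + 1e-12)
  curve$threshold[best[which.max(curve$threshold[best])]]
}
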