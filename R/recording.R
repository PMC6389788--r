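#' Multichannel recording container
#'
#' Bundles a channels x samples signal matrix (microvolts), its sampling
#' rate, per-channel metadata (label, region-of-interest tag, excluded
#' flag), and the synchronized single-channel microphone track.
#'
#' @param signal numeric matrix, channels x samples.
#' @param rate sampling rate in Hz (> 0).
#' @param channels data.frame with columns `label` (unique character),
#'   `roi` (one of `"vSMC"`, `"STG"`, `"other"`), `excluded` (logical);
#'   one row per signal row.
#' @param mic numeric vector, same number of samples as `signal`, or NULL.
#' @param session_id character fingerprint used by the train/test leakage
#'   guard; defaults to a hash of the signal dimensions.
#' @return object of class `ecog_recording`.
#' @export
ecog_recording <- function(signal, rate, channels, mic = NULL, session_id = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) stop("`rate` must be > 0")
  req <- c("label", "roi", "excluded")
  missing_cols <- setdiff(req, names(channels))
  if (length(missing_cols)) {
    stop("channel table missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(channels) != nrow(signal)) {
    stop("channel table rows (", nrow(channels), ") != signal channels (",
         nrow(signal), ")")
  }
  if (anyDuplicated(channels$label)) stop("channel labels must be unique")
  bad_roi <- setdiff(unique(channels$roi), c("vSMC", "STG", "other"))
  if (length(bad_roi)) {
    stop("unknown roi tag(s): ", paste(bad_roi, collapse = ", "))
  }
  channels$excluded <- as.logical(channels$excluded)
  if (!any(!channels$excluded)) stop("at least one channel must be non-excluded")
  if (!is.null(mic)) {
    if (length(mic) != ncol(signal)) stop("`mic` length must equal sample count")
    mic <- as.numeric(mic)
  }
  rownames(signal) <- channels$label
  if (is.null(session_id)) session_id <- paste0("rec-", fnv1a(dim(signal)))
  structure(
    list(signal = signal, rate = rate, channels = channels, mic = mic,
         session_id = session_id),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf(
    "<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), %s mic\n",
    nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate,
    if (is.null(x$mic)) "no" else "with"
  ))
  cat("  ROI:",
      paste(sprintf("%s=%d", names(table(x$channels$roi)), table(x$channels$roi)),
            collapse = " "),
      sprintf(" excluded=%d\n", sum(x$channels$excluded)))
  cat("  session_id:", x$session_id, "\n")
  invisible(x)
}

#' Trial event table
#'
#' Validates and classes a per-trial event table: stimulus onsets, syllable
#' labels, block ids, and (optionally) microphone-derived voice onsets.
#'
#' @param trial integer trial ids.
#' @param stimulus_onset stimulus presentation times, seconds, strictly
#'   increasing.
#' @param label syllable labels drawn from [syllable_inventory()].
#' @param block block ids.
#' @param voice_onset voice onset times in seconds, NA when the microphone
#'   detection failed or has not been run yet.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(trial, stimulus_onset, label, block,
                        voice_onset = rep(NA_real_, length(trial))) {
  if (is.unsorted(stimulus_onset, strictly = TRUE)) {
    stop("stimulus onsets must be strictly increasing")
  }
  bad <- setdiff(unique(label), syllable_inventory()$label)
  if (length(bad)) {
    stop("event label(s) outside the syllable inventory: ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(
    trial = as.integer(trial), stimulus_onset = as.numeric(stimulus_onset),
    label = as.character(label), block = as.integer(block),
    voice_onset = as.numeric(voice_onset), stringsAsFactors = FALSE
  )
  class(out) <- c("event_table", "data.frame")
  out
}

#' Common-average re-referencing
#'
#' Subtracts, per sample, the mean over non-excluded channels from each
#' non-excluded channel. Excluded channels pass through unchanged and stay
#' flagged; the microphone track is untouched.
#'
#' @param recording an [ecog_recording()].
#' @return re-referenced `ecog_recording`.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "ecog_recording"))
  inc <- !recording$channels$excluded
  if (!any(inc)) stop("all channels excluded: nothing to re-reference")
  avg <- colMeans(recording$signal[inc, , drop = FALSE])
  recording$signal[inc, ] <-
    sweep(recording$signal[inc, , drop = FALSE], 2, avg)
  recording
}

#' Channel downselection by region of interest
#'
#' Retains channels whose ROI tag is in `rois`, that are not flagged
#' excluded, and that are not in `manual_exclude`. Channel ordering is
#' preserved.
#'
#' @param recording an [ecog_recording()].
#' @param rois subset of `c("vSMC", "STG")`.
#' @param manual_exclude character labels to drop in addition.
#' @return `ecog_recording` containing only the retained channels.
#' @export
select_channels <- function(recording, rois = c("vSMC", "STG"),
                            manual_exclude = character()) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (!all(rois %in% c("vSMC", "STG"))) {
    stop("`rois` must be a subset of {vSMC, STG}")
  }
  keep <- recording$channels$roi %in% rois &
    !recording$channels$excluded &
    !(recording$channels$label %in% manual_exclude)
  if (!any(keep)) stop("channel selection retained no channels")
  recording$signal <- recording$signal[keep, , drop = FALSE]
  recording$channels <- recording$channels[keep, , drop = FALSE]
  rownames(recording$channels) <- NULL
  recording
}
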