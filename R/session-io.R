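#' Write a session to disk
#'
#' Persists a recording plus its event table as a plain-text session
#' directory: `meta.json` (rate, session id, channel count), `channels.csv`,
#' `events.csv`, `signal.tsv` (channels x samples, one row per channel) and
#' `mic.tsv`. The layout is open and language-neutral; values are written
#' at full precision so a write/read round trip is lossless to double
#' precision.
#'
#' @param recording an [ecog_recording()].
#' @param events an [event_table()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, events, path) {
  stopifnot(inherits(recording, "ecog_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "neurokws-session", version = 1L,
    rate = recording$rate, session_id = recording$session_id,
    n_channels = nrow(recording$signal), n_samples = ncol(recording$signal),
    has_mic = !is.null(recording$mic)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(recording$channels, file.path(path, "channels.csv"))
  write_events_csv(events, file.path(path, "events.csv"))
  data.table::fwrite(data.table::as.data.table(recording$signal),
                     file.path(path, "signal.tsv"),
                     sep = "\t", col.names = FALSE)
  if (!is.null(recording$mic)) {
    data.table::fwrite(data.table::data.table(mic = recording$mic),
                       file.path(path, "mic.tsv"),
                       sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' @param path session directory written by [write_session()].
#' @return list with elements `recording` and `events`.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a session directory (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("rate", "n_channels", "n_samples")) {
    if (is.null(meta[[field]])) stop("session meta.json missing required field: ", field)
  }
  channels <- as.data.frame(data.table::fread(file.path(path, "channels.csv")))
  for (field in c("label", "roi", "excluded")) {
    if (!field %in% names(channels)) {
      stop("session channel table missing required field: ", field)
    }
  }
  sig <- as.matrix(data.table::fread(file.path(path, "signal.tsv"),
                                     sep = "\t", header = FALSE))
  dimnames(sig) <- NULL
  if (nrow(sig) != meta$n_channels || ncol(sig) != meta$n_samples) {
    stop(sprintf("signal dimensions %dx%d disagree with meta (%dx%d)",
                 nrow(sig), ncol(sig), meta$n_channels, meta$n_samples))
  }
  mic <- NULL
  mic_path <- file.path(path, "mic.tsv")
  if (isTRUE(meta$has_mic)) {
    if (!file.exists(mic_path)) stop("session meta declares a mic track but mic.tsv is missing")
    mic <- data.table::fread(mic_path, sep = "\t", header = FALSE)[[1]]
  }
  events <- read_events_csv(file.path(path, "events.csv"))
  rec <- ecog_recording(sig, meta$rate, channels, mic = mic,
                        session_id = meta$session_id)
  list(recording = rec, events = events)
}

#' Export / import an event table as CSV
#'
#' @param events an [event_table()].
#' @param path CSV file path.
#' @return `path` (export) or an `event_table` (import).
#' @export
write_events_csv <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- as.data.frame(data.table::fread(path, na.strings = c("NA", "")))
  for (field in c("trial", "stimulus_onset", "label", "block")) {
    if (!field %in% names(ev)) stop("event table missing required field: ", field)
  }
  if (!"voice_onset" %in% names(ev)) ev$voice_onset <- NA_real_
  event_table(ev$trial, ev$stimulus_onset, ev$label, ev$block, ev$voice_onset)
}
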