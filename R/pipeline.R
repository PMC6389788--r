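#' Pipeline configuration
#'
#' Collects every tunable of the keyword-spotting pipeline with its
#' canonical default: high-gamma band 70-110 Hz, 128 ms / 16 ms analysis
#' window and hop, significance-mask cutoff z = 3.0, smoothing kernels
#' {0.1, 0.25, 1.0} s, 90% PCA variance, VAD threshold sweep 0-20 SD,
#' classifier threshold sweep -10..10, +/- 100 ms event tolerance, PA-I
#' aggressiveness C = 1 with 10 epochs.
#'
#' @param train_path,test_path session directories (see [write_session()]);
#'   may be NULL when sessions are passed to the fit/apply functions
#'   directly.
#' @param out_dir artifact output directory for [run_pipeline()].
#' @param rois ROIs retained by channel downselection.
#' @param band high-gamma band, Hz.
#' @param win_s,hop_s spectral analysis window and hop, seconds.
#' @param mask_z significance-mask cutoff.
#' @param smooth_template_s,smooth_y_s,smooth_v_s smoothing kernel
#'   durations, seconds.
#' @param pca_variance cumulative explained-variance target in (0, 1].
#' @param vad_sweep VAD threshold sweep range, SD units.
#' @param vad_step VAD sweep step.
#' @param theta_sweep classifier threshold sweep range.
#' @param tolerance_s event-matching tolerance, seconds.
#' @param C,epochs PA-I training constants.
#' @param halfwidth_frames competitor context half-width, frames.
#' @param seed master RNG seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(train_path = NULL, test_path = NULL,
                            out_dir = NULL,
                            rois = c("vSMC", "STG"), band = c(70, 110),
                            win_s = 0.128, hop_s = 0.016, mask_z = 3.0,
                            smooth_template_s = 0.1, smooth_y_s = 0.25,
                            smooth_v_s = 1.0, pca_variance = 0.90,
                            vad_sweep = c(0, 20), vad_step = 0.25,
                            theta_sweep = c(-10, 10), tolerance_s = 0.1,
                            C = 1, epochs = 10L, halfwidth_frames = 6L,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (pca_variance <= 0 || pca_variance > 1) {
    stop("pca_variance must be in (0, 1]")
  }
  if (band[2] <= band[1]) stop("invalid band")
  if (vad_sweep[1] < 0 || vad_sweep[2] <= vad_sweep[1]) stop("invalid vad_sweep")
  if (tolerance_s <= 0) stop("tolerance_s must be > 0")
  if (C <= 0 || epochs < 1) stop("invalid classifier constants")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Train the full keyword-spotting pipeline on one session
#'
#' Runs the training side of the pipeline on a (reading-style) session:
#' common-average referencing, ROI downselection, high-gamma feature
#' extraction normalized to the session's own pooled baseline, microphone
#' voice-onset detection, response epoching, template building, matched
#' filtering, PCA, one PA-I classifier per syllable (with an
#' equal-error-rate decision threshold each), and an equal-error-rate VAD
#' operating threshold.
#'
#' @param recording,events a session (see [generate_session()] /
#'   [read_session()]).
#' @param config a [pipeline_config()].
#' @param ablate_rectangular propagate the rectangular-window ablation
#'   into filtering.
#' @return list of class `kws_fit` holding every frozen artifact
#'   (templates, PCA, models, VAD threshold) plus the training-task
#'   intermediates needed for evaluation.
#' @export
fit_kws_pipeline <- function(recording, events, config = pipeline_config(),
                             ablate_rectangular = FALSE) {
  rec <- select_channels(common_average_reference(recording),
                         rois = config$rois)
  events <- mic_voice_onsets(recording, events, threshold_sd = 5,
                             win_s = config$win_s, hop_s = config$hop_s)
  feats <- extract_high_gamma(rec, events, band = config$band,
                              win_s = config$win_s, hop_s = config$hop_s)
  epochs_arr <- suppressWarnings(epoch_stream(feats, events$voice_onset))
  kept <- attr(epochs_arr, "kept")
  tset <- build_templates(
    epochs_arr, events$label[kept], feats$baseline_stats,
    channel_rois = rec$channels$roi, frame_rate = feats$frame_rate,
    z_cut = config$mask_z, smooth_s = config$smooth_template_s
  )
  fo <- matched_filter(feats, tset, ablate_rectangular = ablate_rectangular,
                       smooth_y_s = config$smooth_y_s,
                       smooth_v_s = config$smooth_v_s)
  pca <- fit_pca(fo$y, variance_target = config$pca_variance)
  pc <- pca_transform(fo, pca)
  # event-aligned template-output reads compensate the 0.25 s smoother's
  # group delay (training, ROC and detection classification all use the
  # same convention)
  read_offset <- attr(fo, "y_event_offset")

  keywords <- syllable_inventory()$label
  models <- list()
  for (i in seq_along(keywords)) {
    kw <- keywords[i]
    pairs <- build_training_pairs(pc, fo$frame_times, read_offset, events,
                                  kw, halfwidth = config$halfwidth_frames)
    model <- train_keyword_classifier(
      pairs, pc, kw, C = config$C, epochs = config$epochs,
      halfwidth = config$halfwidth_frames,
      seed = (config$seed + i) %% .Machine$integer.max
    )
    pos <- event_time_to_output_frame(
      fo$frame_times, events$voice_onset[events$label == kw], read_offset)
    neg <- event_time_to_output_frame(
      fo$frame_times, events$voice_onset[events$label != kw], read_offset)
    sil <- event_time_to_output_frame(
      fo$frame_times, events$stimulus_onset[events$label == kw] - 1.0,
      read_offset)
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]; sil <- sil[!is.na(sil)]
    model$theta <- select_theta_eer(
      score_keyword(model, pc[pos, , drop = FALSE]),
      score_keyword(model, pc[c(neg, sil), , drop = FALSE]),
      grid = seq(config$theta_sweep[1], config$theta_sweep[2], by = 0.1)
    )
    models[[kw]] <- model
  }

  vad_thresholds <- seq(config$vad_sweep[1], config$vad_sweep[2],
                        by = config$vad_step)
  mic_onsets <- events$voice_onset[!is.na(events$voice_onset)]
  vad_curve <- vad_performance(fo, mic_onsets, thresholds = vad_thresholds,
                               tol = config$tolerance_s)
  vad_threshold <- select_threshold_eer(vad_curve)

  structure(
    list(config = config, session_id = recording$session_id,
         channels = rec$channels, templates = tset, pca = pca,
         models = models, vad_threshold = vad_threshold,
         vad_curve = vad_curve, ablate_rectangular = ablate_rectangular,
         train = list(events = events, features = feats, outputs = fo,
                      pc = pc, read_offset = read_offset)),
    class = "kws_fit"
  )
}

#' @export
print.kws_fit <- function(x, ...) {
  cat(sprintf("<kws_fit> %d keyword models, %d discrimination templates, PCA k=%d, VAD threshold %.2f SD\n",
              length(x$models), length(x$templates$discrimination),
              x$pca$k, x$vad_threshold))
  invisible(x)
}

#' Apply frozen pipeline artifacts to a test session
#'
#' Applies the trained artifacts without recalibration: the test task is
#' re-referenced and downselected identically, its high-gamma features are
#' normalized to the test task's own pooled baseline (the one deliberate
#' per-task step), and the frozen templates and PCA are applied. A leakage
#' guard refuses to evaluate on the training session.
#'
#' @param fit a [fit_kws_pipeline()] result.
#' @param recording,events the test session.
#' @param allow_leakage disable the train/test identity guard (for
#'   deliberate in-sample diagnostics only).
#' @return list of class `kws_eval`: test-task events (with mic onsets),
#'   filter outputs, standardized PC series, `center_offset`.
#' @export
apply_kws_pipeline <- function(fit, recording, events, allow_leakage = FALSE) {
  stopifnot(inherits(fit, "kws_fit"))
  if (!allow_leakage && identical(recording$session_id, fit$session_id)) {
    stop("leakage guard: test session is identical to the training session (",
         fit$session_id, ")")
  }
  config <- fit$config
  rec <- select_channels(common_average_reference(recording),
                         rois = config$rois)
  events <- mic_voice_onsets(recording, events, threshold_sd = 5,
                             win_s = config$win_s, hop_s = config$hop_s)
  feats <- extract_high_gamma(rec, events, band = config$band,
                              win_s = config$win_s, hop_s = config$hop_s)
  fo <- matched_filter(feats, fit$templates,
                       ablate_rectangular = fit$ablate_rectangular,
                       smooth_y_s = config$smooth_y_s,
                       smooth_v_s = config$smooth_v_s)
  pc <- pca_transform(fo, fit$pca)
  structure(
    list(session_id = recording$session_id, events = events,
         features = feats, outputs = fo, pc = pc,
         center_offset = attr(fo, "center_offset"),
         read_offset = attr(fo, "y_event_offset")),
    class = "kws_eval"
  )
}

#' Per-keyword ROC evaluation on a test session
#'
#' ROC mode: classifier scores are read at the microphone-derived voice
#' onsets of the test task; positives are the keyword trials, negatives
#' all other utterances.
#'
#' @param fit a `kws_fit`.
#' @param eval a [apply_kws_pipeline()] result.
#' @return named list of [roc_auc()] results, one per keyword.
#' @export
evaluate_keyword_rocs <- function(fit, eval) {
  state <- pipeline_state(fit, eval)
  out <- lapply(names(fit$models), function(kw) {
    pos <- ev_frames(state, "test", kw, TRUE)
    neg <- ev_frames(state, "test", kw, FALSE)
    roc_auc(score_keyword(fit$models[[kw]], eval$pc[pos, , drop = FALSE]),
            score_keyword(fit$models[[kw]], eval$pc[neg, , drop = FALSE]),
            thresholds = seq(fit$config$theta_sweep[1],
                             fit$config$theta_sweep[2], by = 0.1))
  })
  names(out) <- names(fit$models)
  out
}

# Frozen-state bundle consumed by bootstrap_null_auc / ev_frames.
pipeline_state <- function(fit, eval) {
  list(
    pc_train = fit$train$pc, events_train = fit$train$events,
    frame_times_train = fit$train$outputs$frame_times,
    pc_test = eval$pc, events_test = eval$events,
    frame_times_test = eval$outputs$frame_times,
    read_offset = fit$train$read_offset,
    C = fit$config$C, epochs = fit$config$epochs,
    halfwidth = fit$config$halfwidth_frames
  )
}

#' Simulated keyword spotting with neural VAD times
#'
#' Runs the causal peak-picker on the test session's VAD series at the
#' trained operating threshold, classifies the PC feature vector of every
#' detection with each keyword model, and scores the result against the
#' test task's ground-truth (microphone-derived) onsets: a keyword trial
#' counts as detected when a keyword-classified detection falls within
#' +/- `tolerance_s` of its onset (matched at most once); every other
#' keyword-classified detection is a false keyword detection, normalized
#' per utterance.
#'
#' @param fit a `kws_fit`.
#' @param eval a [apply_kws_pipeline()] result (the leakage guard ran when
#'   it was built).
#' @param vad_threshold VAD operating threshold; defaults to the trained
#'   equal-error-rate threshold.
#' @return data.frame of class `kws_report`: per keyword, `n_keyword_trials`,
#'   `detection_fraction`, `false_per_utterance`; attribute
#'   `vad_threshold`.
#' @export
simulate_kws <- function(fit, eval, vad_threshold = fit$vad_threshold) {
  stopifnot(inherits(fit, "kws_fit"), inherits(eval, "kws_eval"))
  tol <- fit$config$tolerance_s
  det <- causal_peak_pick(eval$outputs, vad_threshold)
  # classifier features at the raw-correlation peak frame plus the 0.25 s
  # smoother delay: the same event-to-frame convention training uses
  feat_frames <- det$raw_frame + (eval$read_offset - eval$center_offset)
  ok <- feat_frames >= 1 & feat_frames <= nrow(eval$pc)
  det <- det[ok, , drop = FALSE]
  feat_frames <- feat_frames[ok]
  ev <- eval$events
  n_utt <- sum(!is.na(ev$voice_onset))
  rows <- lapply(names(fit$models), function(kw) {
    model <- fit$models[[kw]]
    if (nrow(det)) {
      scores <- score_keyword(model, eval$pc[feat_frames, , drop = FALSE])
      kw_det_times <- det$time[scores > model$theta]
    } else {
      kw_det_times <- numeric(0)
    }
    kw_onsets <- ev$voice_onset[ev$label == kw & !is.na(ev$voice_onset)]
    m <- match_detections(kw_det_times, kw_onsets, tol)
    tp <- sum(!is.na(m$detection))
    data.frame(
      keyword = kw, n_keyword_trials = length(kw_onsets),
      detection_fraction = if (length(kw_onsets)) tp / length(kw_onsets) else NA_real_,
      false_per_utterance = (length(kw_det_times) - tp) / max(n_utt, 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "vad_threshold") <- vad_threshold
  attr(out, "n_detections") <- nrow(det)
  class(out) <- c("kws_report", "data.frame")
  out
}
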