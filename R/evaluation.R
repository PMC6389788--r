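# AUC as the Mann-Whitney pair statistic (ties count 1/2), computed via
# ranks in O(n log n).
auc_mann_whitney <- function(scores_positive, scores_negative) {
  np <- length(scores_positive)
  nn <- length(scores_negative)
  r <- rank(c(scores_positive, scores_negative))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve and AUC for a keyword classifier
#'
#' Builds the ROC curve from a fixed threshold sweep (-10..10 on the
#' standardized score scale) and computes the AUC as the Mann-Whitney pair
#' statistic (ties count 1/2), which is exact regardless of the sweep
#' resolution.
#'
#' @param scores_positive,scores_negative classifier scores at keyword and
#'   non-keyword alignment times (both non-empty).
#' @param thresholds threshold sweep.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores_positive, scores_negative,
                    thresholds = seq(-10, 10, by = 0.1)) {
  if (!length(scores_positive) || !length(scores_negative)) {
    stop("both score sets must be non-empty")
  }
  th <- sort(thresholds, decreasing = TRUE) # TPR/FPR non-decreasing along sweep
  tpr <- vapply(th, function(t) mean(scores_positive > t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores_negative > t), numeric(1))
  structure(
    list(thresholds = th, tpr = tpr, fpr = fpr,
         auc = auc_mann_whitney(scores_positive, scores_negative)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Scrambled-label null distribution of the AUC
#'
#' Repeatedly permutes the training-task utterance labels within stimulus
#' blocks (preserving block balance), retrains the keyword classifier on
#' the permuted pairs (templates and PCA stay fixed), scores the test task
#' at its true alignment times, and records the AUC. Returns the null
#' distribution and its 95th-percentile significance cutoff.
#'
#' @param state list describing the frozen pipeline state:
#'   `pc_train`, `events_train`, `frame_times_train`, `pc_test`,
#'   `events_test`, `frame_times_test`, `read_offset`, and the training
#'   constants `C`, `epochs`, `halfwidth`.
#' @param keyword keyword label.
#' @param n_reps number of permutations (>= 1).
#' @param seed RNG seed; rep r uses seed + r, so the distribution is
#'   reproducible.
#' @return list of class `auc_null`: `null` (numeric n_reps), `cutoff`
#'   (95th percentile), `n_reps`.
#' @export
bootstrap_null_auc <- function(state, keyword, n_reps = 1000, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  ev_tr <- state$events_train
  test_scores <- function(model) {
    pos_t <- ev_frames(state, "test", keyword, TRUE)
    neg_t <- ev_frames(state, "test", keyword, FALSE)
    list(pos = score_keyword(model, state$pc_test[pos_t, , drop = FALSE]),
         neg = score_keyword(model, state$pc_test[neg_t, , drop = FALSE]))
  }
  null <- vapply(seq_len(n_reps), function(r) {
    rep_seed <- (seed + r) %% .Machine$integer.max
    ev_perm <- ev_tr
    withr::with_seed(rep_seed, {
      for (b in unique(ev_perm$block)) {
        idx <- which(ev_perm$block == b)
        ev_perm$label[idx] <- ev_perm$label[sample(idx)]
      }
    })
    pairs <- suppressWarnings(build_training_pairs(
      state$pc_train, state$frame_times_train, state$read_offset,
      ev_perm, keyword, halfwidth = state$halfwidth
    ))
    model <- suppressWarnings(train_keyword_classifier(
      pairs, state$pc_train, keyword, C = state$C, epochs = state$epochs,
      halfwidth = state$halfwidth, seed = rep_seed
    ))
    sc <- test_scores(model)
    auc_mann_whitney(sc$pos, sc$neg)
  }, numeric(1))
  structure(
    list(null = null,
         cutoff = as.numeric(stats::quantile(null, 0.95, type = 7)),
         n_reps = n_reps),
    class = "auc_null"
  )
}

# Output-frame indices of keyword / non-keyword utterances with usable
# voice onsets, for the train or test task of a pipeline state.
ev_frames <- function(state, task = c("train", "test"), keyword, positive) {
  task <- match.arg(task)
  ev <- state[[paste0("events_", task)]]
  ft <- state[[paste0("frame_times_", task)]]
  sel <- !is.na(ev$voice_onset) &
    (if (positive) ev$label == keyword else ev$label != keyword)
  event_time_to_output_frame(ft, ev$voice_onset[sel], state$read_offset)
}
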