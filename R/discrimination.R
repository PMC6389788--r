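#' PCA over template outputs
#'
#' Fits a principal component analysis over all frames of the training
#' task's template-output matrix and retains the minimal number of
#' components whose cumulative explained variance reaches
#' `variance_target`. Transformed series are standardized by the
#' training-set SD of each retained component, so downstream classifier
#' thresholds are on a comparable scale across datasets.
#'
#' @param y frames x contrasts matrix of template outputs (the `y` element
#'   of a `filter_outputs`).
#' @param variance_target cumulative explained-variance fraction to retain.
#' @return list of class `kws_pca`: `center`, `rotation` (contrasts x k),
#'   `sdev` (training SD per retained component), `k`, `explained`.
#' @export
fit_pca <- function(y, variance_target = 0.90) {
  if (nrow(y) < 2) stop("need at least 2 frames to fit a PCA")
  if (!ncol(y)) stop("need at least one template output series")
  pr <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  if (sum(v) <= .Machine$double.eps * nrow(y)) {
    stop("template outputs are constant: PCA is rank-deficient")
  }
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_target - 1e-12)[1]
  structure(
    list(center = pr$center, rotation = pr$rotation[, seq_len(k), drop = FALSE],
         sdev = pr$sdev[seq_len(k)], k = k, explained = cum[k],
         variance_target = variance_target),
    class = "kws_pca"
  )
}

#' @rdname fit_pca
#' @param outputs frames x contrasts matrix (or `filter_outputs`) to
#'   project.
#' @param model a fitted `kws_pca`.
#' @return frames x k matrix of standardized principal-component series.
#' @export
pca_transform <- function(outputs, model) {
  y <- if (inherits(outputs, "filter_outputs")) outputs$y else outputs
  if (ncol(y) != length(model$center)) {
    stop("feature dimension mismatch: got ", ncol(y), ", model expects ",
         length(model$center))
  }
  z <- sweep(y, 2, model$center) %*% model$rotation
  sweep(z, 2, model$sdev, `/`)
}

#' Keyword / non-keyword training pairs
#'
#' Pairs feature vectors within stimulus blocks: every keyword trial is
#' paired with every non-keyword trial of the same block, plus one
#' silent-period competitor (1.0 s before the keyword trial's stimulus
#' onset) per keyword trial. Each competitor carries a +/- `halfwidth`
#' frame context for the max-margin search. Alignment times are the
#' (microphone-derived) voice onsets; trials with missing onsets are
#' skipped.
#'
#' @param pc frames x k standardized PC matrix from [pca_transform()].
#' @param frame_times frame times of the underlying stream, seconds.
#' @param center_offset window-center offset of the filter outputs
#'   (frames); event times map to frame `nearest(time) + center_offset`.
#' @param events an [event_table()] with voice onsets filled.
#' @param keyword the keyword label.
#' @param halfwidth competitor context half-width, frames (+/- 100 ms = 6).
#' @param silent_lead silent-period lead before stimulus onset, seconds.
#' @return data.frame of class `kws_pairs` with columns `pos_frame`,
#'   `neg_center`, `block`, `type` ("utterance" or "silence").
#' @export
build_training_pairs <- function(pc, frame_times, center_offset, events,
                                 keyword, halfwidth = 6L, silent_lead = 1.0) {
  if (!keyword %in% syllable_inventory()$label) stop("unknown keyword: ", keyword)
  rows <- list()
  for (b in unique(events$block)) {
    ev <- events[events$block == b, ]
    kw <- ev[ev$label == keyword & !is.na(ev$voice_onset), ]
    nk <- ev[ev$label != keyword & !is.na(ev$voice_onset), ]
    if (!nrow(kw)) {
      warning("keyword ", keyword, " absent from block ", b,
              ": block contributes no pairs")
      next
    }
    pos <- event_time_to_output_frame(frame_times, kw$voice_onset, center_offset)
    if (nrow(nk)) {
      neg <- event_time_to_output_frame(frame_times, nk$voice_onset, center_offset)
      g <- expand.grid(pos = pos, neg = neg)
      rows[[length(rows) + 1L]] <- data.frame(
        pos_frame = g$pos, neg_center = g$neg, block = b, type = "utterance"
      )
    }
    sil <- event_time_to_output_frame(
      frame_times, kw$stimulus_onset - silent_lead, center_offset
    )
    rows[[length(rows) + 1L]] <- data.frame(
      pos_frame = pos, neg_center = sil, block = b, type = "silence"
    )
  }
  if (!length(rows)) stop("no usable training pairs for keyword ", keyword)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("kws_pairs", "data.frame")
  out
}

#' Train a keyword classifier (online max-margin, PA-I)
#'
#' Runs the passive-aggressive (PA-I) online loop over the training pairs
#' in a seed-fixed shuffled order: for each pair the competitor is the
#' feature vector within the non-keyword context that looks maximally
#' keyword-like under the current boundary, the hinge loss
#' `max(0, 1 - w.x+ + w.x-)` is computed, and
#' `w <- w + tau (x+ - x-)` with `tau = min(C, loss / ||x+ - x-||^2)`.
#' Training stops early when an epoch incurs zero loss.
#'
#' @param pairs a [build_training_pairs()] result.
#' @param pc frames x k standardized PC matrix.
#' @param keyword keyword label stored on the model.
#' @param C aggressiveness parameter.
#' @param epochs maximum passes over the pairs.
#' @param halfwidth competitor context half-width, frames.
#' @param seed shuffle seed.
#' @return list of class `keyword_model`: `keyword`, `w`, `theta`
#'   (NA until selected), `C`, `epochs_run`, `epoch_loss`.
#' @export
train_keyword_classifier <- function(pairs, pc, keyword = attr(pairs, "keyword"),
                                     C = 1, epochs = 10L, halfwidth = 6L,
                                     seed = 1L) {
  if (!nrow(pairs)) stop("need at least one training pair")
  ord <- withr::with_seed(seed, sample.int(nrow(pairs)))
  fit <- pa_train_cpp(pc, as.integer(pairs$pos_frame),
                      as.integer(pairs$neg_center), as.integer(ord),
                      as.integer(halfwidth), C, as.integer(epochs))
  if (fit$skipped > 0) {
    warning(fit$skipped, " pair update(s) skipped (identical keyword and ",
            "competitor vectors with positive loss)")
  }
  w <- as.numeric(fit$w)
  # normalize the decision scores to unit training-frame SD so the fixed
  # theta sweep [-10, 10] is on a meaningful scale across datasets
  score_scale <- stats::sd(drop(pc %*% w))
  if (is.finite(score_scale) && score_scale > 0) w <- w / score_scale
  structure(
    list(keyword = keyword, w = w, theta = NA_real_, C = C,
         score_scale = score_scale,
         epochs_run = sum(cumsum(fit$epoch_loss == 0) <= 1),
         epoch_loss = as.numeric(fit$epoch_loss)),
    class = "keyword_model"
  )
}

#' Score feature vectors with a keyword model
#'
#' `score_keyword()` returns the linear score `w . x`;
#' `classify_keyword()` declares a keyword iff the score exceeds the
#' model's decision threshold.
#'
#' @param model a `keyword_model`.
#' @param x a k-vector or frames x k matrix of standardized PC features.
#' @param theta decision threshold; defaults to the model's stored theta.
#' @return numeric score(s), or logical for `classify_keyword()`.
#' @export
score_keyword <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w)) stop("feature dimension mismatch")
    return(drop(x %*% model$w))
  }
  if (length(x) != length(model$w)) stop("feature dimension mismatch")
  sum(model$w * x)
}

#' @rdname score_keyword
#' @export
classify_keyword <- function(model, x, theta = model$theta) {
  if (is.na(theta)) stop("model has no decision threshold set")
  score_keyword(model, x) > theta
}

#' Equal-error-rate decision threshold for a keyword classifier
#'
#' Sweeps theta over a fixed grid and returns the value minimizing
#' |miss rate - false-positive rate|, ties broken toward the higher
#' threshold.
#'
#' @param scores_pos,scores_neg classifier scores at keyword and
#'   non-keyword (plus silent-period) alignment times.
#' @param grid threshold sweep.
#' @return the selected threshold.
#' @export
select_theta_eer <- function(scores_pos, scores_neg,
                             grid = seq(-10, 10, by = 0.1)) {
  miss <- vapply(grid, function(th) mean(scores_pos <= th), numeric(1))
  fp <- vapply(grid, function(th) mean(scores_neg > th), numeric(1))
  gap <- abs(miss - fp)
  best <- which(gap <= min(gap) + 1e-12)
  grid[best[which.max(grid[best])]]
}
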