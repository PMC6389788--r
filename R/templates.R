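#' Build spatiotemporal templates from training epochs
#'
#' From voice-onset-aligned response epochs, builds: the response template
#' (grand mean over all trials, channels x L); one discrimination template
#' per contrast (the 12 syllables, 3 places of articulation, 2 voicing
#' classes, 2 vowel heights -- 19 in all), each the condition mean minus
#' the response template, temporally smoothed (hamming, 0.1 s, zero-phase)
#' and then significance-masked; and the VAD template, the response
#' template restricted to vSMC channels (auditory STG channels are excluded
#' because they also respond to perceived speech).
#'
#' The significance mask is computed from the condition mean prior to
#' response subtraction: each element is z-scored against the pooled
#' baseline (mean/SD of the band feature, SD scaled by sqrt(n_trials) for
#' the condition mean), and elements with z < `z_cut` are set exactly to
#' zero.
#'
#' @param epochs trials x channels x L array from [epoch_stream()].
#' @param labels syllable label per kept trial.
#' @param baseline_stats the `baseline_stats` element of the
#'   `feature_stream` the epochs were cut from.
#' @param channel_rois per-channel ROI tags (same order as the epoch
#'   channel dimension).
#' @param frame_rate frames per second (defines the smoothing length).
#' @param z_cut significance cutoff; elements with condition-mean z below
#'   it are zeroed.
#' @param smooth_s template smoothing kernel duration, seconds.
#' @return list of class `template_set`: `response` (channels x L),
#'   `discrimination` (named list of `template`, `mask`, `n_trials`),
#'   `vad` (vSMC channels x L), `channels`, `vad_channels`, `L`.
#' @export
build_templates <- function(epochs, labels, baseline_stats, channel_rois,
                            frame_rate = 62.5, z_cut = 3, smooth_s = 0.1) {
  stopifnot(length(dim(epochs)) == 3)
  n_trials <- dim(epochs)[1]
  L <- dim(epochs)[3]
  ch_names <- dimnames(epochs)[[2]]
  if (length(labels) != n_trials) stop("one label per epoch required")
  if (length(unique(labels)) < 2) stop("need epochs from at least 2 conditions")
  response <- apply(epochs, c(2, 3), mean)
  sm_len <- smoother_length(smooth_s, frame_rate)
  mu <- baseline_stats$feature_mean
  sdv <- baseline_stats$feature_sd

  members <- contrast_members()
  disc <- list()
  for (k in names(members)) {
    sel <- labels %in% members[[k]]
    n_k <- sum(sel)
    if (n_k == 0) {
      warning("contrast ", k, " has zero trials; omitted")
      next
    }
    cond_mean <- apply(epochs[sel, , , drop = FALSE], c(2, 3), mean)
    z <- (cond_mean - mu) / (sdv / sqrt(n_k))
    mask <- (z >= z_cut) * 1
    diff <- cond_mean - response
    smoothed <- t(apply(diff, 1, symmetric_smooth, n = sm_len))
    tpl <- smoothed * mask
    dimnames(tpl) <- dimnames(mask) <- list(ch_names, NULL)
    disc[[k]] <- list(template = tpl, mask = mask, n_trials = n_k)
  }

  vad_ch <- which(channel_rois == "vSMC")
  if (!length(vad_ch)) stop("no vSMC channels available for the VAD template")
  vad <- response[vad_ch, , drop = FALSE]
  dimnames(response) <- list(ch_names, NULL)
  dimnames(vad) <- list(ch_names[vad_ch], NULL)
  structure(
    list(response = response, discrimination = disc, vad = vad,
         channels = ch_names, vad_channels = ch_names[vad_ch], L = L),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d discrimination templates, %d channels x L=%d, VAD over %d vSMC channels\n",
              length(x$discrimination), length(x$channels), x$L,
              length(x$vad_channels)))
  invisible(x)
}

# Sliding normalized correlation between a masked template and every
# causal L-frame window of the stream (window at frame t covers frames
# t-L+1 .. t):
#
#   r(t) = sum_mask(T * X_t) / (||T||_mask * ||X_t||_full)
#
# a cosine similarity in which neither side is re-centered: template
# values are already deviations from the response template (their natural
# zero), and the stream is already z-scored to baseline. Re-centering
# over the mask support would cancel the template's own signal whenever
# the mask selects exactly the active regions (a one-lobe window would
# anti-correlate on a two-lobe template's absent lobe). Normalizing by
# the FULL window energy keeps |r| <= 1 (Cauchy-Schwarz) and
# amplitude-invariant. Degenerate windows (zero energy, or an all-masked
# template) give 0, as do frames t < L. Implemented with per-channel FIR
# sliding sums.
sliding_masked_cor <- function(X, template, mask) {
  L <- ncol(template)
  n_frames <- ncol(X)
  if (n_frames < L) stop("stream shorter than the template length")
  out <- numeric(n_frames)
  tm <- template * mask
  q_t <- sum(tm^2)
  if (q_t <= 1e-12) return(out)
  s2 <- numeric(n_frames)
  st <- numeric(n_frames)
  ones <- rep(1, L)
  for (ch in seq_len(nrow(template))) {
    s2 <- s2 + fir_sliding_sum(X[ch, ]^2, ones)
    if (any(tm[ch, ] != 0)) st <- st + fir_sliding_sum(X[ch, ], tm[ch, ])
  }
  den <- sqrt(q_t * pmax(s2, 0))
  ok <- den > 1e-12
  out[ok] <- st[ok] / den[ok]
  out[seq_len(L - 1L)] <- 0
  out
}

# Sliding mean of the window entries (rectangular-window ablation: every
# template replaced by an equal-size all-ones rectangle; a Pearson
# correlation against a constant template is undefined, so the ablated
# output is plain rectangular smoothing of the features).
sliding_rect_mean <- function(X, L) {
  n <- nrow(X) * L
  s <- numeric(ncol(X))
  ones <- rep(1, L)
  for (ch in seq_len(nrow(X))) s <- s + fir_sliding_sum(X[ch, ], ones)
  s[seq_len(L - 1L)] <- 0
  s / n
}

#' Apply a template set to a feature stream
#'
#' Causal matched filtering: at each frame t (window = frames t-L+1 .. t),
#' each discrimination template's output y_k(t) is the normalized
#' correlation (masked-template cosine similarity; see Details) between
#' the template and the window, then causally smoothed (hamming, 0.25 s).
#' The VAD output v(t) is the squared normalized correlation with the VAD
#' template (all entries), causally smoothed (hamming, 1.0 s).
#'
#' @details The correlation is `sum(T * X) / (||T|| * ||X||)` with the sum
#' and template norm over the template's unmasked entries and the window
#' norm over the full window. Neither side is re-centered: template
#' entries are deviations from the response template and the stream is
#' z-scored to baseline, so both carry a meaningful zero, and re-centering
#' over the mask support would cancel the template's own signal when the
#' mask selects exactly the active regions. Output frames align with the input
#' frame grid. Attributes map output frames back to event times:
#' `center_offset` (31 frames) is the window-center offset,
#' `y_event_offset` (39 frames) additionally absorbs the 0.25 s
#' smoother's group delay (the frame where an event's template outputs
#' peak), and `vad_event_offset` (62 frames) absorbs the 1.0 s VAD
#' smoother's delay, realizing the ~1 s total latency of the detector.
#'
#' @param stream a `feature_stream` whose channels are a superset of the
#'   template channels.
#' @param template_set a [build_templates()] result.
#' @param ablate_rectangular replace every template by an equal-size
#'   all-ones rectangle (feature-smoothing ablation).
#' @param smooth_y_s,smooth_v_s causal smoothing durations for the
#'   discrimination and VAD outputs, seconds.
#' @return list of class `filter_outputs`: `y` (frames x contrasts), `v`
#'   (frames), `frame_times`, `baseline_frames`, offsets as attributes.
#' @export
matched_filter <- function(stream, template_set, ablate_rectangular = FALSE,
                           smooth_y_s = 0.25, smooth_v_s = 1.0) {
  stopifnot(inherits(stream, "feature_stream"),
            inherits(template_set, "template_set"))
  missing_ch <- setdiff(template_set$channels, rownames(stream$z))
  if (length(missing_ch)) {
    stop("stream is missing template channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  L <- template_set$L
  if (ncol(stream$z) < L) stop("stream shorter than the template length")
  X <- stream$z[template_set$channels, , drop = FALSE]
  len_y <- smoother_length(smooth_y_s, stream$frame_rate)
  len_v <- smoother_length(smooth_v_s, stream$frame_rate)

  contrasts <- names(template_set$discrimination)
  y <- matrix(0, ncol(stream$z), length(contrasts),
              dimnames = list(NULL, contrasts))
  for (k in contrasts) {
    d <- template_set$discrimination[[k]]
    raw <- if (ablate_rectangular) {
      sliding_rect_mean(X, L)
    } else {
      sliding_masked_cor(X, d$template, d$mask)
    }
    y[, k] <- causal_smooth(raw, len_y)
  }

  Xv <- stream$z[template_set$vad_channels, , drop = FALSE]
  vad_tpl <- template_set$vad
  v_raw <- if (ablate_rectangular) {
    sliding_rect_mean(Xv, L)^2
  } else {
    sliding_masked_cor(Xv, vad_tpl, matrix(1, nrow(vad_tpl), L))^2
  }
  v <- causal_smooth(v_raw, len_v)

  half <- (L - 1L) %/% 2L
  structure(
    list(y = y, v = v, v_raw = v_raw, frame_times = stream$frame_times,
         frame_rate = stream$frame_rate,
         baseline_frames = stream$baseline_frames),
    center_offset = half,
    y_event_offset = half + len_y %/% 2L,
    v_smoother_len = len_v,
    vad_event_offset = half + (len_v - 1L) %/% 2L,
    class = "filter_outputs"
  )
}
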