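#' Simulator configuration
#'
#' Stated-world parameters for the synthetic ECoG session generator: a
#' block-randomized consonant-vowel syllable task (blocks of 60 trials,
#' 5 per syllable), 2-3 s intertrial intervals, 1 s stimulus, overt
#' responses ~0.8 s after stimulus, per-channel syllable-selective
#' high-gamma bursts, and a microphone track carrying 250-450 Hz energy at
#' voice onset.
#'
#' @param n_channels_vsmc,n_channels_stg,n_channels_other channel counts per
#'   region of interest. vSMC carries place-of-articulation selectivity plus
#'   voicing-dependent burst timing (on alternating place channels) and the
#'   always-active channels the VAD template relies on; STG carries the
#'   /a/-vs-/i/ vowel-height amplitude contrast; `other` channels are pure
#'   noise (they exercise downselection). The default (11 vSMC) gives two
#'   VAD-like channels and balanced coverage of three channels per place.
#' @param rate sampling rate, Hz (>= 500 so the 250-450 Hz mic band exists).
#' @param n_blocks,trials_per_block task structure; `trials_per_block` must
#'   be divisible by 12 so every syllable appears equally often per block.
#' @param iti_range intertrial interval range, seconds.
#' @param stim_duration stimulus presentation duration, seconds.
#' @param response_latency_mean,response_latency_sd voice-onset latency
#'   after stimulus onset (mean and jitter SD, seconds).
#' @param burst_snr target peak high-gamma feature z-score of a full-scale
#'   planted burst, in pooled-baseline SD units. 0 disables bursts.
#' @param burst_duration_range per-channel hamming burst-envelope duration
#'   range, seconds.
#' @param voicing_shift timing offset (seconds) by which burst centers
#'   LEAD the acoustic onset on unvoiced trials for voicing-coding
#'   channels (articulatory pressure buildup before plosive release);
#'   voicing is encoded purely as timing, never amplitude. The default
#'   exceeds the classifier's deliberate +/-100 ms shift-invariance
#'   window, without which a timing code cannot act as a keyword cue.
#' @param mic_snr amplitude ratio of the mic speech burst to mic noise.
#' @param seed integer RNG seed for the session realization (trial order,
#'   noise, burst waveforms); identical configs give bit-identical
#'   sessions.
#' @param profile_seed RNG seed for the per-channel selectivity map (the
#'   simulated subject's physiology). Defaults to `seed`; a train/test
#'   session pair for the same simulated subject must share
#'   `profile_seed` while differing in `seed`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels_vsmc = 11, n_channels_stg = 4,
                       n_channels_other = 2, rate = 1000,
                       n_blocks = 2, trials_per_block = 60,
                       iti_range = c(2, 3), stim_duration = 1,
                       response_latency_mean = 0.8,
                       response_latency_sd = 0.1,
                       burst_snr = 5, burst_duration_range = c(0.3, 0.5),
                       voicing_shift = 0.2, mic_snr = 100, seed = 1L,
                       profile_seed = NULL) {
  cfg <- list(
    n_channels_vsmc = as.integer(n_channels_vsmc),
    n_channels_stg = as.integer(n_channels_stg),
    n_channels_other = as.integer(n_channels_other),
    rate = rate, n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    iti_range = as.numeric(iti_range), stim_duration = stim_duration,
    response_latency_mean = response_latency_mean,
    response_latency_sd = response_latency_sd,
    burst_snr = burst_snr,
    burst_duration_range = as.numeric(burst_duration_range),
    voicing_shift = voicing_shift, mic_snr = mic_snr,
    seed = as.integer(seed),
    profile_seed = as.integer(if (is.null(profile_seed)) seed else profile_seed)
  )
  if (cfg$trials_per_block %% 12L != 0L) {
    stop("trials_per_block must be divisible by 12")
  }
  if (cfg$rate < 500) stop("rate must be >= 500 Hz (mic band below Nyquist)")
  if (cfg$n_blocks < 1) stop("need at least one block")
  durs <- c(cfg$iti_range, cfg$stim_duration, cfg$burst_duration_range,
            cfg$response_latency_mean)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (cfg$iti_range[2] < cfg$iti_range[1]) stop("invalid iti_range")
  if (cfg$burst_snr < 0) stop("burst_snr must be >= 0")
  if (cfg$n_channels_vsmc <= 0) {
    stop("configuration error: vSMC must have channels to carry place/VAD effects")
  }
  if (cfg$n_channels_stg <= 0) {
    stop("configuration error: STG must have channels to carry the vowel effect")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Per-channel selectivity map
#'
#' Deterministically (given `config$profile_seed`) assigns each simulated channel
#' its response profile: vSMC channels get a place-of-articulation
#' preference with voicing encoded as a burst-timing offset, a subset of
#' vSMC channels are non-selective "VAD-like" responders active for every
#' utterance, STG vowel channels carry an /a/-vs-/i/ amplitude contrast,
#' and `other`-ROI channels carry no effect.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per channel: `label`, `roi`, `type`
#'   (`place`, `vowel`, `vad`, `none`), `pref`, `scale_pref`, `scale_other`,
#'   `latency_offset` (s), `voicing_timing` (logical), `burst_duration` (s).
#' @export
syllable_effect_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nv <- config$n_channels_vsmc
  ns <- config$n_channels_stg
  no <- config$n_channels_other
  withr::with_seed((config$profile_seed + 7919L) %% .Machine$integer.max, {
    n_vad <- max(1L, nv %/% 5L)
    n_place <- nv - n_vad
    places <- rep_len(c("bilabial", "alveolar", "velar"), max(n_place, 1L))
    vsmc <- data.frame(
      roi = "vSMC",
      type = c(rep("place", n_place), rep("vad", n_vad)),
      pref = c(places[seq_len(n_place)], rep(NA_character_, n_vad)),
      scale_pref = 1, scale_other = c(rep(0.15, n_place), rep(NA_real_, n_vad)),
      # voicing timing on alternating place channels only: real arrays mix
      # timing-coding electrodes with ones that respond at a consistent
      # latency for every utterance
      voicing_timing = c(seq_len(n_place) %% 2L == 1L, rep(FALSE, n_vad)),
      stringsAsFactors = FALSE
    )
    n_vowel <- max(1L, as.integer(ceiling(ns / 2)))
    stg <- data.frame(
      roi = "STG",
      type = c(rep("vowel", n_vowel), rep("vad", ns - n_vowel)),
      pref = c(rep_len(c("a", "i"), n_vowel), rep(NA_character_, ns - n_vowel)),
      scale_pref = 1,
      scale_other = c(rep(0.35, n_vowel), rep(NA_real_, ns - n_vowel)),
      voicing_timing = FALSE,
      stringsAsFactors = FALSE
    )
    prof <- rbind(vsmc, stg)
    if (no > 0) {
      prof <- rbind(prof, data.frame(
        roi = "other", type = "none", pref = NA_character_,
        scale_pref = NA_real_, scale_other = NA_real_, voicing_timing = FALSE,
        stringsAsFactors = FALSE
      )[rep(1, no), ])
    }
    prof$latency_offset <- ifelse(
      prof$type %in% c("place", "vowel"),
      runif(nrow(prof), -0.05, 0.05), 0
    )
    prof$burst_duration <- runif(nrow(prof), config$burst_duration_range[1],
                                 config$burst_duration_range[2])
    prof$label <- sprintf("ch%02d", seq_len(nrow(prof)))
    rownames(prof) <- NULL
    prof[, c("label", "roi", "type", "pref", "scale_pref", "scale_other",
             "latency_offset", "voicing_timing", "burst_duration")]
  })
}

# 1/f ("pink") noise via frequency-domain shaping of white noise; flat
# below 1 Hz to keep the DC region finite. Unit-SD output scaled by `sd`.
# Synthesis runs at the next highly-composite length (fft cost) and
# truncates.
pink_noise <- function(n, rate, sd = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  f <- seq(0, rate, length.out = m + 1)[seq_len(m)]
  f[f > rate / 2] <- rate - f[f > rate / 2] # mirror half
  w <- 1 / sqrt(pmax(f, 1))
  x <- Re(stats::fft(stats::fft(white) * w, inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

# Band-limited unit-SD noise via FFT masking.
bandlimited_noise <- function(n, rate, lo, hi) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  f <- seq(0, rate, length.out = m + 1)[seq_len(m)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(stats::fft(white) * mask, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Solve for the burst amplitude A whose peak-window high-gamma feature
# z-score (against a pooled pink-noise baseline, computed with the exact
# feature definition: per-bin log-power z, band average, band re-z) equals
# config$burst_snr. Deterministic given the config seed.
calibrate_burst_amplitude <- function(config, win_s = 0.128, hop_s = 0.016,
                                      band = c(70, 110)) {
  if (config$burst_snr == 0) return(0)
  rate <- config$rate
  win <- round(rate * win_s)
  hop <- round(rate * hop_s)
  taper <- hamming_window(win)
  freqs <- fft_bin_freqs(win, rate)
  bins <- which(freqs >= band[1] & freqs <= band[2])
  withr::with_seed((config$profile_seed + 104729L) %% .Machine$integer.max, {
    x <- pink_noise(120 * rate, rate)
    grid <- frame_grid(length(x), rate, win, hop)
    lp <- stft_logpower(x, grid, win, bins, taper)
    mu_b <- rowMeans(lp)
    sd_b <- apply(lp, 1, stats::sd)
    zb <- (lp - mu_b) / sd_b
    band_base <- colMeans(zb)
    m_band <- mean(band_base)
    s_band <- stats::sd(band_base)
    # mean per-bin linear power of a unit-amplitude burst in its peak window
    nb <- round(mean(config$burst_duration_range) * rate)
    env <- hamming_window(nb)
    u <- rowMeans(vapply(seq_len(32), function(i) {
      burst <- bandlimited_noise(nb, rate, 70, 110) * env
      mid <- (nb - win) %/% 2
      seg <- burst[mid + seq_len(win)]
      sp <- stats::fft(taper * seg)[bins]
      Re(sp)^2 + Im(sp)^2
    }, numeric(length(bins))))
    f <- function(log_a) {
      a2 <- exp(2 * log_a)
      zbin <- (log(exp(mu_b) + a2 * u) - mu_b) / sd_b
      (mean(zbin) - m_band) / s_band - config$burst_snr
    }
    exp(stats::uniroot(f, c(log(1e-4), log(1e4)), tol = 1e-8)$root)
  })
}

#' Generate a ground-truthed synthetic session
#'
#' Synthesizes one block-randomized consonant-vowel syllable session:
#' per-channel pink-noise background plus a shared common-mode component
#' (so common-average referencing is exercised nontrivially), per-trial
#' band-limited (70-110 Hz) high-gamma noise bursts whose hamming envelope
#' amplitude and latency follow the channel selectivity map around the
#' true voice onset, and a microphone track with a strong 250-450 Hz burst
#' starting at the true voice onset. Burst amplitude is calibrated so the
#' peak high-gamma feature z of a full-scale burst is `config$burst_snr`.
#'
#' @param config a [sim_config()].
#' @return list with `recording` ([ecog_recording()]), `events`
#'   ([event_table()], `voice_onset` left NA -- it is the microphone
#'   detector's job to fill it), and `ground_truth` (data.frame of true
#'   per-trial voice onsets plus the selectivity map as attribute
#'   `profiles`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  profiles <- syllable_effect_profiles(config)
  amp <- calibrate_burst_amplitude(config)
  syl <- syllable_inventory()
  rate <- config$rate
  withr::with_seed(config$seed, {
    n_trials <- config$n_blocks * config$trials_per_block
    per <- config$trials_per_block %/% 12L
    labels <- unlist(lapply(seq_len(config$n_blocks), function(b) {
      sample(rep(syl$label, per))
    }))
    blocks <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
    iti <- runif(n_trials - 1, config$iti_range[1], config$iti_range[2])
    stim_onsets <- 2.5 + c(0, cumsum(config$stim_duration + iti))
    latency <- pmin(pmax(rnorm(n_trials, config$response_latency_mean,
                               config$response_latency_sd), 0.4), 1.2)
    voice_onsets <- stim_onsets + latency
    n_samples <- ceiling((max(stim_onsets) + config$stim_duration + 2.5) * rate)

    n_ch <- nrow(profiles)
    common <- pink_noise(n_samples, rate)
    signal <- matrix(0, n_ch, n_samples)
    for (ch in seq_len(n_ch)) {
      signal[ch, ] <- pink_noise(n_samples, rate) + 0.5 * common
    }

    trial_meta <- syl[match(labels, syl$label), ]
    if (amp > 0) {
      for (ch in seq_len(n_ch)) {
        p <- profiles[ch, ]
        if (p$type == "none") next
        nb <- round(p$burst_duration * rate)
        env <- hamming_window(nb)
        scale <- switch(
          p$type,
          vad = rep(1, n_trials),
          place = ifelse(trial_meta$place == p$pref, p$scale_pref, p$scale_other),
          vowel = ifelse(trial_meta$vowel == p$pref, p$scale_pref, p$scale_other)
        )
        shift <- if (p$voicing_timing) {
          ifelse(trial_meta$voicing == "unvoiced", -config$voicing_shift, 0)
        } else {
          rep(0, n_trials)
        }
        centers <- round((voice_onsets + p$latency_offset + shift) * rate) + 1L
        for (tr in seq_len(n_trials)) {
          wave <- bandlimited_noise(nb, rate, 70, 110) * env
          at <- centers[tr] - nb %/% 2L + seq_len(nb) - 1L
          ok <- at >= 1L & at <= n_samples
          signal[ch, at[ok]] <- signal[ch, at[ok]] + amp * scale[tr] * wave[ok]
        }
      }
    }

    mic <- rnorm(n_samples, 0, 1 / config$mic_snr)
    nbm <- round(0.4 * rate)
    # speech-like envelope: fast (10 ms) attack at voice onset, flat
    # sustain, 100 ms raised-cosine decay
    tt <- (seq_len(nbm) - 1) / rate
    attack <- pmin(tt / 0.01, 1)
    decay <- rep(1, nbm)
    nd <- round(0.1 * rate)
    decay[(nbm - nd + 1):nbm] <- (1 + cos(pi * seq_len(nd) / nd)) / 2
    env_m <- attack * decay
    if (config$mic_snr > 0) {
      for (tr in seq_len(n_trials)) {
        at <- round(voice_onsets[tr] * rate) + 1L + seq_len(nbm) - 1L
        ok <- at >= 1L & at <= n_samples
        wave <- bandlimited_noise(nbm, rate, 250, 450) * env_m
        mic[at[ok]] <- mic[at[ok]] + wave[ok]
      }
    }

    channels <- data.frame(label = profiles$label, roi = profiles$roi,
                           excluded = FALSE, stringsAsFactors = FALSE)
    session_id <- sprintf("sim-%d-%s", config$seed,
                          fnv1a(unclass(config)))
    rec <- ecog_recording(signal, rate, channels, mic = mic,
                          session_id = session_id)
    ev <- event_table(seq_len(n_trials), stim_onsets, labels, blocks)
    gt <- data.frame(trial = seq_len(n_trials), voice_onset = voice_onsets)
    attr(gt, "profiles") <- profiles
    attr(gt, "burst_amplitude") <- amp
    list(recording = rec, events = ev, ground_truth = gt)
  })
}
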