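test_that("frame grid matches the closed-form frame count", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(500:5000, 1)
      win <- sample(c(64, 100, 128), 1)
      hop <- sample(c(8, 16, 20), 1)
      g <- neurokws:::frame_grid(n, 1000, win, hop)
      expect_equal(g$n, floor((n - win) / hop) + 1)
      expect_equal(g$times[1], (win - 1) / 1000)
      expect_equal(diff(g$times)[1], hop / 1000)
    }
  })
})

test_that("pooled-baseline frames of the stream are self-normalized", {
  sess <- tiny_session()
  feats <- extract_high_gamma(sess$recording, sess$events)
  bl <- feats$baseline_frames
  expect_false(anyNA(feats$z))
  expect_true(all(abs(rowMeans(feats$z[, bl])) < 0.05))
  sds <- apply(feats$z[, bl], 1, sd)
  expect_true(all(sds > 0.95 & sds < 1.05))
  expect_equal(feats$frame_rate, 62.5)
})

test_that("a switched-on 90 Hz tone steps the band feature, matching a naive oracle", {
  rate <- 1000
  n <- 8 * rate
  withr::with_seed(3, x <- rnorm(n, sd = 1))
  t_on <- 5
  idx_on <- (t_on * rate + 1):n
  x[idx_on] <- x[idx_on] + 6 * sin(2 * pi * 90 * ((idx_on - 1) / rate))
  ch <- data.frame(label = "e1", roi = "vSMC", excluded = FALSE)
  rec <- ecog_recording(matrix(x, 1), rate, ch)
  ev <- event_table(1:2, c(2, 4), c("/ba/", "/da/"), c(1, 1))
  feats <- extract_high_gamma(rec, ev)

  before <- feats$z[1, feats$frame_times > 3 & feats$frame_times < t_on]
  after <- feats$z[1, feats$frame_times > t_on + 0.128 &
                     feats$frame_times < t_on + 1]
  expect_lt(mean(before), 1)
  expect_gt(mean(after), 5)
  # the step completes within one window length
  step_frames <- which(feats$z[1, ] > 0.5 * mean(after))
  expect_lt(feats$frame_times[min(step_frames[step_frames >
    which.max(feats$frame_times > t_on)])] - t_on, 0.128 + 0.017)

  # naive oracle: recompute the full feature chain per frame with direct FFTs
  win <- 128; hop <- 16
  taper <- neurokws:::hamming_window(win)
  freqs <- (0:(win - 1)) * rate / win
  bins <- which(freqs >= 70 & freqs <= 110 & freqs <= rate / 2)
  grid <- neurokws:::frame_grid(n, rate, win, hop)
  bl <- feats$baseline_frames
  logp_frame <- function(f) {
    seg <- x[grid$starts[f] + 0:(win - 1)] * taper
    log(Mod(stats::fft(seg))[bins]^2)
  }
  lp_bl <- vapply(bl, logp_frame, numeric(length(bins)))
  mu <- rowMeans(lp_bl); sd_b <- apply(lp_bl, 1, sd)
  band_bl <- colMeans((lp_bl - mu) / sd_b)
  m <- mean(band_bl); s <- sd(band_bl)
  for (f in c(150, 260, 371, 430)) {
    z_naive <- (mean((logp_frame(f) - mu) / sd_b) - m) / s
    expect_equal(unname(feats$z[1, f]), z_naive, tolerance = 1e-10)
  }
})

test_that("stationary white noise rarely exceeds |z| = 4", {
  rate <- 1000
  withr::with_seed(9, x <- matrix(rnorm(2 * 60 * rate), 2))
  ch <- data.frame(label = c("e1", "e2"), roi = "vSMC", excluded = FALSE)
  rec <- ecog_recording(x, rate, ch)
  ev <- event_table(1:10, seq(2, 56, by = 6), rep(syllable_inventory()$label[1:5], 2),
                    rep(1L, 10))
  feats <- extract_high_gamma(rec, ev)
  expect_lt(mean(abs(feats$z) > 4), 0.01)
})

test_that("feature extraction is causal", {
  # causality is relative to the task-level normalization constants: the
  # pooled baseline is a per-task artifact, so perturb after the last
  # baseline window
  sess <- tiny_session()
  rec <- sess$recording
  feats <- extract_high_gamma(rec, sess$events)
  t_cut <- max(sess$events$stimulus_onset) + 0.2
  f_cut <- max(which(feats$frame_times <= t_cut))
  rec2 <- rec
  late <- (round(t_cut * rec$rate) + 2):ncol(rec$signal)
  rec2$signal[, late] <- rec2$signal[, late] + 40
  feats2 <- extract_high_gamma(rec2, sess$events)
  expect_identical(feats$z[, seq_len(f_cut)], feats2$z[, seq_len(f_cut)])
})

test_that("errors: no baseline frames and zero-variance channels", {
  rec <- toy_recording(n = 2, len = 3000)
  ev <- event_table(1, 0.05, "/ba/", 1) # no full window fits before onset
  expect_error(extract_high_gamma(rec, ev), "baseline")
  withr::with_seed(2, sig <- rbind(rnorm(3000), 0))
  ch <- data.frame(label = c("a", "b"), roi = "vSMC", excluded = FALSE)
  rec2 <- ecog_recording(sig, 1000, ch)
  expect_error(extract_high_gamma(rec2, event_table(1, 1.5, "/ba/", 1)), "b")
})

test_that("mic voice onsets recover planted onsets and miss absent ones", {
  sess <- tiny_session()
  ev <- mic_voice_onsets(sess$recording, sess$events)
  err <- ev$voice_onset - sess$ground_truth$voice_onset
  expect_false(anyNA(err))
  expect_true(all(abs(err) <= 0.016 + 1e-9))

  # silence one trial's response window -> missing onset for that trial only
  rec2 <- sess$recording
  tr <- 5
  span <- round(sess$events$stimulus_onset[tr] * rec2$rate):
    round((sess$events$stimulus_onset[tr + 1] - 0.05) * rec2$rate)
  rec2$mic[span] <- 0
  ev2 <- mic_voice_onsets(rec2, sess$events)
  expect_true(is.na(ev2$voice_onset[tr]))
  expect_false(anyNA(ev2$voice_onset[-tr]))

  # a tapered burst below the band (100 Hz) is not detected (the taper
  # avoids broadband onset clicks, and the moderate amplitude keeps
  # rectangular-window sidelobe leakage below the noise floor)
  rate <- 1000
  withr::with_seed(14, mic <- rnorm(20 * rate, sd = 0.01))
  at <- (5 * rate):(5.4 * rate)
  env <- sin(pi * seq_along(at) / length(at))^2
  mic[at] <- mic[at] + 0.1 * env * sin(2 * pi * 100 * (at / rate))
  rec3 <- toy_recording(n = 1, len = 20 * rate, mic = mic)
  ev3 <- mic_voice_onsets(rec3, event_table(1:2, c(3, 10), c("/ba/", "/da/"),
                                            c(1, 1)))
  expect_true(all(is.na(ev3$voice_onset)))
  rec4 <- toy_recording(n = 1, len = 2500)
  expect_error(mic_voice_onsets(rec4, toy_events()), "mic")
})

test_that("epoching centers on the nearest frame and drops unusable trials", {
  sess <- tiny_session()
  feats <- extract_high_gamma(sess$recording, sess$events)
  align <- feats$frame_times[c(100, 160, 220)]
  ep <- epoch_stream(feats, align)
  expect_equal(dim(ep), c(3, nrow(feats$z), 63))
  expect_equal(ep[2, , 32], feats$z[, 160])
  expect_equal(attr(ep, "center_frames"), c(100L, 160L, 220L))

  expect_warning(ep2 <- epoch_stream(feats, c(align, NA, 0.01, 1e6)),
                 "dropped")
  expect_equal(dim(ep2)[1], 3)
  expect_equal(attr(ep2, "kept"), 1:3)

  const <- feats
  const$z[] <- 1
  epc <- epoch_stream(const, align)
  expect_equal(epc[1, , ], epc[2, , ])
})
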