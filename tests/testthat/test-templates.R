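# baseline stats stub on the final feature scale
stub_stats <- function(n_ch) {
  list(feature_mean = rep(0, n_ch), feature_sd = rep(1, n_ch))
}

test_that("toy templates equal the hand-computed mask(smooth(delta))", {
  # 2 channels x 5 frames, 4 trials of /ba/ and 4 of /ti/, frame rate low
  # enough that the 0.1 s smoothing kernel is a single tap (identity)
  ba <- matrix(c(2, 3, 2, 0, 0,
                 0, 0, 0, 0, 0), 2, 5, byrow = TRUE)
  ti <- matrix(c(0, 0, 0, 0, 0,
                 0, 2.5, 2.5, 0, 0), 2, 5, byrow = TRUE)
  epochs <- array(NA_real_, c(8, 2, 5),
                  dimnames = list(NULL, c("c1", "c2"), NULL))
  for (i in 1:4) epochs[i, , ] <- ba
  for (i in 5:8) epochs[i, , ] <- ti
  labels <- rep(c("/ba/", "/ti/"), each = 4)
  tset <- suppressWarnings(build_templates(
    epochs, labels, stub_stats(2), channel_rois = c("vSMC", "STG"),
    frame_rate = 5, z_cut = 3
  ))
  grand <- (ba + ti) / 2
  # mask: condition mean z = mean * sqrt(4); kept where mean >= 1.5
  expect_equal(unname(tset$discrimination[["/ba/"]]$template),
               (ba - grand) * (ba * 2 >= 3))
  expect_equal(unname(tset$discrimination[["/ti/"]]$template),
               (ti - grand) * (ti * 2 >= 3))
  expect_equal(unname(tset$response), grand)
  # VAD template: vSMC rows only
  expect_equal(unname(tset$vad), grand[1, , drop = FALSE])
  # contrasts with zero trials are omitted with a warning
  w <- capture_warnings(build_templates(epochs, labels, stub_stats(2),
                                        channel_rois = c("vSMC", "STG"),
                                        frame_rate = 5))
  expect_true(any(grepl("zero trials", w)))
  expect_equal(length(tset$discrimination), 2 + 2 + 2 + 2) # place/voicing/vowel + 2 syllables
})

test_that("condition-mean z below the cutoff is zeroed exactly", {
  # 4 identical trials with value 1.45 -> z = 2.9 < 3 -> masked out;
  # value 1.6 -> z = 3.2 -> kept
  ep <- array(0, c(4, 1, 3), dimnames = list(NULL, "c1", NULL))
  ep[, 1, 1] <- 1.45
  ep[, 1, 2] <- 1.6
  ep2 <- array(0.5, c(4, 1, 3), dimnames = list(NULL, "c1", NULL))
  epochs <- array(NA_real_, c(8, 1, 3), dimnames = list(NULL, "c1", NULL))
  epochs[1:4, , ] <- ep
  epochs[5:8, , ] <- ep2
  tset <- suppressWarnings(build_templates(
    epochs, rep(c("/ba/", "/ti/"), each = 4), stub_stats(1),
    channel_rois = "vSMC", frame_rate = 5, z_cut = 3
  ))
  tpl <- tset$discrimination[["/ba/"]]
  expect_identical(unname(tpl$template[1, 1]), 0) # z = 2.9 -> exactly zero
  expect_gt(tpl$template[1, 2], 0)            # z = 3.2 -> kept
  expect_equal(unname(tpl$mask[1, ]), c(0, 1, 0))
})

test_that("identical trials give all-zero discrimination templates", {
  ep <- array(rep(1:6, each = 6), c(6, 2, 3),
              dimnames = list(NULL, c("a", "b"), NULL))
  for (i in 1:6) ep[i, , ] <- matrix(2, 2, 3)
  tset <- suppressWarnings(build_templates(
    ep, rep(c("/ba/", "/ti/", "/ka/"), 2), stub_stats(2),
    channel_rois = c("vSMC", "vSMC"), frame_rate = 5
  ))
  for (d in tset$discrimination) {
    expect_true(all(d$template == 0))
  }
})

test_that("sliding correlation matches the naive double-loop oracle", {
  withr::with_seed(21, {
    X <- matrix(rnorm(4 * 200), 4, 200)
    tpl <- matrix(rnorm(4 * 63), 4, 63)
    mask <- matrix(rbinom(4 * 63, 1, 0.4), 4, 63)
    fast <- neurokws:::sliding_masked_cor(X, tpl, mask)
    slow <- naive_masked_cor(X, tpl, mask)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-10)
  })
})

test_that("an embedded template copy correlates at exactly 1", {
  withr::with_seed(5, {
    tpl <- matrix(rnorm(3 * 20), 3, 20)
    mask <- matrix(1, 3, 20)
    mask[, 1:4] <- 0
    X <- matrix(0, 3, 120)
    X[, 61:80] <- tpl * mask
    r <- neurokws:::sliding_masked_cor(X, tpl, mask)
    expect_equal(which.max(r), 80)
    expect_equal(r[80], 1, tolerance = 1e-12)
    expect_true(all(r <= 1 + 1e-12))
  })
})

test_that("matched filter outputs respect shape, sign and causality", {
  sess <- tiny_session()
  fit <- cached("tiny_fit", fit_kws_pipeline(sess$recording, sess$events))
  fo <- fit$train$outputs
  expect_s3_class(fo, "filter_outputs")
  expect_true(all(fo$v >= 0))
  expect_true(all(fo$v_raw >= 0))
  expect_equal(ncol(fo$y), 19)
  expect_equal(attr(fo, "center_offset"), 31L)
  expect_equal(attr(fo, "vad_event_offset"), 62L)

  # causality: perturb the feature stream after a cut frame
  feats <- fit$train$features
  f_cut <- 900
  feats2 <- feats
  feats2$z[, (f_cut + 1):ncol(feats2$z)] <- 0
  fo2 <- matched_filter(feats2, fit$templates)
  expect_identical(fo$y[seq_len(f_cut), ], fo2$y[seq_len(f_cut), ])
  expect_identical(fo$v[seq_len(f_cut)], fo2$v[seq_len(f_cut)])

  # stream must contain the template channels and be long enough
  short <- feats
  short$z <- short$z[, 1:10]
  short$frame_times <- short$frame_times[1:10]
  expect_error(matched_filter(short, fit$templates), "shorter")
  missing_ch <- feats
  missing_ch$z <- missing_ch$z[-1, ]
  expect_error(matched_filter(missing_ch, fit$templates), "missing")
})

test_that("rectangular ablation collapses templates to window means", {
  sess <- tiny_session()
  fit <- cached("tiny_fit", fit_kws_pipeline(sess$recording, sess$events))
  fo_abl <- matched_filter(fit$train$features, fit$templates,
                           ablate_rectangular = TRUE)
  # every discrimination series is the same rectangular smoothing
  expect_true(all(apply(fo_abl$y, 1, function(r) diff(range(r))) < 1e-12))
  expect_true(all(fo_abl$v >= 0))
})
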