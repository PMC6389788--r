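test_that("PCA retains the minimal component count for the variance target", {
  # 2-feature data with a 99:1 variance split -> k = 1; oracle: eigen()
  withr::with_seed(31, {
    z <- cbind(rnorm(4000, sd = sqrt(99)), rnorm(4000, sd = 1))
    rot <- matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2)
    y <- z %*% rot
    m <- fit_pca(y)
    expect_equal(m$k, 1)
    ev <- eigen(cov(y))$values
    expect_gt(ev[1] / sum(ev), 0.9)

    # isotropic 3-feature data: no 2 components reach 90% -> k = 3
    y3 <- matrix(rnorm(9000), ncol = 3)
    expect_equal(fit_pca(y3)$k, 3)

    # transform of the training mean vector is the zero PC vector
    tr <- pca_transform(matrix(colMeans(y), 1), m)
    expect_equal(as.numeric(tr), rep(0, m$k), tolerance = 1e-10)

    # reconstruction keeps >= 90% of training variance
    mfull <- fit_pca(y3, variance_target = 0.90)
    pcs <- sweep(y3, 2, mfull$center) %*% mfull$rotation
    expect_gte(sum(apply(pcs, 2, var)) / sum(apply(y3, 2, var)), 0.9)
  })
  expect_error(fit_pca(matrix(1, 50, 3)), "constant")
  expect_error(pca_transform(matrix(0, 2, 5), fit_pca(matrix(rnorm(60), 30, 2))),
               "dimension")
})

# synthetic pc series + events on a fake frame grid
fake_state <- function(n_frames = 4000, k = 3, n_trials = 60, seed = 17,
                       effect = 0) {
  withr::with_seed(seed, {
    pc <- matrix(rnorm(n_frames * k), n_frames, k)
    frame_times <- (seq_len(n_frames) - 1) / 62.5
    onsets <- seq(5, by = 0.9, length.out = n_trials)
    labels <- rep(syllable_inventory()$label, length.out = n_trials)
    if (effect != 0) {
      fr <- vapply(onsets[labels == "/ba/"], function(s) {
        which.min(abs(frame_times - s)) + 31L
      }, integer(1))
      pc[fr, 1] <- pc[fr, 1] + effect
    }
    ev <- event_table(seq_len(n_trials), onsets - 1.5, labels,
                      rep(1L, n_trials), voice_onset = onsets)
    list(pc = pc, frame_times = frame_times, events = ev)
  })
}

test_that("pair building counts 5 x 55 utterance pairs plus 5 silent pairs per block", {
  st <- fake_state(n_frames = 4000, n_trials = 60)
  pairs <- build_training_pairs(st$pc, st$frame_times, 31L, st$events, "/ba/")
  expect_equal(sum(pairs$type == "utterance"), 5 * 55)
  expect_equal(sum(pairs$type == "silence"), 5)
  # silent competitor centered 1.0 s before stimulus onset
  sil <- pairs[pairs$type == "silence", ]
  expected <- vapply(st$events$stimulus_onset[st$events$label == "/ba/"] - 1,
                     function(s) which.min(abs(st$frame_times - s)) + 31L,
                     integer(1))
  expect_setequal(sil$neg_center, expected)

  # two blocks: pairs never cross blocks
  ev2 <- st$events
  ev2$block <- rep(1:2, each = 30)
  pairs2 <- build_training_pairs(st$pc, st$frame_times, 31L, ev2, "/ba/")
  # /ba/ occurs 3x in block 1 (27 non-keywords) and 2x in block 2 (28)
  expect_equal(nrow(pairs2), (3 * 27 + 3) + (2 * 28 + 2))
  expect_true(all(pairs2$block %in% 1:2))
})

test_that("pair building warns when the keyword is absent from a block", {
  st <- fake_state(n_trials = 24)
  ev <- st$events
  ev$block <- rep(1:2, each = 12)
  ev$label[ev$block == 2 & ev$label == "/ba/"] <- "/da/"
  expect_warning(
    pairs <- build_training_pairs(st$pc, st$frame_times, 31L, ev, "/ba/"),
    "absent from block"
  )
  expect_true(all(pairs$block == 1))
  expect_error(build_training_pairs(st$pc, st$frame_times, 31L, st$events,
                                    "/zz/"), "unknown keyword")
})

test_that("PA-I first step moves exactly along the pair difference", {
  pc <- rbind(c(2, 0), c(0, 1), c(0.5, 0.5))
  pairs <- data.frame(pos_frame = 1L, neg_center = 2L, block = 1L,
                      type = "utterance")
  model <- train_keyword_classifier(pairs, pc, "/ba/", C = 1, epochs = 1L,
                                    halfwidth = 0L, seed = 1)
  d <- pc[1, ] - pc[2, ]
  # w = 0 -> loss = 1, tau = min(C, 1/|d|^2); direction is exactly d
  expect_equal(model$w / sqrt(sum(model$w^2)), d / sqrt(sum(d^2)),
               tolerance = 1e-12)
})

test_that("separable pairs reach zero hinge loss", {
  withr::with_seed(23, {
    # positives at +(2, 2), negatives at -(2, 2): margin 1 achievable
    pc <- rbind(matrix(rep(c(2, 2), 10), ncol = 2, byrow = TRUE) + rnorm(20, sd = 0.1),
                matrix(rep(c(-2, -2), 10), ncol = 2, byrow = TRUE) + rnorm(20, sd = 0.1))
    pairs <- expand.grid(pos_frame = 1:10, neg_center = 11:20)
    pairs$block <- 1L; pairs$type <- "utterance"
    model <- train_keyword_classifier(pairs, pc, "/ba/", C = 1, epochs = 10L,
                                      halfwidth = 0L, seed = 2)
    expect_equal(min(model$epoch_loss), 0)
    # every pair satisfied with margin (on the unscaled boundary, scores
    # separate)
    s_pos <- score_keyword(model, pc[1:10, ])
    s_neg <- score_keyword(model, pc[11:20, ])
    expect_gt(min(s_pos), max(s_neg))
  })
})

test_that("a PA step never increases the current pair's hinge loss", {
  withr::with_seed(29, {
    for (rep in 1:50) {
      k <- sample(2:5, 1)
      w <- rnorm(k)
      xp <- rnorm(k); xn <- rnorm(k)
      loss <- max(0, 1 - sum(w * xp) + sum(w * xn))
      d <- xp - xn
      if (sum(d^2) == 0) next
      tau <- min(1, loss / sum(d^2))
      w2 <- w + tau * d
      loss2 <- max(0, 1 - sum(w2 * xp) + sum(w2 * xn))
      expect_lte(loss2, loss + 1e-12)
    }
  })
})

test_that("scrambled labels give chance-level held-out discrimination", {
  # a single 5 x 55 AUC has null SD ~ 0.14, so average a few scrambles
  st <- fake_state(n_frames = 4000, n_trials = 60, seed = 41, effect = 3)
  held <- fake_state(n_frames = 4000, n_trials = 60, seed = 43, effect = 3)
  fr <- function(lab_is_kw) {
    sel <- (held$events$label == "/ba/") == lab_is_kw
    vapply(held$events$voice_onset[sel], function(s) {
      which.min(abs(held$frame_times - s)) + 31L
    }, integer(1))
  }
  aucs <- vapply(1:8, function(r) {
    ev_scr <- st$events
    withr::with_seed(r, ev_scr$label <- sample(ev_scr$label))
    pairs <- build_training_pairs(st$pc, st$frame_times, 31L, ev_scr, "/ba/")
    model <- train_keyword_classifier(pairs, st$pc, "/ba/", seed = r)
    neurokws:::auc_mann_whitney(
      score_keyword(model, held$pc[fr(TRUE), ]),
      score_keyword(model, held$pc[fr(FALSE), ])
    )
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("scoring is linear and thresholds gate classification", {
  model <- structure(list(keyword = "/ba/", w = c(1, -2), theta = 0.5, C = 1),
                     class = "keyword_model")
  x <- c(2, 0.5)
  expect_equal(score_keyword(model, 3 * x), 3 * score_keyword(model, x))
  expect_true(classify_keyword(model, x))
  expect_false(classify_keyword(model, x, theta = 10))
  expect_error(score_keyword(model, c(1, 2, 3)), "dimension")
  m2 <- model; m2$theta <- NA_real_
  expect_error(classify_keyword(m2, x), "threshold")
  # EER theta: separable scores -> any gap threshold; ties -> higher
  expect_equal(select_theta_eer(c(5, 6), c(-5, -6), grid = seq(-10, 10, 1)), 4)
})
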