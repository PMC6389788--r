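# Small sessions for unit tests; the full-size train/test pair for the
# acceptance criteria is built once per test run and cached.

tiny_config <- function(seed = 42, ...) {
  sim_config(n_channels_vsmc = 6, n_channels_stg = 2, n_channels_other = 1,
             n_blocks = 1, trials_per_block = 12, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_session <- function() cached("tiny_session", generate_session(tiny_config()))

# Acceptance-scale fixture: 2 blocks each, burst_snr = 5, one simulated
# subject (shared profile seed), fixed seeds.
acceptance_sessions <- function() {
  cached("acc_sessions", list(
    train = generate_session(sim_config(seed = 101, profile_seed = 7)),
    test = generate_session(sim_config(seed = 202, profile_seed = 7))
  ))
}

acceptance_fit <- function() {
  cached("acc_fit", {
    s <- acceptance_sessions()
    fit_kws_pipeline(s$train$recording, s$train$events)
  })
}

acceptance_eval <- function() {
  cached("acc_eval", {
    s <- acceptance_sessions()
    apply_kws_pipeline(acceptance_fit(), s$test$recording, s$test$events)
  })
}

# Independent oracle: naive double-loop masked-template normalized
# correlation (cosine over unmasked template entries, full-window energy
# norm), mirroring the documented definition but implemented without
# sliding sums.
naive_masked_cor <- function(X, template, mask) {
  L <- ncol(template)
  n <- ncol(X)
  tm <- template * mask
  qt <- sum(tm^2)
  out <- numeric(n)
  if (qt <= 1e-12) return(out)
  for (t in seq_len(n)) {
    if (t < L) next
    w <- X[, (t - L + 1):t, drop = FALSE]
    den <- sqrt(qt * sum(w^2))
    out[t] <- if (den > 1e-12) sum(tm * w) / den else 0
  }
  out
}

# Independent oracle: AUC by exhaustive pair counting (ties count 1/2).
naive_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# A tiny deterministic recording for IO / referencing tests.
toy_recording <- function(values = NULL, n = 3, len = 2500, rate = 1000,
                          mic = NULL) {
  sig <- if (is.null(values)) {
    matrix(seq_len(n * len) %% 7, n, len)
  } else {
    matrix(rep(values, len), length(values), len)
  }
  ch <- data.frame(
    label = sprintf("e%02d", seq_len(nrow(sig))),
    roi = rep_len(c("vSMC", "STG", "other"), nrow(sig)),
    excluded = FALSE, stringsAsFactors = FALSE
  )
  ecog_recording(sig, rate, ch, mic = mic)
}

toy_events <- function(onsets = c(1.2, 1.8), labels = c("/ba/", "/ti/")) {
  event_table(seq_along(onsets), onsets, labels, rep(1L, length(onsets)))
}
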