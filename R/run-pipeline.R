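#' Run the end-to-end pipeline from session files
#'
#' Orchestrates the full flow: read the training and testing sessions,
#' train every artifact on the training task ([fit_kws_pipeline()]), apply
#' the frozen artifacts to the testing task ([apply_kws_pipeline()]),
#' compute per-keyword ROC/AUC, the VAD test curve, and the simulated
#' keyword-spotting report, and write all artifacts plus a JSON manifest
#' (config hash, seed, package version) and a human-readable log to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()] with `train_path`, `test_path`, and
#'   `out_dir` set.
#' @param null_reps scrambled-label permutation count per keyword for AUC
#'   significance (0 skips the null).
#' @param quiet suppress progress messages.
#' @return list (invisibly): `fit`, `eval`, `rocs`, `kws`, `null`,
#'   `manifest`, `paths`.
#' @export
run_pipeline <- function(config, null_reps = 0L, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$train_path) || is.null(config$test_path) ||
      is.null(config$out_dir)) {
    stop("config must set train_path, test_path and out_dir")
  }
  if (normalizePath(config$train_path, mustWork = FALSE) ==
      normalizePath(config$test_path, mustWork = FALSE)) {
    stop("leakage guard: train and test sessions are the same file")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- "read"
  result <- tryCatch({
    say(stage, "reading sessions")
    train <- read_session(config$train_path)
    test <- read_session(config$test_path)

    stage <- "train"
    say(stage, "fitting templates, PCA, classifiers, VAD threshold")
    fit <- fit_kws_pipeline(train$recording, train$events, config)
    say(stage, sprintf("%d keyword models, %d discrimination templates, PCA k=%d, VAD EER threshold %.2f SD",
                       length(fit$models), length(fit$templates$discrimination),
                       fit$pca$k, fit$vad_threshold))

    stage <- "test"
    say(stage, "applying frozen artifacts to the test session")
    eval <- apply_kws_pipeline(fit, test$recording, test$events)
    rocs <- evaluate_keyword_rocs(fit, eval)
    mic_onsets <- eval$events$voice_onset[!is.na(eval$events$voice_onset)]
    vad_test <- vad_performance(
      eval$outputs, mic_onsets,
      thresholds = seq(config$vad_sweep[1], config$vad_sweep[2],
                       by = config$vad_step),
      tol = config$tolerance_s
    )
    kws <- simulate_kws(fit, eval)

    null <- NULL
    if (null_reps > 0) {
      stage <- "null"
      say(stage, sprintf("scrambled-label null, %d reps per keyword", null_reps))
      state <- pipeline_state(fit, eval)
      null <- lapply(names(fit$models), function(kw) {
        bootstrap_null_auc(state, kw, n_reps = null_reps, seed = config$seed)
      })
      names(null) <- names(fit$models)
    }

    stage <- "write"
    say(stage, "writing artifacts to ", out)
    paths <- write_pipeline_artifacts(config, fit, eval, rocs, vad_test,
                                      kws, null, out)
    say("done", "pipeline complete")
    invisible(list(fit = fit, eval = eval, rocs = rocs, kws = kws,
                   null = null, vad_test = vad_test,
                   manifest = paths$manifest, paths = paths))
  }, error = function(e) {
    say(stage, "ERROR: ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

write_pipeline_artifacts <- function(config, fit, eval, rocs, vad_test, kws,
                                     null, out) {
  cfg_plain <- unclass(config)
  cfg_plain$out_dir <- NULL
  manifest <- list(
    package = "neurokws",
    version = as.character(utils::packageVersion("neurokws")),
    config = cfg_plain,
    config_hash = fnv1a(cfg_plain),
    seed = config$seed,
    train_session = fit$session_id,
    test_session = eval$session_id,
    n_keyword_models = length(fit$models),
    keyword_models = names(fit$models),
    n_discrimination_templates = length(fit$templates$discrimination),
    discrimination_templates = names(fit$templates$discrimination),
    pca_k = fit$pca$k
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  tpl_dir <- file.path(out, "templates")
  dir.create(tpl_dir, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(fit$templates$response),
                     file.path(tpl_dir, "response.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(fit$templates$vad),
                     file.path(tpl_dir, "vad.tsv"), sep = "\t")
  for (k in names(fit$templates$discrimination)) {
    safe <- gsub("/", "", k)
    data.table::fwrite(
      data.table::as.data.table(fit$templates$discrimination[[k]]$template),
      file.path(tpl_dir, paste0(safe, ".tsv")), sep = "\t")
  }

  models_path <- file.path(out, "models.json")
  jsonlite::write_json(
    lapply(fit$models, function(m) {
      list(keyword = m$keyword, w = m$w, theta = m$theta, C = m$C)
    }),
    models_path, auto_unbox = TRUE, digits = NA
  )

  det <- causal_peak_pick(eval$outputs, fit$vad_threshold)
  det_path <- file.path(out, "detections.csv")
  det_out <- as.data.frame(det)
  det_out$threshold <- rep(fit$vad_threshold, nrow(det_out))
  data.table::fwrite(det_out, det_path)

  report <- list(
    vad = list(
      threshold = fit$vad_threshold,
      train_curve = as.data.frame(fit$vad_curve),
      test_curve = as.data.frame(vad_test)
    ),
    auc = lapply(rocs, function(r) r$auc),
    kws = as.data.frame(kws)
  )
  if (!is.null(null)) {
    report$null <- lapply(null, function(x) {
      list(cutoff = x$cutoff, mean = mean(x$null), n_reps = x$n_reps)
    })
  }
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)

  list(manifest = manifest, manifest_path = manifest_path,
       models = models_path, detections = det_path, report = report_path,
       templates = tpl_dir)
}

#' Plot an ROC curve to SVG
#'
#' @param rocs named list of [roc_auc()] results.
#' @param path output SVG file.
#' @return `path`, invisibly.
#' @export
plot_rocs_svg <- function(rocs, path) {
  grDevices::svg(path, width = 6, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate", main = "Keyword discrimination ROC")
  abline(0, 1, lty = 3, col = "grey60")
  cols <- grDevices::hcl.colors(max(length(rocs), 2L), "Dark 3")
  for (i in seq_along(rocs)) {
    lines(c(rocs[[i]]$fpr, 1), c(rocs[[i]]$tpr, 1), col = cols[i])
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.2f)", names(rocs),
                          vapply(rocs, `[[`, numeric(1), "auc")),
         col = cols[seq_along(rocs)], lty = 1, cex = 0.6, bty = "n")
  invisible(path)
}
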