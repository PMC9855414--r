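#' Run the full per-strip feature extraction for one subject
#'
#' For each requested strip: R-peak detection on the 10-min strip signal,
#' fixed 50/75-sample beat segmentation, the automated quality filter,
#' wavelet delineation, and 26-feature extraction. Strip label and timing are
#' attached to every beat row.
#'
#' @param subject A `synthetic_subject`, or a list with an `ecg_record`
#'   (`$record`) and a BG table (`$bg` with `time_s`, `glucose_mgdl`).
#' @param cfg A [pipeline_config()].
#' @param strip_ids Which strips to process (default: all usable, i.e.
#'   non-excluded-label, strips).
#' @return A list: `features` (one row per usable beat: identifiers, `label`,
#'   `strip_id`, `strip_start_s`, and the 26 features), `strips` (the strip
#'   table), and `counts` (per-strip tallies of detected R peaks, boundary
#'   drops, quality rejections by reason, delineation failures, and feature
#'   rows).
#' @export
extract_subject_features <- function(subject, cfg = pipeline_config(),
                                     strip_ids = NULL) {
  record <- subject$record
  strips <- match_ecg_to_bg(record, subject$bg, cfg)
  if (is.null(strip_ids)) strip_ids <- strips$strip_id[strips$usable]
  fs <- cfg$sampling_rate_hz
  res <- purrr::map(strip_ids, function(sid) {
    st <- strips[strips$strip_id == sid, ]
    i0 <- as.integer(round((st$start_s - record$start_time_s) * fs)) + 1L
    i1 <- as.integer(round((st$end_s - record$start_time_s) * fs))
    x <- record$samples[i0:i1]
    r <- detect_r_peaks(x, cfg)
    bs <- segment_beats(x, r, cfg, start_time_s = st$start_s)
    bs <- quality_filter(bs, cfg)
    fid <- delineate(bs, cfg)
    feats <- extract_features(fid, bs, cfg)
    if (nrow(feats)) {
      feats <- feats |>
        mutate(subject_id = subject$subject_id %||% record$subject_id,
               strip_id = sid, strip_start_s = st$start_s,
               label = st$label, .before = 1)
    }
    counts <- tibble(
      strip_id = sid,
      n_r_peaks = length(r),
      n_boundary_dropped = bs$n_boundary_dropped,
      n_segmented = ncol(bs$samples),
      n_quality_rejected = sum(!bs$info$accepted),
      n_delineation_failed = sum(bs$info$accepted & !fid$ok),
      n_features = nrow(feats))
    list(features = feats, counts = counts)
  })
  features <- purrr::list_rbind(purrr::map(res, "features"))
  counts <- purrr::list_rbind(purrr::map(res, "counts"))
  list(features = features, strips = strips, counts = counts)
}

#' Train, score and evaluate one subject
#'
#' The per-subject study protocol: split the usable strips 10/5/5 (train on
#' 10 euglycemic strips, validate on 5 euglycemic + 5 dysglycemic), fit the
#' linear one-class SVM on the training beats, score every validation beat,
#' aggregate votes into 10-s windows, and compute metrics at both levels
#' (window-level AUC uses the dysglycemic-vote fraction as the continuous
#' score).
#'
#' @param subject A `synthetic_subject` (or compatible list, see
#'   [extract_subject_features()]).
#' @param seed Seed for the strip split.
#' @param cfg A [pipeline_config()].
#' @return A list of class `subject_run`: `model`, `beat_preds`,
#'   `window_preds`, `metrics` (two rows), `split`, `counts`.
#' @export
run_subject <- function(subject, seed, cfg = pipeline_config()) {
  ext <- extract_subject_features(subject, cfg)
  split <- split_records(ext$strips, seed, cfg)
  feats <- ext$features |>
    left_join(split[c("strip_id", "split")], by = "strip_id")
  train <- feats |> filter(.data$split == "train")
  val <- feats |> filter(.data$split == "val")
  model <- fit_subject_model(train, cfg,
                             subject_id = subject$subject_id %||% "s1")
  beat_preds <- predict_beats(model, val)
  window_preds <- vote_windows(beat_preds, cfg)
  m_beat <- compute_metrics(beat_preds, level = "beat",
                            subject_id = model$subject_id)
  m_win <- window_preds |>
    filter(.data$n_beats > 0) |>
    mutate(score = .data$window_score) |>
    compute_metrics(level = "window10s", subject_id = model$subject_id)
  structure(
    list(model = model, beat_preds = beat_preds, window_preds = window_preds,
         metrics = bind_rows(m_beat, m_win), split = split,
         counts = ext$counts, val_features = val),
    class = "subject_run")
}

#' Run the full study replica on a synthetic cohort
#'
#' Simulates (or accepts) a cohort, applies the subject inclusion filters,
#' runs the per-subject protocol, and aggregates: cohort mean/SD of every
#' metric at beat and 10-s level, cohort-averaged feature importance, and the
#' pooled euglycemia-vs-dysglycemia feature comparison. Rerunning with the
#' same configuration and seed reproduces the report exactly.
#'
#' @param n_subjects Number of subjects to simulate (ignored when `cohort` is
#'   given).
#' @param effect_scale Between-state effect multiplier (0 = null cohort).
#' @param seed Master seed (simulation and splits).
#' @param cfg A [pipeline_config()].
#' @param jitter_frac Within-subject jitter scale (see [simulate_subject()]).
#' @param cohort Optional pre-built list of subjects.
#' @param out_dir Optional directory: writes the manifest, per-subject model
#'   JSONs, metrics CSV and report JSON.
#' @return A `cohort_report`: `subject_metrics`, `summary`, `importance`,
#'   `feature_comparison`, `counts`, `manifest`, and `runs` (per-subject
#'   results).
#' @export
run_study <- function(n_subjects = 10, effect_scale = 1, seed = 42,
                      cfg = pipeline_config(), jitter_frac = cfg$jitter_frac,
                      cohort = NULL, out_dir = NULL) {
  t_start <- Sys.time()
  if (is.null(cohort)) {
    if (n_subjects < 1) {
      abort("run_study: n_subjects must be >= 1", class = "ecgdys_config_error")
    }
    cohort <- make_cohort(n_subjects, effect_scale = effect_scale, seed = seed,
                          cfg = cfg, jitter_frac = jitter_frac)
  }
  summary_df <- tibble(
    subject_id = vapply(cohort, function(s) s$subject_id, character(1)),
    n_bg = vapply(cohort, function(s) nrow(s$bg), integer(1)),
    n_dys = vapply(cohort, function(s)
      sum(label_bg(s$bg$glucose_mgdl, cfg) == "dysglycemia"), integer(1)),
    n_eu = vapply(cohort, function(s)
      sum(label_bg(s$bg$glucose_mgdl, cfg) == "euglycemia"), integer(1)),
    af_or_pacemaker = vapply(cohort, function(s)
      isTRUE(s$af_or_pacemaker), logical(1)))
  retained <- filter_subjects(summary_df, cfg)$retained
  cohort <- cohort[retained]
  if (!length(cohort)) {
    abort("run_study: no subject passes the inclusion filters",
          class = "ecgdys_data_error")
  }
  runs <- purrr::imap(cohort, function(s, i) {
    tryCatch(run_subject(s, seed = seed + 10000L + i, cfg = cfg),
             error = function(e) {
               abort(sprintf("stage failure for subject %s: %s",
                             s$subject_id, conditionMessage(e)),
                     class = "ecgdys_stage_error", parent = e)
             })
  })
  metrics <- purrr::list_rbind(purrr::map(runs, "metrics"))
  val_feats <- purrr::list_rbind(purrr::map(runs, "val_features"))
  models <- purrr::map(runs, "model")
  report <- structure(
    list(subject_metrics = metrics,
         summary = aggregate_cohort(metrics),
         importance = feature_importance(models),
         feature_comparison = feature_comparison(val_feats),
         counts = purrr::list_rbind(
           purrr::imap(runs, function(r, i)
             mutate(r$counts, subject_id = models[[i]]$subject_id,
                    .before = 1))),
         manifest = list(
           config = unclass(cfg),
           config_digest = config_digest(cfg),
           seed = seed,
           effect_scale = effect_scale,
           jitter_frac = jitter_frac,
           n_subjects_simulated = length(retained),
           n_subjects_retained = length(cohort),
           started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
           finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
         runs = runs),
    class = "cohort_report")
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects\n",
              x$manifest$n_subjects_retained))
  s <- x$summary |>
    filter(.data$metric %in% c("auc", "sensitivity", "specificity")) |>
    mutate(txt = sprintf("%s %.2f +/- %.2f", .data$metric, .data$mean,
                         .data$sd))
  for (lv in unique(s$level)) {
    cat(" ", lv, ": ", paste(s$txt[s$level == lv], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$subject_metrics, file.path(out_dir, "subject_metrics.csv"),
            row.names = FALSE)
  write.csv(report$summary, file.path(out_dir, "cohort_summary.csv"),
            row.names = FALSE)
  write.csv(report$importance, file.path(out_dir, "feature_importance.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (r in report$runs) {
    m <- r$model
    jsonlite::write_json(
      list(subject_id = m$subject_id, nu = m$nu, rho = m$rho,
           feature_scaling = m$feature_scaling,
           weights = as.list(m$weights),
           scaler = m$scaler,
           train_outlier_fraction = m$train_outlier_fraction,
           sv_fraction = m$sv_fraction, n_train_beats = m$n_train_beats),
      file.path(out_dir, sprintf("model_%s.json", m$subject_id)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
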