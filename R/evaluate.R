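#' Classification metrics for one subject at one level
#'
#' AUC is computed by the rank statistic (Mann-Whitney with midranks for
#' ties), with dysglycemia as the positive class throughout. Sensitivity,
#' specificity, PPV and NPV are taken at the operating point: `score >
#' threshold` for beats, or the majority-vote label when the predictions
#' carry a `pred` column (windows).
#'
#' @param preds A predictions tibble with `score`, the truth column `label`
#'   (`euglycemia`/`dysglycemia`), and optionally `pred`. Unlabelled rows
#'   (empty windows) are dropped.
#' @param level `"beat"` or `"window10s"`, recorded in the output.
#' @param threshold Decision threshold on `score` when no `pred` column is
#'   present.
#' @param subject_id Recorded in the output.
#' @return A one-row tibble: `subject_id`, `level`, `auc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(preds, level = "beat", threshold = 0,
                            subject_id = NULL) {
  subject_id <- subject_id %||%
    (if ("subject_id" %in% names(preds)) preds$subject_id[1] else "s1")
  stopifnot(all(c("score", "label") %in% names(preds)))
  preds <- preds[!is.na(preds$score) & !is.na(preds$label), , drop = FALSE]
  truth_pos <- preds$label == "dysglycemia"
  n_pos <- sum(truth_pos); n_neg <- sum(!truth_pos)
  if (n_pos == 0 || n_neg == 0) {
    abort(sprintf(
      "compute_metrics: both classes required (have %d dysglycemic, %d euglycemic); AUC undefined",
      n_pos, n_neg), class = "ecgdys_metrics_error")
  }
  auc <- rank_auc(preds$score, truth_pos)
  pred_pos <- if ("pred" %in% names(preds)) {
    preds$pred == "dysglycemia"
  } else {
    preds$score > threshold
  }
  tp <- sum(pred_pos & truth_pos); fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fp <- sum(pred_pos & !truth_pos)
  tibble(subject_id = subject_id, level = level, auc = auc,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         n_pos = n_pos, n_neg = n_neg)
}

# Mann-Whitney AUC with midranks; positive = logical vector
rank_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (mean(r[positive]) - (n_pos + 1) / 2) / n_neg
}

#' Aggregate per-subject metrics into a cohort report table
#'
#' Unweighted per-subject mean and sample standard deviation (n - 1) of each
#' metric, by level — the "mean (SD)" presentation used for cohort
#' performance tables.
#'
#' @param metrics Row-bound outputs of [compute_metrics()], >= 2 subjects per
#'   level.
#' @return A tibble: `level`, `metric`, `mean`, `sd`, `n_subjects`.
#' @export
aggregate_cohort <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  metrics |>
    pivot_longer(c("auc", "sensitivity", "specificity", "ppv", "npv",
                   "accuracy"),
                 names_to = "metric", values_to = "value") |>
    group_by(.data$level, .data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_subjects = dplyr::n(), .groups = "drop")
}

#' Compare feature distributions between glycemic states
#'
#' Pooled-beat mean and SD per class for each of the 26 features, with a
#' two-sided Welch (unequal-variance) t-test p-value. Zero-variance features
#' get no p-value and a note.
#'
#' @param features Feature tibble with a `label` column containing both
#'   classes (>= 2 beats each).
#' @return A tibble: `feature`, `mean_eu`, `sd_eu`, `mean_dys`, `sd_dys`,
#'   `p_value`, `note`.
#' @export
feature_comparison <- function(features) {
  if (!"label" %in% names(features)) {
    abort("feature_comparison: needs a 'label' column",
          class = "ecgdys_data_error")
  }
  keep <- features$label %in% glycemic_levels()[1:2]
  X <- feature_matrix(features[keep, , drop = FALSE])
  lab <- features$label[keep]
  eu <- lab == "euglycemia"
  if (sum(eu) < 2 || sum(!eu) < 2) {
    abort("feature_comparison: need >= 2 beats per class",
          class = "ecgdys_data_error")
  }
  purrr::map(colnames(X), function(f) {
    x_eu <- X[eu, f]; x_dys <- X[!eu, f]
    degenerate <- sd(x_eu) < 1e-12 && sd(x_dys) < 1e-12
    p <- if (degenerate) NA_real_ else t.test(x_eu, x_dys)$p.value
    tibble(feature = f,
           mean_eu = mean(x_eu), sd_eu = sd(x_eu),
           mean_dys = mean(x_dys), sd_dys = sd(x_dys),
           p_value = p,
           note = if (degenerate) "zero variance in both classes"
                  else NA_character_)
  }) |> purrr::list_rbind()
}
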