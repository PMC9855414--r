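#' Tidy a fitted subject model
#'
#' One row per feature: hyperplane weight, importance (absolute weight),
#' rank, and the recorded training scaler statistics.
#'
#' @param x A `subject_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.subject_model <- function(x, ...) {
  feature_importance(x) |>
    left_join(x$scaler, by = "feature") |>
    select("feature", "weight", "importance", "rank", "mean", "sd", "used")
}

#' One-row summary of a fitted subject model
#'
#' @param x A `subject_model`.
#' @param ... Unused.
#' @return A one-row tibble: `subject_id`, `nu`, `rho`,
#'   `train_outlier_fraction`, `sv_fraction`, `n_train_beats`, `n_features`.
#' @export
glance.subject_model <- function(x, ...) {
  tibble(subject_id = x$subject_id, nu = x$nu, rho = x$rho,
         train_outlier_fraction = x$train_outlier_fraction,
         sv_fraction = x$sv_fraction, n_train_beats = x$n_train_beats,
         n_features = sum(x$scaler$used))
}

#' Tidy a cohort report
#'
#' The long cohort summary: mean and SD of each metric per prediction level.
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return A tibble: `level`, `metric`, `mean`, `sd`, `n_subjects`.
#' @export
tidy.cohort_report <- function(x, ...) x$summary

#' One-row summary of a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline AUCs at both levels.
#' @export
glance.cohort_report <- function(x, ...) {
  s <- x$summary
  pick <- function(lv) s$mean[s$level == lv & s$metric == "auc"]
  tibble(n_subjects = x$manifest$n_subjects_retained,
         beat_auc_mean = pick("beat"),
         window_auc_mean = pick("window10s"),
         seed = x$manifest$seed,
         effect_scale = x$manifest$effect_scale)
}
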