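#' Fit the per-subject linear one-class SVM on euglycemic beats
#'
#' The personalized anomaly detector: a nu one-class SVM with a linear kernel
#' trained only on a subject's euglycemic beats. nu (0.75) upper-bounds the
#' fraction of training errors and lower-bounds the fraction of support
#' vectors; both bounds are recorded on the fitted model. Fitting is
#' deterministic for a fixed input order (libsvm with a fixed solver
#' tolerance; no randomized initialization).
#'
#' Features enter the solver in their native units by default
#' (`cfg$feature_scaling = "none"`); `"sd"` divides each feature by its
#' training standard deviation without centering. Centering is deliberately
#' not offered: a linear one-class SVM separates the data from the origin, and
#' mean-centred training data make the zero vector the dual optimum — see the
#' methods vignette. Per-feature training means and SDs are recorded on the
#' model either way; zero-variance features are dropped with a note.
#'
#' @param train_features A feature tibble from [extract_features()] (only the
#'   26 canonical feature columns are used). All beats must be euglycemic; if
#'   a `label` column is present this is checked.
#' @param cfg A [pipeline_config()].
#' @param subject_id Identifier stored on the model.
#' @return A `subject_model`: hyperplane weights `w` (named), offset `rho`,
#'   `nu`, the per-feature scaler table, `train_outlier_fraction`,
#'   `sv_fraction`, and `n_train_beats`. Decision scores from
#'   [predict_beats()] are `-(w . x - rho)`, so positive means dysglycemic.
#' @export
fit_subject_model <- function(train_features, cfg = pipeline_config(),
                              subject_id = "s1") {
  if ("label" %in% names(train_features) &&
      any(train_features$label != "euglycemia")) {
    abort("fit_subject_model: training beats must all be euglycemic",
          class = "ecgdys_training_error")
  }
  X <- feature_matrix(train_features)
  if (nrow(X) < cfg$min_train_beats) {
    abort(sprintf("fit_subject_model: %d training beats < required %d",
                  nrow(X), cfg$min_train_beats),
          class = "ecgdys_training_error")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  used <- sdv > 1e-12
  dropped <- colnames(X)[!used]
  if (length(dropped)) {
    warn(sprintf("fit_subject_model: dropping zero-variance feature(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  scale_div <- if (cfg$feature_scaling == "sd") sdv else rep(1, ncol(X))
  Xs <- sweep(X[, used, drop = FALSE], 2, scale_div[used], "/")
  fit <- e1071::svm(Xs, y = NULL, type = "one-classification",
                    kernel = "linear", nu = cfg$nu, scale = FALSE,
                    tolerance = cfg$svm_tolerance)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(Xs)
  dec <- as.numeric(Xs %*% w) - fit$rho
  structure(
    list(subject_id = subject_id,
         weights = w,
         rho = fit$rho,
         nu = cfg$nu,
         feature_scaling = cfg$feature_scaling,
         scaler = tibble(feature = colnames(X), mean = as.numeric(mu),
                         sd = as.numeric(sdv), used = used,
                         scale_div = as.numeric(scale_div)),
         train_outlier_fraction = mean(dec < 0),
         sv_fraction = nrow(fit$SV) / nrow(Xs),
         n_train_beats = nrow(Xs)),
    class = "subject_model")
}

feature_matrix <- function(features) {
  need <- ecg_feature_names()
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    abort(sprintf("missing feature column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ecgdys_prediction_error")
  }
  X <- as.matrix(features[need])
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("feature matrix contains non-finite values",
          class = "ecgdys_prediction_error")
  }
  X
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "<subject_model> %s: linear one-class SVM, nu = %g, %d training beats\n",
    x$subject_id, x$nu, x$n_train_beats))
  cat(sprintf("  train outlier fraction %.3f, support-vector fraction %.3f\n",
              x$train_outlier_fraction, x$sv_fraction))
  invisible(x)
}

#' Score beats against a fitted subject model
#'
#' The signed decision value is `score = -(w . x - rho)`: positive scores lie
#' on the anomalous side of the hyperplane and are labelled dysglycemic;
#' scores of exactly zero (on the hyperplane) are euglycemic. A pure function
#' of the model and the features.
#'
#' @param model A `subject_model`.
#' @param features A feature tibble; must contain every canonical feature
#'   column (a missing feature is an error naming it). Identifier columns
#'   (`beat`, `r_time_s`, `strip_id`, `label`, ...) are passed through.
#' @return The pass-through columns plus `score` and `pred` (factor
#'   `euglycemia`/`dysglycemia`).
#' @export
predict_beats <- function(model, features) {
  stopifnot(inherits(model, "subject_model"))
  X <- feature_matrix(features)
  sc <- model$scaler
  used <- sc$feature[sc$used]
  Xs <- sweep(X[, used, drop = FALSE], 2, sc$scale_div[sc$used], "/")
  score <- -(as.numeric(Xs %*% model$weights[used]) - model$rho)
  keep <- intersect(c("beat", "r_time_s", "strip_id", "strip_start_s",
                      "label", "subject_id"), names(features))
  bind_cols(as_tibble(features[keep]),
            tibble(score = score,
                   pred = factor(ifelse(score > 0, "dysglycemia", "euglycemia"),
                                 levels = glycemic_levels()[1:2])))
}

#' Aggregate beat predictions into 10-s majority-vote windows
#'
#' Each strip is partitioned into consecutive `[k*10, (k+1)*10)` s windows
#' from its start; every beat votes with its R time. A window is labelled
#' dysglycemic when dysglycemic votes reach at least half of its beats (ties
#' go to dysglycemia: sensitivity is the clinically primary operating
#' property). The continuous window score is the dysglycemic vote fraction.
#' Windows containing no beat are emitted unlabelled and flagged.
#'
#' @param preds Beat predictions from [predict_beats()] for one or more
#'   strips; needs `r_time_s`, `pred`, `strip_id`, and `strip_start_s` (the
#'   strip's first second; `label`/`subject_id` pass through if present).
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per window: `strip_id`, `window`,
#'   `window_start_s`, `n_beats`, `n_dys_votes`, `window_score`, `pred`.
#' @export
vote_windows <- function(preds, cfg = pipeline_config()) {
  need <- c("r_time_s", "pred", "strip_id", "strip_start_s")
  missing <- setdiff(need, names(preds))
  if (length(missing)) {
    abort(sprintf("vote_windows: missing column(s) %s",
                  paste(missing, collapse = ", ")), class = "ecgdys_data_error")
  }
  vw <- cfg$vote_window_s
  n_windows <- as.integer(ceiling(cfg$bg_corr_window_s / vw))
  carry <- intersect(c("label", "subject_id"), names(preds))
  strips <- preds |>
    distinct(.data$strip_id, .data$strip_start_s,
             across(dplyr::all_of(carry)))
  grid <- strips |>
    tidyr::crossing(window = seq_len(n_windows) - 1L) |>
    mutate(window_start_s = .data$strip_start_s + .data$window * vw)
  votes <- preds |>
    mutate(window = as.integer(floor((.data$r_time_s - .data$strip_start_s) / vw))) |>
    filter(.data$window >= 0L, .data$window < n_windows) |>
    group_by(.data$strip_id, .data$window) |>
    summarise(n_beats = dplyr::n(),
              n_dys_votes = sum(.data$pred == "dysglycemia"),
              .groups = "drop")
  grid |>
    left_join(votes, by = c("strip_id", "window")) |>
    mutate(
      n_beats = dplyr::coalesce(.data$n_beats, 0L),
      n_dys_votes = dplyr::coalesce(.data$n_dys_votes, 0L),
      window_score = ifelse(.data$n_beats > 0,
                            .data$n_dys_votes / .data$n_beats, NA_real_),
      pred = factor(
        ifelse(.data$n_beats == 0, NA_character_,
               ifelse(2L * .data$n_dys_votes >= .data$n_beats,
                      "dysglycemia", "euglycemia")),
        levels = glycemic_levels()[1:2])) |>
    arrange(.data$strip_id, .data$window)
}

#' Rank features by hyperplane weight magnitude
#'
#' For a linear one-class SVM the hyperplane normal's coefficients are the
#' feature weights; the longer the component, the more that feature moves the
#' decision value. Importance is `|w_j|` on the solver's feature scale,
#' descending, ties broken by canonical feature order. Because the model is
#' fitted on euglycemic beats only, this ranking reflects the geometry of
#' normal beats — not validation-class separation (see the methods vignette).
#'
#' @param model A `subject_model`, or a list of them for the cohort aggregate
#'   (mean importance across subject models).
#' @return A tibble `feature`, `weight` (NA for the cohort aggregate),
#'   `importance`, `rank`.
#' @export
feature_importance <- function(model) {
  if (inherits(model, "subject_model")) {
    imp <- tibble(feature = names(model$weights),
                  weight = as.numeric(model$weights),
                  importance = abs(as.numeric(model$weights)))
  } else {
    stopifnot(length(model) > 0,
              all(vapply(model, inherits, logical(1), "subject_model")))
    per <- purrr::map(model, function(m) {
      tibble(feature = names(m$weights), importance = abs(m$weights))
    }) |> purrr::list_rbind()
    imp <- per |>
      group_by(.data$feature) |>
      summarise(importance = mean(.data$importance), .groups = "drop") |>
      mutate(weight = NA_real_)
  }
  canon <- ecg_feature_names()
  imp |>
    arrange(desc(.data$importance), match(.data$feature, canon)) |>
    mutate(rank = dplyr::row_number()) |>
    select("feature", "weight", "importance", "rank")
}

#' Per-feature ANOVA F statistics between glycemic states
#'
#' A separate, model-free importance report: the one-way ANOVA F statistic of
#' each feature between euglycemic and dysglycemic beats (equivalent to the
#' squared two-sample t statistic). This is *not* the hyperplane-weight
#' ranking of [feature_importance()]; the two answer different questions and
#' are reported side by side.
#'
#' @param features Feature tibble with a `label` column containing both
#'   classes.
#' @return A tibble `feature`, `f_stat`, `rank`.
#' @export
feature_f_scores <- function(features) {
  if (!"label" %in% names(features)) {
    abort("feature_f_scores: needs a 'label' column", class = "ecgdys_data_error")
  }
  lab <- features$label
  if (length(unique(lab[lab %in% glycemic_levels()[1:2]])) < 2) {
    abort("feature_f_scores: need both classes present",
          class = "ecgdys_data_error")
  }
  keep <- lab %in% glycemic_levels()[1:2]
  X <- feature_matrix(features[keep, ])
  g <- factor(as.character(lab[keep]))
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  m1 <- colMeans(X[g == levels(g)[1], , drop = FALSE])
  m2 <- colMeans(X[g == levels(g)[2], , drop = FALSE])
  mall <- colMeans(X)
  ssb <- n1 * (m1 - mall)^2 + n2 * (m2 - mall)^2
  ssw <- colSums((X - rep(ifelse(g == levels(g)[1], 1, 0), ncol(X)) *
                    rep(m1, each = nrow(X)) -
                    rep(ifelse(g == levels(g)[2], 1, 0), ncol(X)) *
                    rep(m2, each = nrow(X)))^2)
  f <- ssb / (ssw / (n1 + n2 - 2))
  tibble(feature = names(f), f_stat = as.numeric(f)) |>
    arrange(desc(.data$f_stat)) |>
    mutate(rank = dplyr::row_number())
}
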