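#' Plot beats from a beat set
#'
#' Overlays up to `n` beats (time relative to the R peak), coloured by
#' quality-filter acceptance.
#'
#' @param object A `beat_set`.
#' @param n Maximum number of beats to draw.
#' @param cfg A [pipeline_config()] (for the sampling rate).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beat_set <- function(object, n = 30, cfg = pipeline_config(), ...) {
  m <- ncol(object$samples)
  if (!m) abort("empty beat_set", class = "ecgdys_data_error")
  pick <- seq_len(min(n, m))
  fs <- cfg$sampling_rate_hz
  t_rel <- (seq_len(nrow(object$samples)) - (cfg$pre_r_samples + 1L)) / fs
  df <- purrr::map(pick, function(i) {
    tibble(beat = object$info$beat[i], t = t_rel,
           v = object$samples[, i],
           accepted = object$info$accepted[i])
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$v, group = .data$beat,
                                   colour = .data$accepted)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey25",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "time from R peak (s)", y = "voltage (mV)",
                  colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Plot one delineated beat
#'
#' The beat trace with its located P, Q, R, S, T points.
#'
#' @param beats A `beat_set`.
#' @param fiducials Output of [delineate()] on `beats`.
#' @param beat Which beat number to draw.
#' @param cfg A [pipeline_config()].
#' @return A ggplot object.
#' @export
plot_delineation <- function(beats, fiducials, beat = 1,
                             cfg = pipeline_config()) {
  fs <- cfg$sampling_rate_hz
  i <- match(beat, beats$info$beat)
  f <- fiducials[fiducials$beat == beat, ]
  if (is.na(i) || !nrow(f)) {
    abort("beat not found", class = "ecgdys_data_error")
  }
  t_rel <- (seq_len(nrow(beats$samples)) - (cfg$pre_r_samples + 1L)) / fs
  df <- tibble(t = t_rel, v = beats$samples[, i])
  pts <- tibble(
    wave = c("P", "Q", "R", "S", "T"),
    idx = c(f$idx_p, f$idx_q, f$idx_r, f$idx_s, f$idx_t),
    amp = c(f$amp_p, f$amp_q, f$amp_r, f$amp_s, f$amp_t)) |>
    filter(!is.na(.data$idx)) |>
    mutate(t = t_rel[.data$idx])
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$v)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$amp),
                        colour = "firebrick", size = 2) +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(y = .data$amp, label = .data$wave),
                       vjust = -1, colour = "firebrick") +
    ggplot2::labs(x = "time from R peak (s)", y = "voltage (mV)") +
    ggplot2::theme_minimal()
}

#' Feature-importance bar chart for a subject model
#'
#' @param object A `subject_model`.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subject_model <- function(object, top_n = 12, ...) {
  imp <- feature_importance(object) |> head(top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|hyperplane weight|",
                  title = sprintf("Feature importance, subject %s",
                                  object$subject_id)) +
    ggplot2::theme_minimal()
}

#' ROC curve for a set of predictions
#'
#' Threshold sweep over the continuous score with dysglycemia positive.
#'
#' @param preds Tibble with `score` and `label`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_roc <- function(preds, title = NULL) {
  preds <- preds[!is.na(preds$score) & !is.na(preds$label), ]
  pos <- preds$label == "dysglycemia"
  ord <- order(preds$score, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", title = title) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Cohort metric summary plot
#'
#' Mean with +/- 1 SD error bars for each metric at beat and 10-s window
#' level.
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$metric, .data$mean,
                               fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = pmin(1, .data$mean + .data$sd)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean over subjects (+/- SD)", fill = NULL) +
    ggplot2::theme_minimal()
}
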