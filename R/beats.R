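#' Detect R peaks in a single-lead ECG strip
#'
#' A deterministic Pan-Tompkins-style chain: zero-phase Butterworth band-pass
#' (5-15 Hz), derivative, squaring, 150 ms moving-window integration, fixed
#' quantile threshold on the integrated energy, greedy peak picking with a
#' 0.3 s refractory period, and refinement of each peak to the local maximum
#' of `|signal|` in a small neighbourhood.
#'
#' @param x Numeric signal (mV) or an [ecg_record()]; at least 2 s.
#' @param cfg A [pipeline_config()].
#' @return Strictly increasing integer sample indices of R peaks (possibly
#'   empty for flat signal, with a warning).
#' @export
detect_r_peaks <- function(x, cfg = pipeline_config()) {
  if (inherits(x, "ecg_record")) x <- x$samples
  fs <- cfg$sampling_rate_hz
  if (length(x) < 2 * fs) {
    abort("detect_r_peaks: need at least 2 s of signal",
          class = "ecgdys_data_error")
  }
  if (all(abs(x - x[1]) < 1e-12)) {
    warn("detect_r_peaks: flat signal, no peaks")
    return(integer(0))
  }
  bp <- signal::butter(2, c(cfg$rpeak_band_low_hz, cfg$rpeak_band_high_hz) /
                         (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf))
  sq <- d^2
  k <- max(3L, as.integer(round(cfg$rpeak_mwi_ms / 1000 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / k, k), sides = 2))
  mwi[is.na(mwi)] <- 0
  thr <- 0.2 * quantile(mwi, 0.98, names = FALSE)
  if (thr <= 0) {
    warn("detect_r_peaks: no QRS energy above threshold")
    return(integer(0))
  }
  is_peak <- mwi > thr &
    mwi >= c(-Inf, mwi[-length(mwi)]) & mwi >= c(mwi[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(integer(0))
  ## greedy refractory: strongest first, suppress neighbours within 0.3 s
  refr <- as.integer(round(cfg$rpeak_refractory_s * fs))
  cand <- cand[order(mwi[cand], decreasing = TRUE)]
  keep <- logical(length(x))
  sel <- integer(0)
  for (i in cand) {
    lo <- max(1L, i - refr); hi <- min(length(x), i + refr)
    if (!any(keep[lo:hi])) { keep[i] <- TRUE; sel <- c(sel, i) }
  }
  sel <- sort(sel)
  ## refine to the raw-signal extremum near the energy peak
  half <- as.integer(round(0.08 * fs))
  r <- vapply(sel, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  r <- sort(unique(r))
  # a refined pair can collapse below the refractory gap; keep the first
  if (length(r) > 1) r <- r[c(TRUE, diff(r) > refr)]
  r
}

#' Segment a signal into fixed one-second beats
#'
#' Each R peak yields a beat of `pre_r_samples` (50) samples before and
#' `post_r_samples` (75) samples after the peak — the 2:3 split of a 1 s
#' window at 125 Hz, R pinned at index 51 (1-based). Beats without full
#' support inside the signal are dropped and counted. `rr_next_s` is the
#' interval to the next detected R peak (absent for the final beat).
#'
#' @param x Numeric signal (mV) or an [ecg_record()].
#' @param r_indices R-peak sample indices from [detect_r_peaks()].
#' @param cfg A [pipeline_config()].
#' @param start_time_s Time of sample 1, used for beat timestamps.
#' @return A `beat_set`: list with `samples` (a `beat_length x n` matrix) and
#'   `info` (tibble: `beat`, `r_index`, `r_time_s`, `rr_next_s`, `accepted`,
#'   `reason`), plus the count of boundary-dropped beats.
#' @export
segment_beats <- function(x, r_indices, cfg = pipeline_config(),
                          start_time_s = 0) {
  if (inherits(x, "ecg_record")) {
    start_time_s <- x$start_time_s
    x <- x$samples
  }
  pre <- cfg$pre_r_samples; post <- cfg$post_r_samples
  fs <- cfg$sampling_rate_hz
  r_indices <- as.integer(r_indices)
  rr_next <- c(diff(r_indices) / fs, NA_real_)
  full <- r_indices - pre >= 1L & r_indices + post - 1L <= length(x)
  n_dropped <- sum(!full)
  r_keep <- r_indices[full]
  rr_keep <- rr_next[full]
  samples <- if (length(r_keep)) {
    vapply(r_keep, function(r) x[(r - pre):(r + post - 1L)],
           numeric(pre + post))
  } else {
    matrix(numeric(0), nrow = pre + post, ncol = 0)
  }
  structure(
    list(samples = samples,
         info = tibble(
           beat = seq_along(r_keep),
           r_index = r_keep,
           r_time_s = start_time_s + (r_keep - 1L) / fs,
           rr_next_s = rr_keep,
           accepted = rep(TRUE, length(r_keep)),
           reason = rep(NA_character_, length(r_keep))),
         n_boundary_dropped = n_dropped,
         cfg_window = c(pre = pre, post = post)),
    class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats (%d accepted, %d boundary-dropped)\n",
              ncol(x$samples), sum(x$info$accepted), x$n_boundary_dropped))
  invisible(x)
}

#' Automated beat-quality filter
#'
#' The reproducible surrogate for manual noise inspection. A beat is rejected
#' when (1) its Pearson correlation with the strip's median-beat template
#' falls below `qc_min_template_cor` (0.8), (2) its peak-to-peak amplitude
#' lies outside `[qc_p2p_lo, qc_p2p_hi]` (0.2-5) times the strip median, or
#' (3) it contains a non-finite sample. With fewer than `qc_min_beats` (8)
#' beats the template is unsupported and all beats are accepted with a
#' warning. Filtering already-accepted beats again rejects nothing.
#'
#' @param beats A `beat_set` from [segment_beats()].
#' @param cfg A [pipeline_config()].
#' @return The `beat_set` with updated `accepted`/`reason` columns.
#' @export
quality_filter <- function(beats, cfg = pipeline_config()) {
  stopifnot(inherits(beats, "beat_set"))
  X <- beats$samples
  n <- ncol(X)
  if (n == 0) return(beats)
  if (n < cfg$qc_min_beats) {
    warn(sprintf(
      "quality_filter: only %d beats (< %d), template unsupported; all accepted",
      n, cfg$qc_min_beats))
    return(beats)
  }
  finite_ok <- colSums(!is.finite(X)) == 0L
  Xf <- X; Xf[!is.finite(Xf)] <- 0
  template <- apply(Xf[, finite_ok, drop = FALSE], 1, median)
  tc <- template - mean(template)
  tn <- sqrt(sum(tc^2))
  Xc <- Xf - rep(colMeans(Xf), each = nrow(Xf))
  cors <- as.numeric(crossprod(Xc, tc)) / (sqrt(colSums(Xc^2)) * tn)
  cors[!is.finite(cors)] <- 0
  p2p <- apply(Xf, 2, function(v) diff(range(v)))
  p2p_med <- median(p2p[finite_ok])
  reason <- rep(NA_character_, n)
  reason[p2p < cfg$qc_p2p_lo * p2p_med | p2p > cfg$qc_p2p_hi * p2p_med] <-
    "amplitude"
  reason[cors < cfg$qc_min_template_cor] <- "correlation"
  reason[!finite_ok] <- "nonfinite"
  beats$info$accepted <- beats$info$accepted & is.na(reason)
  beats$info$reason <- ifelse(is.na(beats$info$reason), reason,
                              beats$info$reason)
  beats
}
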