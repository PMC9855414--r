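#' Canonical feature names
#'
#' The 26 morphology features of one beat, in canonical order: the ten
#' pairwise intervals (s), the R-R interval to the next beat (s), the ten
#' pairwise absolute amplitude differences (mV), and the five signed slope
#' gradients (mV/s).
#'
#' @return Character vector of length 26.
#' @export
ecg_feature_names <- function() {
  pairs <- feature_pairs()
  c(paste0(pairs, "_int"), "rr",
    paste0(pairs, "_amp"),
    paste0(slope_pairs(), "_slope"))
}

feature_pairs <- function() {
  c("pq", "pr", "ps", "pt", "qr", "qs", "qt", "rs", "rt", "st")
}

slope_pairs <- function() c("pr", "pq", "qs", "st", "rt")

#' Delineate P, Q, S and T relative to the known R peak
#'
#' Works on the wavelet-denoised beat (stationary db4 transform, 3 levels,
#' per-beat universal soft threshold). With R pinned at the segmentation
#' anchor: Q is the minimum of the denoised trace in the `q_search_ms` window
#' before R; S the minimum in the `s_search_ms` window after R; P the maximum
#' of the low-frequency reconstruction (approximation + coarsest detail) in a
#' `p_search_ms` window before Q, refined to the nearest local maximum of the
#' denoised trace; T the extremum of largest absolute amplitude from
#' `t_gap_ms` after S to the end of the beat (an inverted T is still found,
#' with its sign preserved). Amplitudes are read from the denoised trace at
#' the located indices.
#'
#' Delineation fails (flagged, never an error) when the Q or S search window
#' is monotone with its extremum on the window edge — the signature of a beat
#' with no recoverable QRS structure — or when the fiducials violate the
#' ordering P < Q < R < S < T.
#'
#' @param beats A `beat_set` (only accepted beats are delineated).
#' @param cfg A [pipeline_config()].
#' @return A tibble, one row per beat in `beats`: sample indices (1-based,
#'   within the beat) and amplitudes (mV) for P, Q, R, S, T, with `ok` and
#'   `fail_reason`.
#' @export
delineate <- function(beats, cfg = pipeline_config()) {
  stopifnot(inherits(beats, "beat_set"))
  X <- beats$samples
  n <- ncol(X)
  fs <- cfg$sampling_rate_hz
  r_idx <- cfg$pre_r_samples + 1L
  empty <- tibble(
    beat = beats$info$beat,
    idx_p = NA_integer_, idx_q = NA_integer_, idx_r = r_idx,
    idx_s = NA_integer_, idx_t = NA_integer_,
    amp_p = NA_real_, amp_q = NA_real_, amp_r = NA_real_,
    amp_s = NA_real_, amp_t = NA_real_,
    ok = FALSE, fail_reason = NA_character_)
  use <- which(beats$info$accepted)
  if (!length(use)) return(empty)
  dn <- swt_denoise(X[, use, drop = FALSE], cfg$swt_levels)
  D <- dn$denoised; LP <- dn$lowpass
  N <- nrow(X)
  m <- length(use)
  q_w <- max(2L, as.integer(round(cfg$q_search_ms / 1000 * fs)))
  s_w <- max(2L, as.integer(round(cfg$s_search_ms / 1000 * fs)))
  p_w <- max(3L, as.integer(round(cfg$p_search_ms / 1000 * fs)))
  t_gap <- max(1L, as.integer(round(cfg$t_gap_ms / 1000 * fs)))

  fixed_window <- function(M, rows, what) {
    seg <- M[rows, , drop = FALSE]
    rel <- if (what == "min") max.col(t(-seg), ties.method = "first")
           else max.col(t(seg), ties.method = "first")
    d <- diff(seg)
    mono <- colSums(d >= 0) == nrow(d) | colSums(d <= 0) == nrow(d)
    edge <- rel == 1L | rel == length(rows)
    list(idx = rows[1] + rel - 1L, fail = edge & mono)
  }

  q <- fixed_window(D, (r_idx - q_w):(r_idx - 1L), "min")
  s <- fixed_window(D, (r_idx + 1L):min(N, r_idx + s_w), "min")

  # P: maximum of the low-frequency trace in a window anchored at each Q
  pcols <- (-p_w):(-2L)
  pmat <- outer(q$idx, pcols, "+")
  pclip <- pmat < 1L
  pmat[pclip] <- 1L
  valsP <- matrix(LP[cbind(as.vector(pmat), rep(seq_len(m), times = length(pcols)))],
                  m, length(pcols), byrow = FALSE)
  dim(valsP) <- c(m, length(pcols))
  valsP[pclip] <- -Inf
  p_idx <- q$idx + pcols[max.col(valsP, ties.method = "first")]
  # refine on the denoised trace within +/- 2 samples, staying left of Q
  rcols <- -2:2
  rmat <- outer(p_idx, rcols, "+")
  rclip <- rmat < 1L | rmat > matrix(q$idx - 1L, m, length(rcols))
  rmat[rclip] <- 1L
  valsR <- matrix(D[cbind(as.vector(rmat), rep(seq_len(m), times = length(rcols)))],
                  m, length(rcols))
  valsR[rclip] <- -Inf
  p_idx <- p_idx + rcols[max.col(valsR, ties.method = "first")]

  # T: largest |amplitude| from t_gap after each S to the end of the beat
  tcols <- t_gap:(N - r_idx - 1L)
  tmat <- outer(s$idx, tcols, "+")
  tclip <- tmat > N
  tmat[tclip] <- N
  valsT <- matrix(abs(D[cbind(as.vector(tmat),
                              rep(seq_len(m), times = length(tcols)))]),
                  m, length(tcols))
  valsT[tclip] <- -Inf
  t_idx <- s$idx + tcols[max.col(valsT, ties.method = "first")]

  fail_reason <- rep(NA_character_, m)
  fail_reason[s$fail] <- "monotone S window"
  fail_reason[q$fail] <- "monotone Q window"
  ord_ok <- p_idx < q$idx & q$idx < r_idx & r_idx < s$idx & s$idx < t_idx
  fail_reason[is.na(fail_reason) & !ord_ok] <- "ordering violated"
  ok <- is.na(fail_reason)

  gather <- function(idx) D[cbind(idx, seq_len(m))]
  out <- empty
  out$idx_p[use] <- ifelse(ok, p_idx, NA_integer_)
  out$idx_q[use] <- ifelse(ok, q$idx, NA_integer_)
  out$idx_s[use] <- ifelse(ok, s$idx, NA_integer_)
  out$idx_t[use] <- ifelse(ok, t_idx, NA_integer_)
  out$amp_p[use] <- ifelse(ok, gather(p_idx), NA_real_)
  out$amp_q[use] <- ifelse(ok, gather(q$idx), NA_real_)
  out$amp_r[use] <- ifelse(ok, gather(rep(r_idx, m)), NA_real_)
  out$amp_s[use] <- ifelse(ok, gather(s$idx), NA_real_)
  out$amp_t[use] <- ifelse(ok, gather(t_idx), NA_real_)
  out$ok[use] <- ok
  out$fail_reason[use] <- fail_reason
  out
}

#' Extract the 26-feature morphology vector per beat
#'
#' From each delineated beat: `interval(X-Y) = (idx_Y - idx_X) / fs` for the
#' ten fiducial pairs; `amplitude(X-Y) = |amp_Y - amp_X|`;
#' `slope(X-Y) = (amp_Y - amp_X) / interval(X-Y)` (signed) for the five slope
#' pairs; plus the R-R interval to the next beat. Beats that failed
#' delineation, were rejected by the quality filter, or have no next-beat R-R
#' (the final beat of a strip) are omitted — R-R is a required input feature.
#'
#' @param fiducials Output of [delineate()].
#' @param beats The `beat_set` the fiducials came from (provides `rr_next_s`,
#'   timestamps, and acceptance).
#' @param cfg A [pipeline_config()].
#' @return A tibble with `beat`, `r_time_s`, and the 26 features named as in
#'   [ecg_feature_names()]. Intervals are exactly additive
#'   (`pt_int = pq_int + qr_int + rs_int + st_int`) because they share integer
#'   sample indices.
#' @export
extract_features <- function(fiducials, beats, cfg = pipeline_config()) {
  stopifnot(inherits(beats, "beat_set"))
  fs <- cfg$sampling_rate_hz
  df <- fiducials |>
    left_join(beats$info[c("beat", "r_time_s", "rr_next_s", "accepted")],
              by = "beat") |>
    filter(.data$ok, .data$accepted, !is.na(.data$rr_next_s))
  if (!nrow(df)) {
    return(bind_cols(
      tibble(beat = integer(0), r_time_s = numeric(0)),
      as_tibble(setNames(rep(list(numeric(0)), 26), ecg_feature_names()))))
  }
  idx <- list(p = df$idx_p, q = df$idx_q, r = df$idx_r, s = df$idx_s,
              t = df$idx_t)
  amp <- list(p = df$amp_p, q = df$amp_q, r = df$amp_r, s = df$amp_s,
              t = df$amp_t)
  out <- tibble(beat = df$beat, r_time_s = df$r_time_s)
  for (pr in feature_pairs()) {
    a <- substr(pr, 1, 1); b <- substr(pr, 2, 2)
    out[[paste0(pr, "_int")]] <- (idx[[b]] - idx[[a]]) / fs
  }
  out$rr <- df$rr_next_s
  for (pr in feature_pairs()) {
    a <- substr(pr, 1, 1); b <- substr(pr, 2, 2)
    out[[paste0(pr, "_amp")]] <- abs(amp[[b]] - amp[[a]])
  }
  for (pr in slope_pairs()) {
    a <- substr(pr, 1, 1); b <- substr(pr, 2, 2)
    out[[paste0(pr, "_slope")]] <-
      (amp[[b]] - amp[[a]]) / ((idx[[b]] - idx[[a]]) / fs)
  }
  out
}
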