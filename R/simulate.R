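#' Single-lead ECG record container
#'
#' @param samples Numeric voltage vector (mV), finite, length >= 1.
#' @param sampling_rate_hz Sampling rate; the pipeline requires 125 Hz.
#' @param start_time_s Time of the first sample (s).
#' @param subject_id Subject identifier.
#' @return An `ecg_record` object.
#' @export
ecg_record <- function(samples, sampling_rate_hz, start_time_s = 0,
                       subject_id = "s1") {
  if (!length(samples) || !all(is.finite(samples))) {
    abort("ecg_record: samples must be a non-empty finite numeric vector",
          class = "ecgdys_data_error")
  }
  structure(list(subject_id = subject_id,
                 samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 start_time_s = start_time_s),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s: %d samples @ %g Hz (%.1f s from t=%g)\n",
              x$subject_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$start_time_s))
  invisible(x)
}

default_composition <- function(n_bg, cfg) {
  n_dys <- max(cfg$min_dys_records, 5L)
  need_eu <- cfg$n_train_eu + cfg$n_val_eu
  n_buf <- max(0L, min(2L, n_bg - n_dys - need_eu))  # buffer strips when room
  c(eu = n_bg - n_dys - n_buf, hypo = 2L, hyper = n_dys - 2L,
    buffer_lo = if (n_buf >= 1L) 1L else 0L,
    buffer_hi = if (n_buf >= 2L) 1L else 0L)
}

bg_value_for_class <- function(class, cfg) {
  switch(class,
    eu        = runif(1, cfg$bg_eu_low_mgdl + 10, cfg$bg_eu_high_mgdl - 10),
    hypo      = runif(1, 40, cfg$bg_hypo_mgdl - 5),
    hyper     = runif(1, cfg$bg_hyper_mgdl + 5, 300),
    buffer_lo = runif(1, cfg$bg_hypo_mgdl + 1, cfg$bg_eu_low_mgdl - 1),
    buffer_hi = runif(1, cfg$bg_eu_high_mgdl + 5, cfg$bg_hyper_mgdl - 2))
}

# truncated standard normal draws; truncation keeps jittered waves ordered
# and inside the beat window at the jitter scales used
rtnorm <- function(n, sd, trunc = 2.5) {
  pmin(pmax(rnorm(n), -trunc), trunc) * sd
}

jitter_sds <- function(params_eu, params_dys, jitter_frac) {
  c_sd <- pmax(jitter_frac * abs(params_dys$centers_s - params_eu$centers_s),
               0.002)
  c_sd[["R"]] <- 0
  a_sd <- pmax(jitter_frac * abs(params_dys$amplitudes_mv - params_eu$amplitudes_mv),
               0.005)
  rr_sd <- max(jitter_frac * abs(params_dys$heart_period_s -
                                   params_eu$heart_period_s), 0.005)
  list(center = c_sd, amp = a_sd, rr = rr_sd)
}

#' Simulate one subject: glycemic-state-modulated ECG plus a BG timeline
#'
#' Emits a continuous 125 Hz single-lead record built from 10-min strips, one
#' strip per blood-glucose record (the BG storage time is the strip end, so the
#' 10 min of signal preceding each BG value is that strip). Beats within a
#' strip are drawn from the state-appropriate wave parameters with per-beat
#' Gaussian jitter of the wave centres, peak amplitudes, and the R-R period,
#' plus additive white measurement noise; samples are quantized to 1 uV, the
#' amplitude resolution of bedside-monitor archives. The output is fully
#' reproducible from `seed`.
#'
#' @param params_eu,params_dys `wave_params` for the euglycemic and
#'   dysglycemic states (equal parameters give a null subject).
#' @param n_bg Number of BG records (strips); must be >= `cfg$min_bg_records`.
#' @param seed Integer seed for this subject.
#' @param cfg A [pipeline_config()].
#' @param subject_id Identifier carried through the pipeline.
#' @param composition Named integer vector of strip counts per class
#'   (`eu`, `hypo`, `hyper`, `buffer_lo`, `buffer_hi`) summing to `n_bg`.
#'   The default includes both buffer-zone classes so exclusion logic is
#'   exercised.
#' @param jitter_frac Within-subject jitter SD as a fraction of each wave
#'   parameter's between-state shift (small floors keep a minimum of
#'   within-subject variability); `cfg$jitter_frac` by default.
#' @param jitter_slow_frac Fraction of the morphology-jitter *variance*
#'   carried by a slow per-strip component rather than beat-to-beat noise.
#'   The default is 0 (fully beat-independent jitter): beat independence is
#'   what makes pooled feature means converge to the designed means at the
#'   1/sqrt(n-beats) rate and keeps validation strips exchangeable, which is
#'   what a verification generator needs. Real within-subject ECG morphology
#'   drifts on the minutes scale instead; raising this knob emulates that
#'   (marginal per-feature SDs are unaffected), at the cost of strip-level
#'   confounding in small validation splits. R-R jitter is always fully
#'   beat-to-beat.
#' @param noise_sd_mv Additive white-noise SD (mV).
#' @param baseline_amp_mv Amplitude of an optional baseline-wander sine
#'   (`cfg$baseline_freq_hz`); 0 disables it.
#' @return A `synthetic_subject`: list with the `ecg_record`, the BG tibble
#'   (`time_s`, `glucose_mgdl`, `class`), the per-beat design tibble (realized
#'   wave centres and peak amplitudes — the ground truth for delineation
#'   oracles), the per-state parameters, and the jitter SDs.
#' @examples
#' cfg <- pipeline_config()
#' wp <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
#' \donttest{
#' subj <- simulate_subject(wp, wp, n_bg = 20, seed = 7, cfg = cfg)
#' }
#' @export
simulate_subject <- function(params_eu, params_dys, n_bg, seed,
                             cfg = pipeline_config(), subject_id = "s1",
                             composition = default_composition(n_bg, cfg),
                             jitter_frac = cfg$jitter_frac,
                             jitter_slow_frac = 0,
                             noise_sd_mv = cfg$noise_sd_mv,
                             baseline_amp_mv = cfg$baseline_amp_mv) {
  stopifnot(inherits(params_eu, "wave_params"), inherits(params_dys, "wave_params"))
  if (n_bg < cfg$min_bg_records) {
    abort(sprintf("n_bg (%d) must be >= min_bg_records (%d)", n_bg,
                  cfg$min_bg_records), class = "ecgdys_generation_error")
  }
  composition <- composition[composition > 0]
  if (sum(composition) != n_bg) {
    abort("composition counts must sum to n_bg", class = "ecgdys_generation_error")
  }
  n_eu <- composition[["eu"]] %||% 0L
  n_dys <- (composition["hypo"] %||% 0L) + (composition["hyper"] %||% 0L)
  if (n_eu < cfg$n_train_eu + cfg$n_val_eu || n_dys < cfg$min_dys_records) {
    abort(sprintf(
      "infeasible class counts: %d euglycemic (need >= %d) and %d dysglycemic (need >= %d) strips",
      n_eu, cfg$n_train_eu + cfg$n_val_eu, n_dys, cfg$min_dys_records),
      class = "ecgdys_generation_error")
  }
  jit <- jitter_sds(params_eu, params_dys, jitter_frac)
  fs <- cfg$sampling_rate_hz
  strip_s <- cfg$bg_corr_window_s
  dur <- n_bg * strip_s
  n_samples <- as.integer(round(dur * fs))

  withr::with_seed(seed, {
    classes <- sample(rep(names(composition), composition))
    bg <- tibble(
      time_s = seq_len(n_bg) * strip_s,
      glucose_mgdl = vapply(classes, bg_value_for_class, numeric(1), cfg = cfg),
      class = classes)
    strip_state <- ifelse(classes %in% c("hypo", "hyper"), "dys",
                          ifelse(classes == "eu", "eu", "buffer"))
    # buffer strips carry euglycemic-looking morphology (BG just outside band)
    beat_state <- ifelse(strip_state == "dys", "dys", "eu")
    params_by_state <- list(eu = params_eu, dys = params_dys)

    ## beat times: sequential per strip, continuous across strips
    r_time <- vector("list", n_bg)
    t_cur <- 0.35
    for (k in seq_len(n_bg)) {
      p <- params_by_state[[beat_state[k]]]$heart_period_s
      end_k <- k * strip_s
      n_max <- ceiling((end_k - t_cur) / max(p - 3 * jit$rr, 0.3)) + 2L
      gaps <- p + rtnorm(n_max, jit$rr)
      gaps <- pmax(gaps, 0.3)
      tt <- t_cur + cumsum(gaps)
      tt <- tt[tt < end_k]
      r_time[[k]] <- c(t_cur, tt)
      t_cur <- if (length(tt)) tt[length(tt)] + gaps[length(tt) + 1L] else t_cur + p
      # next strip starts where this one's beat train left off
      if (t_cur <= end_k) t_cur <- end_k + 0.05
    }
    strip_id <- rep.int(seq_len(n_bg), lengths(r_time))
    r_time <- unlist(r_time)
    keep <- r_time < dur - 0.7   # last beat needs full post-window support
    r_time <- r_time[keep]; strip_id <- strip_id[keep]
    nb <- length(r_time)
    state <- beat_state[strip_id]

    ## per-beat realized wave centres and peak amplitudes; morphology jitter
    ## optionally splits into a slow per-strip component and a beat-to-beat
    ## remainder (marginal SD = jit$center/amp either way). R-R jitter stays
    ## fully beat-to-beat: that is heart-rate variability itself.
    sl <- sqrt(jitter_slow_frac); fa <- sqrt(1 - jitter_slow_frac)
    cjit <- vapply(wave_names(), function(w) {
      rtnorm(n_bg, sl * jit$center[[w]])[strip_id] +
        rtnorm(nb, fa * jit$center[[w]])
    }, numeric(nb))
    ajit <- vapply(wave_names(), function(w) {
      rtnorm(n_bg, sl * jit$amp[[w]])[strip_id] +
        rtnorm(nb, fa * jit$amp[[w]])
    }, numeric(nb))
    centers <- matrix(NA_real_, nb, 5, dimnames = list(NULL, wave_names()))
    amps <- matrix(NA_real_, nb, 5, dimnames = list(NULL, wave_names()))
    gcoef <- matrix(NA_real_, nb, 5)
    for (st in c("eu", "dys")) {
      i <- which(state == st)
      if (!length(i)) next
      p <- params_by_state[[st]]
      centers[i, ] <- rep(p$centers_s, each = length(i)) + cjit[i, , drop = FALSE]
      amps[i, ] <- rep(p$amplitudes_mv, each = length(i)) + ajit[i, , drop = FALSE]
      # map peak-amplitude jitter to Gaussian coefficients through the overlap
      # inverse so the summed trace still peaks at the designed values
      gcoef[i, ] <- rep(p$gauss_amp, each = length(i)) +
        ajit[i, , drop = FALSE] %*% t(p$overlap_inv)
    }
    centers_abs <- centers + r_time

    x <- numeric(n_samples)
    for (st in c("eu", "dys")) {
      i <- which(state == st)
      if (!length(i)) next
      widths <- params_by_state[[st]]$widths_s
      for (wi in seq_along(wave_names())) {
        sigma <- widths[[wi]]
        L <- ceiling(4 * sigma * fs)
        cols <- -L:L
        cab <- centers_abs[i, wi]
        cidx <- round(cab * fs) + 1L
        resid <- (cidx - 1) / fs - cab
        val <- gcoef[i, wi] * exp(-outer(resid, cols / fs, "+")^2 / (2 * sigma^2))
        for (j in seq_along(cols)) {
          ii <- cidx + cols[j]
          ok <- ii >= 1L & ii <= n_samples
          if (any(ok)) x[ii[ok]] <- x[ii[ok]] + val[ok, j]
        }
      }
    }
    if (baseline_amp_mv > 0) {
      x <- x + baseline_amp_mv *
        sin(2 * pi * cfg$baseline_freq_hz * (seq_len(n_samples) - 1) / fs)
    }
    if (noise_sd_mv > 0) x <- x + rnorm(n_samples, 0, noise_sd_mv)
    x <- round(x * 1000) / 1000    # 1 uV amplitude quantization

    design <- tibble(
      beat = seq_len(nb), strip_id = strip_id, state = state,
      r_time_s = r_time)
    for (w in wave_names()) design[[paste0("c_", w)]] <- centers_abs[, w]
    for (w in wave_names()) design[[paste0("a_", w)]] <- amps[, w]

    structure(
      list(subject_id = subject_id,
           record = ecg_record(x, fs, 0, subject_id),
           bg = bg,
           design = design,
           params = params_by_state,
           jitter = jit,
           seed = seed,
           af_or_pacemaker = FALSE),
      class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s: %d BG records, %d beats, %.0f min of ECG\n",
              x$subject_id, nrow(x$bg), nrow(x$design),
              length(x$record$samples) / x$record$sampling_rate_hz / 60))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject baseline physiology (heart-period factor ~ N(1, 0.07) and
#' amplitude gain ~ N(1, 0.10), both truncated) around the reference
#' calibration targets, scales the dysglycemic-state shift by `effect_scale`
#' (0 gives a null cohort with identical state distributions), and simulates
#' each subject with a child seed derived arithmetically from `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param effect_scale Multiplier on every between-state target shift.
#' @param seed Master seed; child seeds are `seed * 1000 + subject index`.
#' @param cfg A [pipeline_config()].
#' @param n_bg BG records (strips) per subject.
#' @param jitter_frac Within-subject jitter scale passed to
#'   [simulate_subject()].
#' @param targets Calibration target table, by default [feature_targets()].
#' @param subject_variation Draw between-subject baseline variation? The
#'   calibration runs used for parameter-recovery checks turn this off so that
#'   designed means equal the target table exactly.
#' @return A list of `synthetic_subject` objects.
#' @examples
#' \donttest{
#' cohort <- make_cohort(2, effect_scale = 1, seed = 42)
#' }
#' @export
make_cohort <- function(n_subjects, effect_scale = 1, seed,
                        cfg = pipeline_config(), n_bg = 23L,
                        jitter_frac = cfg$jitter_frac,
                        targets = feature_targets(),
                        subject_variation = TRUE) {
  if (n_subjects < 1) {
    abort("n_subjects must be >= 1", class = "ecgdys_config_error")
  }
  tg <- targets
  base_seed <- (seed %% 1000000L) * 1000L
  withr::with_seed(seed, {
    pf <- pmin(pmax(rnorm(n_subjects, 1, 0.07), 0.85), 1.15)
    ag <- pmin(pmax(rnorm(n_subjects, 1, 0.10), 0.75), 1.30)
  })
  if (!subject_variation) {
    pf[] <- 1; ag[] <- 1
  }
  lapply(seq_len(n_subjects), function(i) {
    t_eu <- setNames(tg$eu, tg$target)
    t_dys <- t_eu + effect_scale * (setNames(tg$dys, tg$target) - t_eu)
    amp_keys <- grep("_mv$", tg$target, value = TRUE)
    t_eu["rr_s"] <- t_eu["rr_s"] * pf[i]
    t_dys["rr_s"] <- t_dys["rr_s"] * pf[i]
    t_eu[amp_keys] <- t_eu[amp_keys] * ag[i]
    t_dys[amp_keys] <- t_dys[amp_keys] * ag[i]
    wp_eu <- solve_wave_params(as.list(t_eu), cfg = cfg)
    wp_dys <- solve_wave_params(as.list(t_dys), cfg = cfg)
    simulate_subject(wp_eu, wp_dys, n_bg = n_bg, seed = base_seed + i,
                     cfg = cfg, subject_id = sprintf("s%02d", i),
                     jitter_frac = jitter_frac)
  })
}
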