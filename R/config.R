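#' Pipeline configuration
#'
#' Every fixed constant of the screening method lives here, so the processing
#' functions are parameter-free: the 125 Hz sampling rate, the 50/75-sample
#' (2:3) beat window, the 10-min blood-glucose correspondence window, the
#' glycemic class boundaries (dysglycemia strictly above 200 or below 70 mg/dL,
#' euglycemia inclusively between 80 and 180 mg/dL), the 10/5/5 strip split,
#' the one-class SVM settings (linear kernel, nu = 0.75), and the thresholds of
#' the automated beat-quality and delineation rules.
#'
#' @param ... Named overrides of the default keys (see Details).
#'
#' @details
#' Keys and defaults:
#' \describe{
#'   \item{sampling_rate_hz (125)}{ECG sampling rate; other rates are rejected.}
#'   \item{pre_r_samples (50), post_r_samples (75)}{Beat window around the R
#'     peak; must sum to one second of samples and reduce to the 2:3 ratio.}
#'   \item{bg_corr_window_s (600)}{ECG window preceding a BG storage time.}
#'   \item{vote_window_s (10)}{Majority-vote window length.}
#'   \item{nu (0.75), kernel ("linear")}{One-class SVM hyperparameters, shared
#'     across subjects.}
#'   \item{bg_hypo_mgdl (70), bg_eu_low_mgdl (80), bg_eu_high_mgdl (180),
#'     bg_hyper_mgdl (200)}{Glycemic class boundaries; the two buffer bands
#'     (70-80, 180-200 mg/dL) are excluded from analysis.}
#'   \item{n_train_eu (10), n_val_eu (5), n_val_dys (5)}{Per-subject strip
#'     split.}
#'   \item{min_bg_records (20), min_dys_records (5)}{Subject inclusion
#'     thresholds.}
#'   \item{rpeak_band_low_hz (5), rpeak_band_high_hz (15), rpeak_refractory_s
#'     (0.3), rpeak_mwi_ms (150)}{R-peak detector chain settings.}
#'   \item{qc_min_template_cor (0.8), qc_p2p_lo (0.2), qc_p2p_hi (5),
#'     qc_min_beats (8)}{Automated beat-quality filter.}
#'   \item{q_search_ms (100), s_search_ms (120), p_search_ms (180),
#'     t_gap_ms (40), swt_levels (3)}{Delineation search windows and wavelet
#'     depth.}
#'   \item{feature_scaling ("none")}{Per-feature scaling before the one-class
#'     SVM: "none" (raw units) or "sd" (divide by the training standard
#'     deviation, no centering). See the methods vignette for why centering is
#'     not offered.}
#'   \item{svm_tolerance (1e-6), min_train_beats (50)}{Solver settings.}
#'   \item{noise_sd_mv (0.01), baseline_amp_mv (0), baseline_freq_hz (0.3),
#'     jitter_frac (0.2)}{Synthetic-generator defaults.}
#'   \item{rng_seed (1)}{Default master seed.}
#' }
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$pre_r_samples + cfg$post_r_samples == cfg$sampling_rate_hz
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  if (length(dots)) {
    check_known_keys(names(dots))
    cfg <- modifyList(cfg, dots)
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    sampling_rate_hz = 125L,
    pre_r_samples = 50L,
    post_r_samples = 75L,
    bg_corr_window_s = 600,
    vote_window_s = 10,
    nu = 0.75,
    kernel = "linear",
    bg_hypo_mgdl = 70,
    bg_eu_low_mgdl = 80,
    bg_eu_high_mgdl = 180,
    bg_hyper_mgdl = 200,
    n_train_eu = 10L,
    n_val_eu = 5L,
    n_val_dys = 5L,
    min_bg_records = 20L,
    min_dys_records = 5L,
    rpeak_band_low_hz = 5,
    rpeak_band_high_hz = 15,
    rpeak_refractory_s = 0.3,
    rpeak_mwi_ms = 150,
    qc_min_template_cor = 0.8,
    qc_p2p_lo = 0.2,
    qc_p2p_hi = 5,
    qc_min_beats = 8L,
    q_search_ms = 100,
    s_search_ms = 120,
    p_search_ms = 180,
    t_gap_ms = 40,
    swt_levels = 3L,
    feature_scaling = "none",
    svm_tolerance = 1e-6,
    min_train_beats = 50L,
    noise_sd_mv = 0.01,
    baseline_amp_mv = 0,
    baseline_freq_hz = 0.3,
    jitter_frac = 0.2,
    rng_seed = 1L
  )
}

check_known_keys <- function(keys) {
  unknown <- setdiff(keys, names(config_defaults()))
  if (length(unknown)) {
    config_error(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  invisible(keys)
}

config_error <- function(msg) {
  abort(msg, class = "ecgdys_config_error")
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num_pos <- c("sampling_rate_hz", "pre_r_samples", "post_r_samples",
               "bg_corr_window_s", "vote_window_s", "rpeak_refractory_s",
               "rpeak_mwi_ms", "q_search_ms", "s_search_ms", "p_search_ms",
               "t_gap_ms", "swt_levels", "min_train_beats", "qc_min_beats")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      config_error(sprintf("configuration key '%s' must be a positive number", k))
    }
  }
  if (cfg$pre_r_samples + cfg$post_r_samples != cfg$sampling_rate_hz) {
    config_error(sprintf(
      "pre_r_samples + post_r_samples must equal one second of samples (%d): got %d + %d",
      cfg$sampling_rate_hz, cfg$pre_r_samples, cfg$post_r_samples))
  }
  if (cfg$pre_r_samples * 3L != cfg$post_r_samples * 2L) {
    config_error(sprintf(
      "pre_r_samples : post_r_samples must reduce to 2:3, got %d:%d",
      cfg$pre_r_samples, cfg$post_r_samples))
  }
  if (!(cfg$nu > 0 && cfg$nu <= 1)) {
    config_error(sprintf("nu must lie in (0, 1], got %s", format(cfg$nu)))
  }
  if (!identical(cfg$kernel, "linear")) {
    config_error("kernel: only 'linear' is supported")
  }
  bg <- c(cfg$bg_hypo_mgdl, cfg$bg_eu_low_mgdl, cfg$bg_eu_high_mgdl,
          cfg$bg_hyper_mgdl)
  if (any(diff(bg) <= 0)) {
    config_error(paste(
      "blood-glucose boundaries must satisfy",
      "bg_hypo_mgdl < bg_eu_low_mgdl < bg_eu_high_mgdl < bg_hyper_mgdl"))
  }
  if (!cfg$feature_scaling %in% c("none", "sd")) {
    config_error("feature_scaling must be 'none' or 'sd'")
  }
  int_keys <- c("sampling_rate_hz", "pre_r_samples", "post_r_samples",
                "n_train_eu", "n_val_eu", "n_val_dys", "min_bg_records",
                "min_dys_records", "qc_min_beats", "swt_levels",
                "min_train_beats", "rng_seed")
  cfg[int_keys] <- lapply(cfg[int_keys], function(v) as.integer(round(v)))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a flat JSON file
#'
#' @param path Path to a flat (non-nested) JSON object, or `NULL` for the
#'   defaults. Unknown keys are rejected; defaults fill absent keys; all
#'   invariants are checked.
#' @return A [pipeline_config()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) {
    config_error(sprintf("configuration file not found: %s", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || (length(raw) && is.null(names(raw)))) {
    config_error("configuration file must be a flat JSON object of key-value pairs")
  }
  if (any(vapply(raw, function(v) is.list(v) || length(v) != 1L, logical(1)))) {
    config_error("configuration file must be flat: every value a scalar")
  }
  do.call(pipeline_config, raw)
}

#' Serialize a pipeline configuration to flat JSON
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg A [pipeline_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  keys <- names(x)
  for (k in keys) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

config_digest <- function(cfg) {
  # stable short id for manifests; no external digest dependency
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 1000000007
}
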