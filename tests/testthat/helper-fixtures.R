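# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a noise-free beat_set of n identical beats for a state
noisefree_beats <- function(state = "eu", n = 10, cfg = pipeline_config(),
                            quantize = TRUE) {
  wp <- solve_wave_params(feature_targets(), state, cfg = cfg)
  fs <- cfg$sampling_rate_hz
  t <- seq(-cfg$pre_r_samples / fs, (cfg$post_r_samples - 1) / fs, by = 1 / fs)
  v <- gaussian_beat(wp, t)
  if (quantize) v <- round(v * 1000) / 1000
  bs <- structure(
    list(samples = matrix(rep(v, n), ncol = n),
         info = tibble::tibble(
           beat = seq_len(n), r_index = cfg$pre_r_samples + 1L,
           r_time_s = (seq_len(n) - 1) * wp$heart_period_s,
           rr_next_s = wp$heart_period_s,
           accepted = TRUE, reason = NA_character_),
         n_boundary_dropped = 0L,
         cfg_window = c(pre = cfg$pre_r_samples, post = cfg$post_r_samples)),
    class = "beat_set")
  attr(bs, "wave_params") <- wp
  bs
}

# one small simulated subject at default jitter (cached; ~1 s)
small_subject <- function() {
  cached("small_subject", {
    cfg <- pipeline_config()
    wp_eu <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
    wp_dys <- solve_wave_params(feature_targets(), "dys", cfg = cfg)
    simulate_subject(wp_eu, wp_dys, n_bg = 20, seed = 7, cfg = cfg)
  })
}

# its extracted features (cached; ~5 s)
small_subject_features <- function() {
  cached("small_subject_features", {
    extract_subject_features(small_subject(), pipeline_config())
  })
}

# a fitted model on the small subject's euglycemic strips (cached)
small_model <- function() {
  cached("small_model", {
    cfg <- pipeline_config()
    ext <- small_subject_features()
    split <- split_records(ext$strips, seed = 1, cfg = cfg)
    feats <- dplyr::left_join(ext$features, split[c("strip_id", "split")],
                              by = "strip_id")
    train <- dplyr::filter(feats, .data$split == "train")
    list(model = fit_subject_model(train, cfg, subject_id = "s1"),
         features = feats)
  })
}
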