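cfg <- pipeline_config()

test_that("the stationary wavelet transform reconstructs perfectly", {
  sw <- asNamespace("ecgdys")
  set.seed(3)
  x <- matrix(rnorm(125 * 4), 125, 4)
  dec <- sw$swt_decompose(x, 3L)
  expect_equal(sw$swt_reconstruct(dec), x, tolerance = 1e-10)
})

test_that("noise-free beats round-trip their designed fiducials", {
  for (state in c("eu", "dys")) {
    bs <- noisefree_beats(state, n = 10, cfg = cfg)
    d <- attr(attr(bs, "wave_params"), "designed")
    fid <- delineate(bs, cfg)
    expect_true(all(fid$ok))
    found_idx <- unlist(fid[1, c("idx_p", "idx_q", "idx_r", "idx_s", "idx_t")])
    expect_true(all(abs(found_idx - (51L + d$offset_samples)) <= 1L))
    found_amp <- unlist(fid[1, c("amp_p", "amp_q", "amp_r", "amp_s", "amp_t")])
    expect_true(all(abs(found_amp - d$amplitude_mv) <= 1e-3))  # 1 uV
  }
})

test_that("an inverted T wave is still found, sign preserved", {
  wp <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
  neg <- wave_params(wp$centers_s,
                     replace(wp$amplitudes_mv, 5, -0.49),
                     wp$widths_s, wp$heart_period_s)
  fs <- cfg$sampling_rate_hz
  t <- seq(-50 / fs, 74 / fs, by = 1 / fs)
  v <- round(gaussian_beat(neg, t) * 1000) / 1000
  bs <- noisefree_beats("eu", n = 3, cfg = cfg)
  bs$samples[] <- rep(v, 3)
  fid <- delineate(bs, cfg)
  expect_true(all(fid$ok))
  expect_equal(fid$idx_t[1], 51L + 36L)
  expect_lt(fid$amp_t[1], -0.45)
})

test_that("degenerate beats are flagged, not errored", {
  bs <- noisefree_beats("eu", n = 2, cfg = cfg)
  bs$samples[] <- seq(0, 1, length.out = 125)  # monotone ramp: no waves
  fid <- delineate(bs, cfg)
  expect_true(all(!fid$ok))
  expect_match(fid$fail_reason[1], "monotone")
  # rejected beats are skipped entirely
  bs2 <- noisefree_beats("eu", n = 2, cfg = cfg)
  bs2$info$accepted[1] <- FALSE
  fid2 <- delineate(bs2, cfg)
  expect_false(fid2$ok[1])
  expect_true(fid2$ok[2])
})

test_that("features are offset-invariant and gain-equivariant", {
  bs <- noisefree_beats("eu", n = 2, cfg = cfg, quantize = FALSE)
  base <- extract_features(delineate(bs, cfg), bs, cfg)
  ## constant offset leaves every feature unchanged
  bs_off <- bs; bs_off$samples <- bs$samples + 0.25
  off <- extract_features(delineate(bs_off, cfg), bs_off, cfg)
  expect_equal(as.data.frame(off[ecg_feature_names()]),
               as.data.frame(base[ecg_feature_names()]), tolerance = 1e-8)
  ## gain c > 0 scales amplitudes and slopes by c, intervals unchanged
  cc <- 1.8
  bs_g <- bs; bs_g$samples <- bs$samples * cc
  g <- extract_features(delineate(bs_g, cfg), bs_g, cfg)
  ints <- c(paste0(ecgdys:::feature_pairs(), "_int"), "rr")
  amps <- paste0(ecgdys:::feature_pairs(), "_amp")
  slps <- paste0(ecgdys:::slope_pairs(), "_slope")
  expect_equal(as.data.frame(g[ints]), as.data.frame(base[ints]))
  expect_equal(as.data.frame(g[amps]), as.data.frame(base[amps]) * cc,
               tolerance = 1e-8)
  expect_equal(as.data.frame(g[slps]), as.data.frame(base[slps]) * cc,
               tolerance = 1e-8)
})

test_that("feature arithmetic matches the fiducial definitions exactly", {
  fid <- tibble::tibble(
    beat = 1L, idx_p = 25L, idx_q = 41L, idx_r = 51L, idx_s = 56L,
    idx_t = 87L, amp_p = 0.05, amp_q = -0.08, amp_r = 0.6, amp_s = -0.75 + 0.6,
    amp_t = 0.49, ok = TRUE, fail_reason = NA_character_)
  bs <- noisefree_beats("eu", n = 1, cfg = cfg)
  f <- extract_features(fid, bs, cfg)
  # designed euglycemic geometry: Q-T = 0.37 s at the calibration targets,
  # up to the one-sample grid snap (46/125 = 0.368)
  expect_equal(f$qt_int, 46 / 125)
  expect_lt(abs(f$qt_int - 0.37), 1 / 125)
  expect_equal(f$rs_int, 5 / 125)
  expect_equal(f$rs_amp, 0.75)
  # slopes are signed: S below R gives a negative R-S gradient (if it were a
  # slope feature, -0.75 / 0.04 = -18.75); the S-T slope is positive
  expect_equal((f$st_amp * sign(fid$amp_t - fid$amp_s)) / f$st_int,
               (0.49 - (-0.15)) / (31 / 125))
  ## equal amplitudes give zero amplitude difference and zero slope
  fid2 <- fid; fid2$amp_q <- fid2$amp_p
  f2 <- extract_features(fid2, bs, cfg)
  expect_equal(f2$pq_amp, 0)
  expect_equal(f2$pq_slope, 0)
})

test_that("interval additivity and slope-interval consistency hold exactly", {
  subj_f <- small_subject_features()$features
  f <- dplyr::slice_head(subj_f, n = 500)
  expect_equal(f$pt_int, f$pq_int + f$qr_int + f$rs_int + f$st_int)
  expect_equal(f$qt_int, f$qr_int + f$rs_int + f$st_int)
  # slope * interval = signed amplitude difference -> |.| = amplitude feature
  for (pr in ecgdys:::slope_pairs()) {
    expect_equal(abs(f[[paste0(pr, "_slope")]]) * f[[paste0(pr, "_int")]],
                 f[[paste0(pr, "_amp")]], tolerance = 1e-10)
  }
  expect_true(all(is.finite(as.matrix(f[ecg_feature_names()]))))
  expect_true(all(as.matrix(f[c(paste0(ecgdys:::feature_pairs(), "_int"),
                                "rr")]) > 0))
})

test_that("jittered extraction recovers the designed interval means", {
  # pooled over one subject's strips at default jitter: biases stay well
  # below the sample quantization
  f <- small_subject_features()$features
  agg <- f |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(rr = mean(.data$rr), qt = mean(.data$qt_int),
                     st = mean(.data$st_int), n = dplyr::n())
  eu <- agg[agg$label == "euglycemia", ]
  dys <- agg[agg$label == "dysglycemia", ]
  expect_gt(min(agg$n), 2000)
  expect_lt(abs(eu$rr - 0.74), 0.01)
  expect_lt(abs(dys$rr - 0.66), 0.01)
  expect_lt(abs(dys$qt - 0.44), 0.01)
  expect_lt(abs(dys$st - 0.32), 0.01)
})
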