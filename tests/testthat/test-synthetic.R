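cfg <- pipeline_config()

test_that("gaussian_beat: null morphology, peak placement, additivity", {
  t <- seq(-0.4, 0.6 - 1 / 125, by = 1 / 125)
  base <- list(centers_s = c(P = -0.2, Q = -0.08, R = 0, S = 0.04, T = 0.3),
               widths_s = c(P = 0.02, Q = 0.01, R = 0.02, S = 0.01, T = 0.04))
  # all amplitudes zero -> all-zero trace
  wp0 <- wave_params(base$centers_s,
                     c(P = 0, Q = 0, R = 0, S = 0, T = 0),
                     base$widths_s, 0.8)
  expect_equal(gaussian_beat(wp0, t), rep(0, length(t)))
  # single R wave of 1 mV, width 0.02 s -> trace peaks at exactly 1 mV at t=0
  wp_r <- wave_params(base$centers_s,
                      c(P = 0, Q = 0, R = 1, S = 0, T = 0),
                      c(P = 0.02, Q = 0.01, R = 0.02, S = 0.01, T = 0.04), 0.8)
  v <- gaussian_beat(wp_r, t)
  expect_equal(max(v), 1.0, tolerance = 1e-12)
  expect_equal(t[which.max(v)], 0)
  # two well-separated waves superpose additively
  wp_t <- wave_params(base$centers_s,
                      c(P = 0, Q = 0, R = 0, S = 0, T = 0.5),
                      base$widths_s, 0.8)
  wp_rt <- wave_params(base$centers_s,
                       c(P = 0, Q = 0, R = 1, S = 0, T = 0.5),
                       base$widths_s, 0.8)
  expect_equal(gaussian_beat(wp_rt, t),
               gaussian_beat(wp_r, t) + gaussian_beat(wp_t, t),
               tolerance = 1e-6)
})

test_that("wave_params rejects degenerate geometry", {
  c0 <- c(P = -0.2, Q = -0.08, R = 0, S = 0.04, T = 0.3)
  a0 <- c(P = 0.1, Q = -0.1, R = 0.6, S = -0.15, T = 0.4)
  w0 <- c(P = 0.02, Q = 0.01, R = 0.012, S = 0.01, T = 0.04)
  expect_error(wave_params(c0, a0, replace(w0, 2, 0), 0.8),
               "width", class = "ecgdys_param_error")
  expect_error(wave_params(replace(c0, 5, -0.3), a0, w0, 0.8),
               "ordered", class = "ecgdys_param_error")
  expect_error(wave_params(c0, a0, w0, 2.5), "heart_period",
               class = "ecgdys_param_error")
})

test_that("solve_wave_params reproduces the designed fiducial geometry", {
  wp <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
  d <- attr(wp, "designed")
  # designed centres: Q at -0.08 s, S at +0.04 s, T at +0.29 s (grid-snapped)
  expect_equal(d$offset_samples[d$wave == "Q"], -10L)
  expect_equal(d$offset_samples[d$wave == "S"], 5L)
  expect_equal(d$offset_samples[d$wave == "T"], 36L)
  expect_equal(wp$heart_period_s, 0.74)
  # designed amplitude differences hit the targets exactly
  amp <- setNames(d$amplitude_mv, d$wave)
  expect_equal(abs(amp[["R"]] - amp[["Q"]]), 0.68)
  expect_equal(abs(amp[["R"]] - amp[["S"]]), 0.75)
  expect_equal(abs(amp[["T"]] - amp[["S"]]), 0.64)
  # the summed trace passes through the designed peaks
  t <- seq(-0.4, 0.6 - 1 / 125, by = 1 / 125)
  v <- gaussian_beat(wp, t)
  expect_equal(v[d$offset_samples + 51], d$amplitude_mv, tolerance = 1e-10)
  # dysglycemic heart period
  wp2 <- solve_wave_params(feature_targets(), "dys", cfg = cfg)
  expect_equal(wp2$heart_period_s, 0.66)
})

test_that("inconsistent interval systems are calibration errors", {
  tg <- feature_targets()
  bad <- as.list(setNames(tg$eu, tg$target))
  bad$qt_int_s <- 0.50  # != qr + rs + st
  expect_error(solve_wave_params(bad, cfg = cfg), "qt_int_s",
               class = "ecgdys_calibration_error")
  bad2 <- as.list(setNames(tg$eu, tg$target))
  bad2$st_int_s <- 0    # ordering collapses
  expect_error(solve_wave_params(bad2, cfg = cfg),
               class = "ecgdys_calibration_error")
})

test_that("simulate_subject is bit-identical under a fixed seed", {
  wp_eu <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
  wp_dys <- solve_wave_params(feature_targets(), "dys", cfg = cfg)
  s1 <- simulate_subject(wp_eu, wp_dys, n_bg = 20, seed = 7, cfg = cfg)
  s2 <- simulate_subject(wp_eu, wp_dys, n_bg = 20, seed = 7, cfg = cfg)
  expect_identical(s1$record$samples, s2$record$samples)
  expect_identical(s1$bg, s2$bg)
  expect_identical(s1$design, s2$design)
  # 20 strips, 200 min, 1.5M samples
  expect_identical(nrow(s1$bg), 20L)
  expect_identical(length(s1$record$samples), 20L * 600L * 125L)
  # a different seed changes the signal
  s3 <- simulate_subject(wp_eu, wp_dys, n_bg = 20, seed = 8, cfg = cfg)
  expect_false(identical(s1$record$samples, s3$record$samples))
})

test_that("simulate_subject enforces feasibility preconditions", {
  wp <- solve_wave_params(feature_targets(), "eu", cfg = cfg)
  expect_error(simulate_subject(wp, wp, n_bg = 19, seed = 1, cfg = cfg),
               "min_bg_records", class = "ecgdys_generation_error")
  expect_error(
    simulate_subject(wp, wp, n_bg = 20, seed = 1, cfg = cfg,
                     composition = c(eu = 10, hypo = 5, hyper = 5)),
    "infeasible", class = "ecgdys_generation_error")
})

test_that("make_cohort is deterministic and satisfies the BG-count invariants", {
  co <- make_cohort(3, effect_scale = 1, seed = 11, cfg = cfg)
  co2 <- make_cohort(3, effect_scale = 1, seed = 11, cfg = cfg)
  expect_identical(purrr::map(co, "bg"), purrr::map(co2, "bg"))
  expect_identical(co[[2]]$record$samples, co2[[2]]$record$samples)
  for (s in co) {
    lab <- label_bg(s$bg$glucose_mgdl, cfg)
    expect_gte(nrow(s$bg), cfg$min_bg_records)
    expect_gte(sum(lab == "dysglycemia"), cfg$min_dys_records)
    expect_gte(sum(lab == "euglycemia"), cfg$n_train_eu + cfg$n_val_eu)
  }
  expect_error(make_cohort(0, seed = 1), class = "ecgdys_config_error")
})

test_that("null effect leaves state-designed feature means indistinguishable", {
  # effect_scale = 0: both states share wave parameters, so designed features
  # differ only by jitter; a two-sample test on the generator's own design
  # ground truth must stay non-significant for the key intervals
  co <- make_cohort(1, effect_scale = 0, seed = 5, cfg = cfg, n_bg = 20L)
  d <- co[[1]]$design
  d <- d[d$state %in% c("eu", "dys"), ]
  expect_gt(min(table(d$state)), 2000)
  for (col in c("c_T", "c_Q", "a_R")) {
    x <- if (startsWith(col, "c_")) d[[col]] - d$r_time_s else d[[col]]
    p <- t.test(x[d$state == "eu"], x[d$state == "dys"])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("designed dysglycemic means follow the calibration targets", {
  co <- make_cohort(1, effect_scale = 1, seed = 5, cfg = cfg, n_bg = 20L,
                    subject_variation = FALSE)
  d <- co[[1]]$design
  rr_dys <- diff(d$r_time_s)[utils::head(d$state, -1) == "dys" &
                               utils::tail(d$state, -1) == "dys"]
  expect_equal(mean(rr_dys), 0.66, tolerance = 0.005)
  rr_eu <- diff(d$r_time_s)[utils::head(d$state, -1) == "eu" &
                              utils::tail(d$state, -1) == "eu"]
  expect_equal(mean(rr_eu), 0.74, tolerance = 0.005)
})
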