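cfg <- pipeline_config()

# wrap plain 2-D points into a feature tibble the model API accepts:
# the first two canonical features carry the points, the rest are frozen
# at constants plus negligible variation so they do not affect the fit
toy_features <- function(X2) {
  nm <- ecg_feature_names()
  out <- tibble::as_tibble(setNames(rep(list(0), 26), nm))
  out <- out[rep(1, nrow(X2)), ]
  out[[nm[1]]] <- X2[, 1]
  out[[nm[2]]] <- X2[, 2]
  out
}

test_that("decision values match the brute-force dual on toy sets", {
  ## 4 distinct points duplicated 25x, nu = 0.5 (grouped caps in the oracle)
  pts <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE) + 2
  Xfull <- pts[rep(1:4, each = 25), ]
  fit <- e1071::svm(Xfull, type = "one-classification", kernel = "linear",
                    nu = 0.5, scale = FALSE, tolerance = 1e-7)
  w_fit <- as.numeric(t(fit$coefs) %*% fit$SV)
  o <- oracle_decision(pts, u = rep(25, 4), nu = 0.5, X_query = pts)
  dec_fit <- as.numeric(pts %*% w_fit) - fit$rho
  expect_lt(max(abs(dec_fit - o$decision)), 1e-4)

  ## random <= 10-point sets across nu values
  set.seed(14)
  for (nu in c(0.3, 0.5, 0.75)) {
    n <- sample(5:8, 1)
    X <- matrix(rnorm(2 * n, sd = 1.5) + 3, ncol = 2)
    fit <- e1071::svm(X, type = "one-classification", kernel = "linear",
                      nu = nu, scale = FALSE, tolerance = 1e-8)
    w_fit <- as.numeric(t(fit$coefs) %*% fit$SV)
    Xq <- rbind(X, matrix(rnorm(10, sd = 2) + 3, ncol = 2))
    o <- oracle_decision(X, u = rep(1, n), nu = nu, X_query = Xq)
    expect_lt(max(abs((Xq %*% w_fit - fit$rho) - o$decision)), 1e-4)
  }
})

test_that("fit_subject_model agrees with the dual oracle end to end", {
  set.seed(5)
  X2 <- matrix(rnorm(16, sd = 0.8) + 4, ncol = 2)
  feats <- toy_features(X2)
  cfg_small <- pipeline_config(min_train_beats = 8L)
  expect_warning(m <- fit_subject_model(feats, cfg_small), "zero-variance")
  o <- oracle_decision(X2, u = rep(1, 8), nu = cfg$nu, X_query = X2)
  preds <- suppressWarnings(predict_beats(m, feats))
  expect_lt(max(abs(preds$score - (-o$decision))), 1e-4)
})

test_that("duplicating every training beat leaves the boundary unchanged", {
  # libsvm's dual scales with n (sum alpha = nu * n), so the hyperplane is
  # compared after normalization: direction and offset per unit normal
  tr <- small_model()
  m1 <- tr$model
  train <- dplyr::filter(tr$features, .data$split == "train")
  m2 <- fit_subject_model(dplyr::bind_rows(train, train), cfg,
                          subject_id = "dup")
  n1 <- sqrt(sum(m1$weights^2)); n2 <- sqrt(sum(m2$weights^2))
  expect_equal(m2$weights / n2, m1$weights / n1, tolerance = 1e-4)
  expect_equal(m2$rho / n2, m1$rho / n1, tolerance = 1e-4)
  ## and the induced labels agree on validation beats
  val <- dplyr::filter(tr$features, .data$split == "val")
  expect_identical(predict_beats(m2, val)$pred, predict_beats(m1, val)$pred)
})

test_that("the nu-property holds on a fitted subject model", {
  m <- small_model()$model
  expect_lte(m$train_outlier_fraction, m$nu + 0.02)
  expect_gte(m$sv_fraction, m$nu - 0.02)
  expect_gt(sqrt(sum(m$weights^2)), 0)
  expect_true(all(m$scaler$sd[m$scaler$used] > 0))
})

test_that("training preconditions are enforced", {
  tr <- small_model()
  train <- dplyr::filter(tr$features, .data$split == "train")
  expect_error(fit_subject_model(train[1:20, ], cfg), "training beats",
               class = "ecgdys_training_error")
  bad <- train; bad$label <- factor("dysglycemia", glycemic_levels())
  expect_error(fit_subject_model(bad, cfg), "euglycemic",
               class = "ecgdys_training_error")
})

test_that("scores orient dysglycemia positive and the boundary is euglycemic", {
  tr <- small_model()
  m <- tr$model
  val <- dplyr::filter(tr$features, .data$split == "val")
  preds <- predict_beats(m, val)
  ## inliers of the training set score negative
  train_preds <- predict_beats(m, dplyr::filter(tr$features,
                                                .data$split == "train"))
  expect_equal(mean(train_preds$score < 0), 1 - m$train_outlier_fraction,
               tolerance = 0.01)
  ## dysglycemic validation beats score higher than euglycemic ones
  expect_gt(mean(preds$score[preds$label == "dysglycemia"]),
            mean(preds$score[preds$label == "euglycemia"]))
  ## a point exactly on the hyperplane scores 0 and is labelled euglycemic
  ## (crafted model with exact arithmetic so the score is exactly zero)
  m0 <- m
  m0$weights <- setNames(rep(0, length(m$weights)), names(m$weights))
  m0$weights[["rr"]] <- 2
  m0$rho <- 1.5
  m0$scaler$scale_div <- rep(1, nrow(m0$scaler))
  on_df <- tibble::as_tibble(setNames(rep(list(0), 26), ecg_feature_names()))
  on_df$rr <- 0.75   # w . x = 1.5 = rho exactly
  p_on <- predict_beats(m0, on_df)
  expect_identical(p_on$score, 0)
  expect_identical(as.character(p_on$pred), "euglycemia")
  expect_identical(
    as.character(predict_beats(m0, dplyr::mutate(on_df, rr = 0.74))$pred),
    "dysglycemia")
  ## a missing feature is an error naming it
  expect_error(predict_beats(m, val[setdiff(names(val), "rr")]), "rr",
               class = "ecgdys_prediction_error")
})

test_that("window votes follow strip-anchored majority with ties to dysglycemia", {
  mk <- function(n, n_dys, strip = 1L) {
    tibble::tibble(
      r_time_s = seq(0.2, 9.8, length.out = n) + (strip - 1) * 600,
      pred = factor(rep(c("dysglycemia", "euglycemia"), c(n_dys, n - n_dys)),
                    levels = glycemic_levels()[1:2]),
      strip_id = strip, strip_start_s = (strip - 1) * 600,
      label = factor("euglycemia", glycemic_levels()))
  }
  w <- vote_windows(mk(12, 7), cfg)
  w1 <- w[w$n_beats > 0, ]
  expect_identical(nrow(w1), 1L)
  expect_identical(as.character(w1$pred), "dysglycemia")
  expect_equal(w1$window_score, 7 / 12)
  ## tie rule against exhaustive enumeration of vote counts
  for (k in 0:12) {
    wk <- vote_windows(mk(12, k), cfg)
    wk <- wk[wk$n_beats > 0, ]
    expect_identical(as.character(wk$pred),
                     if (k >= 6) "dysglycemia" else "euglycemia")
  }
  ## a full 600-s strip partitions into exactly 60 windows
  full <- tibble::tibble(
    r_time_s = seq(0.5, 599.5, by = 0.74),
    pred = factor("euglycemia", glycemic_levels()[1:2]),
    strip_id = 1L, strip_start_s = 0,
    label = factor("euglycemia", glycemic_levels()))
  wf <- vote_windows(full, cfg)
  expect_identical(nrow(wf), 60L)
  expect_true(all(wf$n_beats > 0))
  ## empty windows are emitted unlabelled
  sparse <- full[full$r_time_s < 10, ]
  ws <- vote_windows(sparse, cfg)
  expect_identical(nrow(ws), 60L)
  expect_identical(sum(ws$n_beats > 0), 1L)
  expect_true(all(is.na(ws$pred[ws$n_beats == 0])))
})

test_that("voting is monotone: flipping a vote to dysglycemia never flips a window to euglycemia", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    k <- sample(0:n, 1)
    mk <- function(n_dys) tibble::tibble(
      r_time_s = seq(0.1, 9.9, length.out = n),
      pred = factor(rep(c("dysglycemia", "euglycemia"), c(n_dys, n - n_dys)),
                    levels = glycemic_levels()[1:2]),
      strip_id = 1L, strip_start_s = 0,
      label = factor("euglycemia", glycemic_levels()))
    w1 <- vote_windows(mk(k), cfg); w1 <- w1[w1$n_beats > 0, ]
    if (k < n) {
      w2 <- vote_windows(mk(k + 1L), cfg); w2 <- w2[w2$n_beats > 0, ]
      if (as.character(w1$pred) == "dysglycemia") {
        expect_identical(as.character(w2$pred), "dysglycemia")
      }
    }
  }
})

test_that("feature importance ranks by |weight| with canonical tie-breaks", {
  m <- small_model()$model
  fake <- m
  fake$weights <- setNames(rep(0, length(m$weights)), names(m$weights))
  fake$weights[["rr"]] <- 3
  imp <- feature_importance(fake)
  expect_identical(imp$feature[1], "rr")
  expect_equal(imp$importance[1], 3)
  # all-tied remainder keeps canonical feature order
  expect_identical(imp$feature[-1],
                   setdiff(ecg_feature_names(), "rr"))
  ## permutation of input feature columns does not change the ranking
  tr <- small_model()
  train <- dplyr::filter(tr$features, .data$split == "train")
  perm <- train[c(setdiff(names(train), ecg_feature_names()),
                  rev(ecg_feature_names()))]
  m_perm <- fit_subject_model(perm, cfg, subject_id = "perm")
  expect_equal(feature_importance(m_perm)$feature,
               feature_importance(m)$feature)
  ## cohort aggregate averages importances
  agg <- feature_importance(list(fake, fake))
  expect_identical(agg$feature[1], "rr")
  expect_equal(agg$importance[1], 3)
})

test_that("per-feature F scores separate shifted features", {
  set.seed(8)
  n <- 400
  f <- toy_features(matrix(rnorm(2 * n), ncol = 2))
  f$rr <- rnorm(n, mean = rep(c(0.74, 0.66), each = n / 2), sd = 0.02)
  f$label <- factor(rep(c("euglycemia", "dysglycemia"), each = n / 2),
                    glycemic_levels())
  fs <- feature_f_scores(f)
  expect_identical(fs$feature[1], "rr")
  expect_gt(fs$f_stat[1], 100)
})

test_that("tidiers expose the model in broom shape", {
  m <- small_model()$model
  td <- tidy(m)
  expect_identical(nrow(td), 26L)
  expect_true(all(c("feature", "weight", "importance", "rank") %in% names(td)))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$nu, 0.75)
})
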