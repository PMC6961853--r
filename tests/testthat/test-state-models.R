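# small synthetic windowed cohorts built directly (no audio needed)
make_windows <- function(n_part, n_win, signs = NULL, noise = 0.3,
                         seed = 1, n_feat = 6) {
  do.call(rbind, lapply(seq_len(n_part), function(i) {
    with_seed(derive_seed(seed, i), {
      s <- if (is.null(signs)) rep(1, n_feat)
           else sample(c(-1, 1), n_feat, replace = TRUE)
      state <- as.numeric(arima.sim(list(ar = 0.6), n_win))
      feats <- sapply(seq_len(n_feat), function(j)
        s[j] * state + rnorm(n_win, 0, noise))
      colnames(feats) <- sprintf("f%02d", seq_len(n_feat))
      cbind(data.frame(participant_id = sprintf("P%02d", i),
                       window_index = seq_len(n_win),
                       n_calls_in_window = 4L,
                       mean_rating = clip(5.5 + 1.5 * state +
                                            rnorm(n_win, 0, 0.3), 1, 10)),
            as.data.frame(feats))
    })
  }))
}

test_that("the hyperparameter grid spans 12 combinations by default", {
  mc <- model_config()
  expect_equal(length(mc$cost_grid) * length(mc$epsilon_grid), 12)
  expect_equal(mc$window_size, 4L)
  expect_equal(mc$min_samples_personalized, 35L)
})

test_that("population LOSO excludes the test participant and learns shared structure", {
  win <- make_windows(6, 10, signs = NULL, seed = 2)
  mc <- model_config(inner_folds = 3, seed = 2)
  ps <- fit_predict_population(win, mc)
  expect_s3_class(ps, "prediction_set")
  expect_equal(sort(unique(ps$records$participant_id)),
               sprintf("P%02d", 1:6))
  # every participant's windows are all predicted (test fold covered once)
  expect_equal(nrow(ps$records), nrow(win))
  ev <- evaluate(ps, baseline_predictions(win, "zero_correlation"))
  expect_gt(ev$mean_rho, 0.5)
  expect_lt(ev$p_vs_baseline, 0.05)

  expect_error(fit_predict_population(win[win$participant_id == "P01", ], mc),
               "3 participants")
  expect_error(fit_predict_population(win, mc, target = "nope"), "target")
})

test_that("personalized model needs the call threshold and beats population on heterogeneous data", {
  win <- make_windows(5, 12, signs = "random", seed = 3)
  calls <- setNames(rep(48L, 5), sprintf("P%02d", 1:5))
  mc <- model_config(inner_folds = 3, seed = 3)
  pers <- fit_predict_personalized(win, mc, calls_per_participant = calls)
  ev_p <- evaluate(pers, baseline_predictions(win, "individual_loo_mean"))
  pop <- fit_predict_population(win, mc)
  ev_o <- evaluate(pop, baseline_predictions(win, "zero_correlation"))
  expect_gt(ev_p$mean_rho, ev_o$mean_rho + 0.15)

  # below the 35-call threshold the participant is skipped with a message
  low <- calls; low["P01"] <- 34L
  expect_message(
    skipped <- fit_predict_personalized(win, mc, calls_per_participant = low),
    "threshold")
  expect_false("P01" %in% skipped$records$participant_id)
})

test_that("baselines: leave-one-out means are exact and zero baseline is empty", {
  win <- data.frame(participant_id = "A", window_index = 1:3,
                    n_calls_in_window = 4L, mean_rating = c(2, 4, 6))
  b <- baseline_predictions(win, "individual_loo_mean")
  expect_equal(b$records$predicted, c(5, 4, 3))

  const <- transform(win, mean_rating = 5)
  expect_equal(baseline_predictions(const,
                                    "individual_loo_mean")$records$predicted,
               c(5, 5, 5))

  z <- baseline_predictions(win, "zero_correlation")
  expect_equal(nrow(z$records), 0)
  expect_equal(attr(z, "reference_rho"), 0)
})

test_that("evaluation: perfect predictions give rho 1; identical sets give p 1", {
  recs <- data.frame(participant_id = rep(c("A", "B"), each = 5),
                     window_index = rep(1:5, 2),
                     actual = c(1:5, 5:1), predicted = c(1:5, 5:1))
  ps <- speechstate:::new_prediction_set(recs, "personalized_concurrent")
  ev <- evaluate(ps)
  expect_equal(ev$mean_rho, 1)

  ev_same <- evaluate(ps, ps)
  expect_equal(ev_same$p_vs_baseline, 1)

  # permuted predictions carry no signal
  perm <- with_seed(9, {
    recs2 <- data.frame(participant_id = rep(sprintf("Q%d", 1:10), each = 12),
                        window_index = rep(1:12, 10),
                        actual = rnorm(120))
    recs2$predicted <- sample(recs2$actual)
    recs2
  })
  ev2 <- evaluate(speechstate:::new_prediction_set(perm, "x"),
                  baseline_predictions(
                    data.frame(participant_id = perm$participant_id,
                               window_index = perm$window_index,
                               n_calls_in_window = 4L,
                               mean_rating = perm$actual), "zero_correlation"))
  expect_lt(abs(ev2$mean_rho), 0.15)
  expect_gt(ev2$p_vs_baseline, 0.05)

  expect_error(evaluate(speechstate:::new_prediction_set(recs[0, ], "x")),
               "empty")
})

test_that("forecasting pairs window t features with window t+1 ratings", {
  win <- make_windows(3, 6, seed = 4)
  lw <- speechstate:::lag_windows(win, "mean_rating", 1L)
  p1 <- lw$data[lw$data$participant_id == "P01", ]
  expect_equal(nrow(p1), 5)
  expect_equal(p1$.target_window, 2:6)
  orig <- win[win$participant_id == "P01", ]
  expect_equal(p1$.target, orig$mean_rating[2:6])
  expect_equal(p1$f01, orig$f01[1:5])
})

test_that("forecasting trails concurrent assessment on autocorrelated states", {
  # with AR(1) latent states (autocorrelation < 1), predicting the next
  # window must be harder than predicting the current one, in expectation
  mc <- model_config(cost_grid = c(0.1, 1), epsilon_grid = 0.1,
                     inner_folds = 2, seed = 1)
  diffs <- vapply(1:20, function(s) {
    win <- make_windows(4, 10, seed = 400 + s, noise = 0.6)
    conc <- evaluate(fit_predict_population(win, mc, lag = 0L))$mean_rho
    fore <- evaluate(fit_predict_population(win, mc, lag = 1L))$mean_rho
    conc - fore
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("diagnosis classifier is perfect on separable classes and chance on random labels", {
  # separable: class decides the feature mean
  tbl <- do.call(rbind, lapply(1:8, function(i) {
    cls <- if (i <= 4) "a" else "b"
    with_seed(i, feature_rows(sprintf("P%d", i), ratings = rep(5, 6),
                              features = list(f1 = rnorm(6, ifelse(cls == "a", -3, 3)),
                                              f2 = rnorm(6))))
  }))
  labels <- setNames(rep(c("a", "b"), each = 4), sprintf("P%d", 1:8))
  res <- classify_diagnosis(tbl, labels, model_config(seed = 5),
                            n_permutations = 50)
  expect_equal(res$uar, 1)
  expect_lt(res$permutation_p, 0.05)

  expect_error(classify_diagnosis(tbl, setNames(rep("a", 8), names(labels))),
               "2 classes")
  one_off <- labels; one_off["P8"] <- "c"
  expect_error(classify_diagnosis(tbl, one_off), "at least 2 participants")
})

test_that("assessment scores serve as population-model targets via nearest-call matching", {
  # periodic scale scores (BASIS-24-like) matched to the nearest call become
  # the .target column of the same population path used for provider ratings
  with_seed(60, {
    tbl <- do.call(rbind, lapply(1:4, function(i) {
      state <- as.numeric(arima.sim(list(ar = 0.6), 12))
      feature_rows(sprintf("P%d", i), ratings = rep(5, 12),
                   features = list(f1 = state + rnorm(12, 0, 0.3),
                                   f2 = -state + rnorm(12, 0, 0.3),
                                   score_true = 2 + 0.5 * state))
    }))
  })
  calls <- lapply(seq_len(nrow(tbl)), function(i)
    list(participant_id = tbl$participant_id[i], call_time = tbl$call_time[i],
         provider_rating = 5, responses = list()))
  assessments <- data.frame(participant_id = tbl$participant_id,
                            date = tbl$call_time + 0.3,   # near each call
                            scale_name = "basis24_dep",
                            score = tbl$score_true)
  pairs <- align_nearest_assessment(calls, assessments, max_gap_days = 14)
  merged <- merge(tbl, pairs[, c("participant_id", "call_time", "score")])
  win <- cbind(merged[c("participant_id", "score", "f1", "f2")],
               window_index = ave(merged$call_time, merged$participant_id,
                                  FUN = seq_along),
               n_calls_in_window = 1L, mean_rating = NA_real_)
  ps <- fit_predict_population(win, model_config(inner_folds = 2, seed = 6),
                               target = "score")
  ev <- evaluate(ps)
  expect_gt(ev$mean_rho, 0.5)
})

test_that("no training-fold statistic leaks from the test fold", {
  win <- make_windows(5, 8, seed = 6)
  feat_cols <- sprintf("f%02d", 1:6)
  # preprocessor statistics come from the training rows only: corrupting a
  # test row must not move them
  tr <- win[win$participant_id != "P01", feat_cols]
  prep1 <- fit_preprocessor(tr)
  te <- win[win$participant_id == "P01", feat_cols]
  te[1, ] <- 1e6  # extreme outlier in the test fold
  prep2 <- fit_preprocessor(tr)  # unchanged input -> unchanged stats
  expect_identical(prep1, prep2)
  Xte <- apply_preprocessor(prep1, te)
  expect_equal(dim(Xte), dim(as.matrix(te)))

  # memorization guard: with pure-noise features a leaky pipeline (test rows
  # visible to the fit or the preprocessing) could memorize held-out targets,
  # while an honest leave-one-subject-out fit must show no test-fold skill
  noise_win <- with_seed(80, {
    nw <- make_windows(8, 12, seed = 8)
    nw[sprintf("f%02d", 1:6)] <- matrix(rnorm(96 * 6), 96)
    nw
  })
  ps <- fit_predict_population(noise_win, model_config(inner_folds = 3,
                                                       seed = 7))
  ev <- evaluate(ps, baseline_predictions(noise_win, "zero_correlation"))
  expect_lt(abs(ev$mean_rho), 0.3)
  expect_gt(ev$p_vs_baseline, 0.01)
})
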