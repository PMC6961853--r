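#' Model configuration for clinical-state tracking
#'
#' Hyperparameters of the nested-cross-validation linear support-vector
#' regression: the cost and epsilon grids searched in the inner layer, the
#' inner fold count, the call-window size, the minimum number of calls a
#' participant needs for a personalized model, the forecasting lag (in
#' windows), and the RNG seed for inner-fold shuffles and permutation tests.
#'
#' @param cost_grid SVR cost values searched.
#' @param epsilon_grid SVR epsilon values searched.
#' @param inner_folds folds of the inner (tuning) cross-validation layer.
#' @param window_size calls per non-overlapping averaging window.
#' @param min_samples_personalized minimum calls for a personalized model.
#' @param forecasting_lag lag in windows for forecasting models.
#' @param seed RNG seed.
#' @return a list of class \code{model_config}.
#' @export
model_config <- function(cost_grid = c(0.01, 0.1, 1, 10),
                         epsilon_grid = c(0.01, 0.1, 1),
                         inner_folds = 5L, window_size = 4L,
                         min_samples_personalized = 35L,
                         forecasting_lag = 1L, seed = 1L) {
  stopifnot(length(cost_grid) > 0, length(epsilon_grid) > 0, window_size >= 1)
  structure(list(cost_grid = cost_grid, epsilon_grid = epsilon_grid,
                 inner_folds = as.integer(inner_folds),
                 window_size = as.integer(window_size),
                 min_samples_personalized = as.integer(min_samples_personalized),
                 forecasting_lag = as.integer(forecasting_lag),
                 seed = as.integer(seed)),
            class = "model_config")
}

# --- preprocessing: fold-internal imputation and standardization ---------

#' Fit fold-internal preprocessing statistics
#'
#' Computes, on training data only, the columns to keep (all-missing and
#' zero-variance columns dropped), per-column medians for imputation, and
#' z-scoring center/scale. Applying the result to test data uses the
#' training statistics unchanged, so no test information leaks into the
#' transform.
#'
#' @param X training feature matrix (may contain NA).
#' @return a list of class \code{preprocessor}.
#' @export
fit_preprocessor <- function(X) {
  X <- as.matrix(X)
  med <- suppressWarnings(apply(X, 2, stats::median, na.rm = TRUE))
  keep <- is.finite(med)
  X <- X[, keep, drop = FALSE]
  med <- med[keep]
  imp <- impute_median(X, medians = med)$X
  center <- colMeans(imp)
  scale <- apply(imp, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  structure(list(columns = colnames(X), medians = med, center = center,
                 scale = scale),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#' @param prep a \code{preprocessor}.
#' @param X feature matrix (training or test fold).
#' @return imputed, standardized matrix restricted to the training columns.
#' @export
apply_preprocessor <- function(prep, X) {
  X <- as.matrix(X)[, prep$columns, drop = FALSE]
  X <- impute_median(X, medians = prep$medians)$X
  sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
}

svr_fit <- function(X, y, cost, epsilon) {
  # with every training target inside the epsilon tube the SVR has no
  # support vectors and the regression function is flat; libsvm cannot even
  # evaluate such a model, so fall back to predicting the training mean
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
               cost = cost, epsilon = epsilon, scale = FALSE, fitted = FALSE,
               tolerance = 0.01),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$tot.nSV) || fit$tot.nSV == 0)
    return(structure(list(const = mean(y)), class = "svr_const"))
  fit
}

svr_predict <- function(fit, X) {
  if (inherits(fit, "svr_const")) return(rep(fit$const, nrow(X)))
  as.numeric(stats::predict(fit, X))
}

# Inner grid search over cost x epsilon minimizing mean absolute error.
# fold_id assigns each training row to an inner fold.
inner_grid_search <- function(X, y, fold_id, config) {
  grid <- expand.grid(cost = config$cost_grid, epsilon = config$epsilon_grid)
  folds <- unique(fold_id)
  if (length(folds) < 2L) return(list(cost = 1, epsilon = 0.1))
  abs_err <- vector("list", nrow(grid))
  for (f in folds) {
    tr <- fold_id != f; te <- !tr
    if (sum(tr) < 2L || !any(te)) next
    prep <- fit_preprocessor(X[tr, , drop = FALSE])
    Xtr <- apply_preprocessor(prep, X[tr, , drop = FALSE])
    Xte <- apply_preprocessor(prep, X[te, , drop = FALSE])
    for (g in seq_len(nrow(grid))) {
      fit <- svr_fit(Xtr, y[tr], grid$cost[g], grid$epsilon[g])
      abs_err[[g]] <- c(abs_err[[g]], abs(svr_predict(fit, Xte) - y[te]))
    }
  }
  mae <- vapply(abs_err, function(e) if (length(e)) mean(e) else Inf, 0)
  best <- which.min(mae)
  list(cost = grid$cost[best], epsilon = grid$epsilon[best])
}

# Pair window features at t with the target at t + lag within participants.
lag_windows <- function(windows, target, lag) {
  feat_cols <- setdiff(names(windows),
                       c("participant_id", "window_index",
                         "n_calls_in_window", "mean_rating", target))
  parts <- split(windows, windows$participant_id)
  out <- lapply(parts, function(p) {
    p <- p[order(p$window_index), , drop = FALSE]
    n <- nrow(p)
    if (n <= lag) return(NULL)
    src <- seq_len(n - lag)
    d <- p[src, c("participant_id", "window_index", feat_cols), drop = FALSE]
    d$.target <- p[[target]][src + lag]
    d$.target_window <- p$window_index[src + lag]
    d
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  list(data = out, feat_cols = feat_cols)
}

new_prediction_set <- function(records, mode) {
  structure(list(mode = mode, records = records), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set [", x$mode, "]: ", nrow(x$records), " records, ",
      length(unique(x$records$participant_id)), " participants\n", sep = "")
  invisible(x)
}

#' Population model: leave-one-subject-out SVR
#'
#' For each participant, trains an L2-regularized linear support-vector
#' regression on every other participant's windows, with an inner
#' participant-grouped grid search over cost x epsilon minimizing mean
#' absolute error. Imputation and standardization statistics are fit on each
#' training fold only. \code{lag = 0} is concurrent assessment (window t's
#' features predict window t's rating); \code{lag = 1} forecasts the next
#' window's rating. Predictions are clipped to the 1-10 rating scale when
#' the target is the provider rating.
#'
#' @param windows windowed cohort data frame from
#'   \code{\link{window_average_cohort}}.
#' @param config a \code{\link{model_config}}.
#' @param target target column (default \code{"mean_rating"}).
#' @param lag forecasting lag in windows.
#' @return a \code{prediction_set}.
#' @export
fit_predict_population <- function(windows, config = model_config(),
                                   target = "mean_rating", lag = 0L) {
  if (!target %in% names(windows)) stop("target column not found: ", target)
  pids <- unique(windows$participant_id)
  if (length(pids) < 3L) stop("population model needs at least 3 participants")
  lw <- lag_windows(windows, target, lag)
  d <- lw$data
  d <- d[is.finite(d$.target), , drop = FALSE]
  clip_preds <- identical(target, "mean_rating")
  recs <- list()
  for (pid in pids) {
    test <- d$participant_id == pid
    train <- !test
    if (!any(test) || sum(train) < 6L) next
    Xtr <- as.matrix(d[train, lw$feat_cols, drop = FALSE])
    ytr <- d$.target[train]
    tr_pids <- d$participant_id[train]
    u <- unique(tr_pids)
    shuffled <- with_seed(derive_seed(config$seed, match(pid, pids)),
                          sample(u))
    grp <- stats::setNames(rep(seq_len(config$inner_folds),
                               length.out = length(u)), shuffled)
    fold_id <- grp[tr_pids]
    best <- inner_grid_search(Xtr, ytr, fold_id, config)
    prep <- fit_preprocessor(Xtr)
    fit <- svr_fit(apply_preprocessor(prep, Xtr), ytr, best$cost, best$epsilon)
    Xte <- apply_preprocessor(prep, d[test, lw$feat_cols, drop = FALSE])
    pred <- svr_predict(fit, Xte)
    if (clip_preds) pred <- clip(pred, 1, 10)
    recs[[pid]] <- data.frame(participant_id = pid,
                              window_index = d$.target_window[test],
                              actual = d$.target[test], predicted = pred,
                              stringsAsFactors = FALSE)
  }
  new_prediction_set(do.call(rbind, recs),
                     if (lag == 0) "population_concurrent"
                     else "population_forecast")
}

#' Personalized model: leave-one-window-out SVR within a participant
#'
#' For each qualifying participant (at least
#' \code{config$min_samples_personalized} calls before windowing), each
#' window is predicted by a model trained on the participant's remaining
#' windows, with a sequential-block inner grid search. Below-threshold
#' participants are skipped with a message.
#'
#' @param windows windowed cohort data frame.
#' @param config a \code{\link{model_config}}.
#' @param lag forecasting lag in windows.
#' @param calls_per_participant named vector of raw call counts (before
#'   windowing); defaults to \code{n_calls_in_window} sums.
#' @return a \code{prediction_set}.
#' @export
fit_predict_personalized <- function(windows, config = model_config(),
                                     lag = 0L, calls_per_participant = NULL) {
  if (is.null(calls_per_participant)) {
    calls_per_participant <- tapply(windows$n_calls_in_window,
                                    windows$participant_id, sum)
  }
  lw <- lag_windows(windows, "mean_rating", lag)
  recs <- list()
  for (pid in unique(windows$participant_id)) {
    if (calls_per_participant[[pid]] < config$min_samples_personalized) {
      message("participant ", pid, " below the ",
              config$min_samples_personalized, "-call threshold; skipped")
      next
    }
    d <- lw$data[lw$data$participant_id == pid, , drop = FALSE]
    d <- d[is.finite(d$.target), , drop = FALSE]
    n <- nrow(d)
    if (n < 4L) next
    X <- as.matrix(d[, lw$feat_cols, drop = FALSE])
    preds <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      Xtr <- X[tr, , drop = FALSE]; ytr <- d$.target[tr]
      fold_id <- rep(seq_len(min(config$inner_folds, length(tr))),
                     length.out = length(tr))   # sequential blocks
      best <- inner_grid_search(Xtr, ytr, fold_id, config)
      prep <- fit_preprocessor(Xtr)
      fit <- svr_fit(apply_preprocessor(prep, Xtr), ytr,
                     best$cost, best$epsilon)
      preds[i] <- svr_predict(fit, apply_preprocessor(prep,
                                                         X[i, , drop = FALSE]))
    }
    recs[[pid]] <- data.frame(participant_id = pid,
                              window_index = d$.target_window,
                              actual = d$.target,
                              predicted = clip(preds, 1, 10),
                              stringsAsFactors = FALSE)
  }
  new_prediction_set(do.call(rbind, recs),
                     if (lag == 0) "personalized_concurrent"
                     else "personalized_forecast")
}

#' Baseline prediction sets
#'
#' \code{"zero_correlation"} is the population baseline: no predictions, a
#' reference correlation fixed at zero. \code{"individual_loo_mean"}
#' predicts each window's rating by the mean of the participant's other
#' windows' ratings.
#'
#' @param windows windowed cohort data frame.
#' @param mode \code{"zero_correlation"} or \code{"individual_loo_mean"}.
#' @return a \code{prediction_set} (empty records for the zero baseline,
#'   with attribute \code{reference_rho = 0}).
#' @export
baseline_predictions <- function(windows,
                                 mode = c("zero_correlation",
                                          "individual_loo_mean")) {
  mode <- match.arg(mode)
  if (mode == "zero_correlation") {
    ps <- new_prediction_set(data.frame(participant_id = character(0),
                                        window_index = integer(0),
                                        actual = numeric(0),
                                        predicted = numeric(0)),
                             "baseline_zero")
    attr(ps, "reference_rho") <- 0
    return(ps)
  }
  parts <- split(windows, windows$participant_id)
  recs <- lapply(parts, function(p) {
    y <- p$mean_rating
    n <- length(y)
    loo <- if (n > 1L) (sum(y) - y) / (n - 1L) else rep(NA_real_, n)
    data.frame(participant_id = p$participant_id, window_index = p$window_index,
               actual = y, predicted = loo, stringsAsFactors = FALSE)
  })
  new_prediction_set(do.call(rbind, recs), "baseline_individual_mean")
}

#' Evaluate a prediction set against actual ratings and a baseline
#'
#' Computes the Spearman correlation between predicted and actual ratings
#' per participant (participants with fewer than three test windows or an
#' undefined correlation are excluded and counted), averages across
#' participants, and tests the improvement over the baseline by a t-test on
#' per-participant correlation differences (two-tailed by default). Against
#' the zero-correlation baseline the test is a one-sample t-test of the
#' per-participant correlations against zero.
#'
#' @param predictions a \code{prediction_set}.
#' @param baseline a baseline \code{prediction_set}, or NULL.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}.
#' @param aggregate \code{"per_participant"} (mean of per-participant rho)
#'   or \code{"pooled"} (single rho over all records).
#' @return list of class \code{evaluation_result}: \code{mean_rho},
#'   \code{per_participant_rho}, \code{pooled_rho}, \code{p_vs_baseline},
#'   \code{baseline_mean_rho}, \code{n_participants}, \code{n_samples},
#'   \code{n_excluded}.
#' @export
evaluate <- function(predictions, baseline = NULL,
                     alternative = c("two.sided", "greater"),
                     aggregate = c("per_participant", "pooled")) {
  alternative <- match.arg(alternative)
  aggregate <- match.arg(aggregate)
  recs <- predictions$records
  if (is.null(recs) || !nrow(recs)) stop("empty prediction set")
  per_part <- vapply(split(recs, recs$participant_id), function(p)
    spearman(p$predicted, p$actual)$rho, 0)
  usable <- is.finite(per_part)
  rhos <- per_part[usable]
  if (!length(rhos))
    stop("no participant with at least 3 evaluable test windows")
  pooled <- spearman(recs$predicted, recs$actual)$rho
  mean_rho <- if (aggregate == "pooled") pooled else mean(rhos)
  p_base <- NA_real_
  base_rho <- NA_real_
  if (!is.null(baseline)) {
    if (identical(baseline$mode, "baseline_zero")) {
      base_rho <- attr(baseline, "reference_rho") %||% 0
      diffs <- rhos - base_rho
    } else {
      bpp <- vapply(split(baseline$records, baseline$records$participant_id),
                    function(p) spearman(p$predicted, p$actual)$rho, 0)
      common <- intersect(names(rhos), names(bpp)[is.finite(bpp)])
      base_rho <- mean(bpp[common])
      diffs <- rhos[common] - bpp[common]
    }
    p_base <- if (length(diffs) >= 2L && stats::sd(diffs) > 1e-12) {
      tryCatch(stats::t.test(diffs, alternative = alternative)$p.value,
               error = function(e) NA_real_)
    } else 1.0
  }
  structure(list(mean_rho = mean_rho, per_participant_rho = per_part,
                 pooled_rho = pooled, p_vs_baseline = p_base,
                 baseline_mean_rho = base_rho,
                 n_participants = length(rhos), n_samples = nrow(recs),
                 n_excluded = sum(!usable)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("mean Spearman rho = %.3f over %d participants (%d samples)\n",
              x$mean_rho, x$n_participants, x$n_samples))
  if (is.finite(x$p_vs_baseline))
    cat(sprintf("vs baseline (mean rho %.3f): p = %.4g\n",
                x$baseline_mean_rho, x$p_vs_baseline))
  invisible(x)
}

#' Diagnosis classification from participant-aggregated features
#'
#' Aggregates each participant's calls to mean features, runs a
#' leave-one-subject-out linear support-vector classifier, and reports
#' per-class recall and the unweighted average recall (UAR), with a
#' label-permutation p-value (chance UAR is 1/k).
#'
#' @param table a \code{call_feature_table}.
#' @param labels named character vector of diagnosis labels per participant.
#' @param config a \code{\link{model_config}} (seed used for permutations).
#' @param n_permutations label permutations for the p-value.
#' @param cost SVC cost.
#' @return list with \code{per_class_recall}, \code{uar},
#'   \code{permutation_p}, \code{n_participants}.
#' @export
classify_diagnosis <- function(table, labels, config = model_config(),
                               n_permutations = 200L, cost = 1) {
  feat_cols <- setdiff(names(table),
                       c("participant_id", "call_time", "provider_rating"))
  agg <- do.call(rbind, lapply(split(as.data.frame(table),
                                     table$participant_id), function(p)
    colMeans(as.matrix(p[, feat_cols, drop = FALSE]), na.rm = TRUE)))
  labels <- labels[rownames(agg)]
  if (any(is.na(labels))) stop("missing diagnosis label for some participants")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("diagnosis classification needs at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 participants")
  loso_uar <- function(y) {
    pred <- character(length(y))
    for (i in seq_along(y)) {
      tr <- -i
      prep <- fit_preprocessor(agg[tr, , drop = FALSE])
      fit <- e1071::svm(apply_preprocessor(prep, agg[tr, , drop = FALSE]),
                        droplevels(y[tr]), type = "C-classification",
                        kernel = "linear", cost = cost, scale = FALSE)
      pred[i] <- as.character(stats::predict(
        fit, apply_preprocessor(prep, agg[i, , drop = FALSE])))
    }
    recalls <- vapply(levels(y), function(cl)
      mean(pred[y == cl] == cl), 0)
    list(uar = mean(recalls), recalls = recalls)
  }
  obs <- loso_uar(y)
  perm <- with_seed(derive_seed(config$seed, 777L),
                    vapply(seq_len(n_permutations), function(i)
                      loso_uar(sample(y))$uar, 0))
  p <- (1 + sum(perm >= obs$uar)) / (n_permutations + 1)
  list(per_class_recall = obs$recalls, uar = obs$uar, permutation_p = p,
       n_participants = length(y))
}
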