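#' Default pipeline configuration
#'
#' A single nested list covering simulation, extraction, correlation,
#' stability, and modeling stages. Unknown keys in a user configuration are
#' rejected at validation time.
#'
#' @return a named list of class \code{pipeline_config}.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 0L,
    out_dir = "speechstate_out",
    simulate = list(n_participants = 12L, calls_per_participant = 60L,
                    loading_mode = "heterogeneous"),
    extract = list(norm_lexicon = NULL, category_lexicon = NULL, lsa_k = 50L),
    stability = list(min_half = 10L, method = "fisher_z"),
    correlate = list(alpha = 0.05, min_calls = 35L),
    model = list(cost_grid = c(0.01, 0.1, 1, 10),
                 epsilon_grid = c(0.01, 0.1, 1), inner_folds = 5L,
                 window_size = 4L, min_samples_personalized = 35L,
                 forecasting_lag = 1L),
    classify = list(n_permutations = 200L)
  ), class = "pipeline_config")
}

load_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad))
        stop("unknown configuration key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      base[[k]][names(user[[k]])] <- user[[k]]
    } else base[[k]] <- user[[k]]
  }
  base
}

#' Run one pipeline command
#'
#' Thin orchestration over the package functions:
#' \code{simulate} writes the synthetic cohort; \code{extract} writes
#' \code{features.csv}; \code{correlate} writes \code{correlations.csv} and
#' \code{profiles.csv}; \code{stability} writes \code{stability.csv};
#' \code{model} writes \code{predictions.csv}; \code{classify} appends the
#' diagnosis-classification result; \code{report} assembles
#' \code{report.json}; \code{all} chains
#' simulate-extract-correlate-model-report.
#'
#' @param name one of simulate, extract, correlate, stability, model,
#'   classify, report, all.
#' @param config a configuration list, a YAML path, or NULL for defaults.
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @return invisibly, a list of the artifacts the command produced.
#' @export
run_command <- function(name, config = NULL, seed = NULL, out_dir = NULL) {
  name <- match.arg(name, c("simulate", "extract", "correlate", "stability",
                            "model", "classify", "report", "all"))
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("speechstate run: command=", name, " seed=", cfg$seed,
          " out=", cfg$out_dir)

  paths <- list(manifest = file.path(cfg$out_dir, "cohort", "manifest.csv"),
                features = file.path(cfg$out_dir, "features.csv"),
                correlations = file.path(cfg$out_dir, "correlations.csv"),
                profiles = file.path(cfg$out_dir, "profiles.csv"),
                stability = file.path(cfg$out_dir, "stability.csv"),
                predictions = file.path(cfg$out_dir, "predictions.csv"),
                report = file.path(cfg$out_dir, "report.json"))

  do_simulate <- function() {
    p <- do.call(sim_params, c(cfg$simulate, list(seed = cfg$seed)))
    simulate_cohort(p, dir = file.path(cfg$out_dir, "cohort"))
  }
  get_features <- function() {
    if (!file.exists(paths$features))
      stop("missing input file: ", paths$features, " (run `extract` first)")
    read_feature_table(paths$features)
  }
  do_extract <- function() {
    if (!file.exists(paths$manifest))
      stop("missing input file: ", paths$manifest, " (run `simulate` first)")
    res <- feature_resources(
      norm_lexicon = if (!is.null(cfg$extract$norm_lexicon))
        read_norm_lexicon(cfg$extract$norm_lexicon),
      category_lexicon = if (!is.null(cfg$extract$category_lexicon))
        read_category_lexicon(cfg$extract$category_lexicon))
    cohort <- read_cohort(paths$manifest)
    feats <- extract_cohort_features(cohort, res, lsa_k = cfg$extract$lsa_k)
    write_feature_table(feats, paths$features)
    feats
  }
  do_correlate <- function(feats) {
    rep <- population_feature_correlations(feats, alpha = cfg$correlate$alpha)
    utils::write.csv(rep$report, paths$correlations, row.names = FALSE)
    prof <- individual_profiles(feats, min_calls = cfg$correlate$min_calls)
    if (!is.null(prof$profiles))
      utils::write.csv(data.frame(participant_id = rownames(prof$profiles),
                                  prof$profiles, check.names = FALSE),
                       paths$profiles, row.names = FALSE)
    list(correlations = rep, profiles = prof)
  }
  do_stability <- function(feats) {
    parts <- split(feats, feats$participant_id)
    res <- lapply(names(parts), function(pid) {
      st <- half_split_stability(parts[[pid]],
                                 method = cfg$stability$method,
                                 min_half = cfg$stability$min_half)
      data.frame(participant_id = pid,
                 stable_fraction = st$stable_fraction)
    })
    df <- do.call(rbind, res)
    utils::write.csv(df, paths$stability, row.names = FALSE)
    df
  }
  do_model <- function(feats) {
    mc <- do.call(model_config, c(cfg$model, list(seed = cfg$seed)))
    win <- window_average_cohort(feats, mc$window_size)
    calls <- table(feats$participant_id)
    sets <- list(
      population_concurrent = fit_predict_population(win, mc, lag = 0L),
      population_forecast = fit_predict_population(win, mc,
                                                   lag = mc$forecasting_lag),
      personalized_concurrent = fit_predict_personalized(
        win, mc, lag = 0L, calls_per_participant = calls),
      personalized_forecast = fit_predict_personalized(
        win, mc, lag = mc$forecasting_lag, calls_per_participant = calls))
    recs <- do.call(rbind, lapply(names(sets), function(m) {
      r <- sets[[m]]$records
      if (is.null(r) || !nrow(r)) return(NULL)
      cbind(mode = m, r)
    }))
    utils::write.csv(recs, paths$predictions, row.names = FALSE)
    sets
  }
  do_classify <- function(feats) {
    cohort_dx <- unique(utils::read.csv(paths$manifest)[
      c("participant_id", "diagnosis")])
    labels <- stats::setNames(cohort_dx$diagnosis, cohort_dx$participant_id)
    mc <- do.call(model_config, c(cfg$model, list(seed = cfg$seed)))
    classify_diagnosis(feats, labels, mc,
                       n_permutations = cfg$classify$n_permutations)
  }
  do_report <- function(sets, feats) {
    win <- window_average_cohort(feats,
                                 do.call(model_config,
                                         c(cfg$model,
                                           list(seed = cfg$seed)))$window_size)
    zero <- baseline_predictions(win, "zero_correlation")
    loo <- baseline_predictions(win, "individual_loo_mean")
    ev <- function(ps, base) {
      if (is.null(ps$records) || !nrow(ps$records)) return(NULL)
      e <- evaluate(ps, base)
      list(mean_rho = e$mean_rho, p_vs_baseline = e$p_vs_baseline,
           n_participants = e$n_participants, n_samples = e$n_samples)
    }
    rep <- list(seed = cfg$seed,
                population_concurrent = ev(sets$population_concurrent, zero),
                population_forecast = ev(sets$population_forecast, zero),
                personalized_concurrent = ev(sets$personalized_concurrent, loo),
                personalized_forecast = ev(sets$personalized_forecast, loo))
    jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA,
                         null = "null")
    rep
  }

  out <- list()
  if (name %in% c("simulate", "all")) out$cohort <- do_simulate()
  if (name %in% c("extract", "all")) out$features <- do_extract()
  feats <- if (!is.null(out$features)) out$features
           else if (name %in% c("correlate", "stability", "model", "classify",
                                "report")) get_features()
  if (name %in% c("correlate", "all")) out$correlate <- do_correlate(feats)
  if (name == "stability") out$stability <- do_stability(feats)
  if (name %in% c("model", "all")) out$model <- do_model(feats)
  if (name == "classify") out$classify <- do_classify(feats)
  if (name %in% c("report", "all")) {
    if (is.null(out$model)) out$model <- do_model(feats)
    out$report <- do_report(out$model, feats)
  }
  invisible(out)
}
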