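#' The default 70-feature per-response manifest
#'
#' 36 norm functionals (9 norms x mean/min/max/std), 15 category
#' percentages, 8 complexity features, 2 coherence features, and 9 acoustic
#' features. The per-call feature vector is this manifest applied to each of
#' the three responses (210 features), keyed \code{q<prompt>__<feature>}.
#'
#' @param categories category names for the percentage block; must have 15
#'   entries so the manifest totals 70.
#' @return character vector of 70 feature names.
#' @export
default_feature_manifest <- function(categories = NULL) {
  if (is.null(categories)) {
    lex <- read_category_lexicon(system.file("extdata", "demo_categories.dic",
                                             package = "speechstate"))
    categories <- names(lex)
  }
  nms <- norm_names()
  norm_feats <- as.vector(t(outer(nms, c("mean", "min", "max", "std"),
                                  function(a, b) paste0("norm_", a, "_", b))))
  manifest <- c(norm_feats,
                paste0("cat_", categories, "_pct"),
                c("flesch_reading_ease", "fk_grade", "smog", "ari",
                  "coleman_liau", "difficult_word_count", "word_count",
                  "mean_syllables_per_word"),
                c("coherence_mean", "coherence_std"),
                acoustic_feature_names())
  if (length(manifest) != 70L || anyDuplicated(manifest))
    stop("feature manifest must contain exactly 70 unique names; got ",
         length(manifest))
  manifest
}

#' Bundle the lexicons and LSA space needed for extraction
#'
#' @param norm_lexicon a \code{norm_lexicon} (default: the bundled demo
#'   norms).
#' @param category_lexicon a \code{category_lexicon} (default: the bundled
#'   demo dictionary).
#' @param lsa_space an \code{lsa_space}, or NULL to build one from the
#'   cohort's own responses at extraction time.
#' @param difficult_min_syllables rule for the difficult-word count.
#' @return a list of class \code{feature_resources}.
#' @export
feature_resources <- function(norm_lexicon = NULL, category_lexicon = NULL,
                              lsa_space = NULL, difficult_min_syllables = 7L) {
  if (is.null(norm_lexicon))
    norm_lexicon <- read_norm_lexicon(system.file("extdata", "demo_norms.csv",
                                                  package = "speechstate"))
  if (is.null(category_lexicon))
    category_lexicon <- read_category_lexicon(
      system.file("extdata", "demo_categories.dic", package = "speechstate"))
  structure(list(norm_lexicon = norm_lexicon,
                 category_lexicon = category_lexicon,
                 lsa_space = lsa_space,
                 difficult_min_syllables = difficult_min_syllables),
            class = "feature_resources")
}

# 70 features for one response; NA-filled when rejected/unreadable.
response_features <- function(resp, resources, manifest) {
  vals <- stats::setNames(rep(NA_real_, length(manifest)), manifest)
  if (isTRUE(resp$rejected)) return(vals)
  tokens <- tokenize(resp$transcript)
  nf <- norm_functionals(tokens, resources$norm_lexicon)
  vals[names(nf$functionals)] <- nf$functionals
  cp <- category_percentages(tokens, resources$category_lexicon)
  vals[paste0("cat_", names(cp), "_pct")] <- cp
  rd <- readability(tokens, resources$difficult_min_syllables)
  vals[names(rd)] <- rd
  if (!is.null(resources$lsa_space)) {
    ch <- coherence_features(tokens, resources$lsa_space, phrase_mode = "auto")
    vals["coherence_mean"] <- ch$mean_coherence
    vals["coherence_std"] <- ch$std_coherence
  }
  # an unreadable audio file invalidates the whole response (rejected); a
  # response with no audio at all keeps its text features and leaves the
  # acoustic block missing
  audio <- NULL
  if (!is.null(resp$audio_path) && !is.na(resp$audio_path) &&
      nzchar(resp$audio_path)) {
    audio <- tryCatch(read_wav(resp$audio_path), error = function(e) {
      message("unreadable audio, response treated as rejected: ",
              resp$audio_path)
      FALSE
    })
    if (isFALSE(audio))
      return(stats::setNames(rep(NA_real_, length(manifest)), manifest))
  } else if (inherits(resp$audio, "audio_segment")) {
    audio <- resp$audio
  }
  if (!is.null(audio)) {
    ac <- acoustic_feature_set(audio)
    vals[names(ac)] <- ac
  }
  vals
}

#' Extract the 210-feature row for one call
#'
#' Runs the lexical, coherence and acoustic extractors on each of the three
#' responses and concatenates them in manifest order. A rejected or
#' unreadable response contributes 70 missing values.
#'
#' @param call one call record from a \code{speech_cohort}.
#' @param resources a \code{feature_resources} (its \code{lsa_space} should
#'   be set for coherence features).
#' @param manifest the 70-name per-response manifest.
#' @return a one-row data frame: participant_id, call_time, provider_rating,
#'   then 210 feature columns named \code{q<prompt>__<feature>}; the
#'   manifest is attached as attribute \code{"manifest"}.
#' @export
extract_call_features <- function(call, resources,
                                  manifest = default_feature_manifest()) {
  stopifnot(length(manifest) == 70L)
  per_resp <- lapply(call$responses, response_features,
                     resources = resources, manifest = manifest)
  vals <- unlist(lapply(seq_len(3), function(q)
    stats::setNames(per_resp[[q]], paste0("q", q, "__", manifest))))
  row <- data.frame(participant_id = call$participant_id,
                    call_time = call$call_time,
                    provider_rating = call$provider_rating,
                    as.list(vals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(row, "manifest") <- manifest
  row
}

#' Extract the feature table for a whole cohort
#'
#' Builds the LSA space from the cohort's own responses when none is
#' supplied (the package's self-contained default), then extracts every
#' call.
#'
#' @param cohort a \code{speech_cohort}.
#' @param resources a \code{feature_resources}.
#' @param manifest the 70-name manifest.
#' @param lsa_k LSA dimensionality used when the space is built here.
#' @return data frame of class \code{call_feature_table}, one row per call,
#'   with the manifest attached as attribute \code{"manifest"}.
#' @export
extract_cohort_features <- function(cohort, resources = feature_resources(),
                                    manifest = default_feature_manifest(),
                                    lsa_k = 50) {
  if (is.null(resources$lsa_space)) {
    docs <- list()
    for (pid in names(cohort$participants))
      for (call in cohort$participants[[pid]])
        for (resp in call$responses)
          if (!isTRUE(resp$rejected) && !is.na(resp$transcript))
            docs[[length(docs) + 1L]] <- tokenize(resp$transcript)
    resources$lsa_space <- build_lsa_space(docs, k = min(lsa_k, 50))
  }
  rows <- list()
  for (pid in names(cohort$participants))
    for (call in cohort$participants[[pid]])
      rows[[length(rows) + 1L]] <- extract_call_features(call, resources,
                                                         manifest)
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- manifest
  class(out) <- c("call_feature_table", class(out))
  out
}

#' Column names of the 210 call-level features
#' @param manifest the 70-name per-response manifest.
#' @return character vector of 210 names.
#' @export
call_feature_names <- function(manifest = default_feature_manifest()) {
  as.vector(vapply(1:3, function(q) paste0("q", q, "__", manifest),
                   character(length(manifest))))
}

#' Non-overlapping window averages of features and ratings
#'
#' Consecutive, non-overlapping blocks of \code{w} calls per participant
#' (trailing remainder dropped, keeping windows independent). Within a
#' block, feature and rating means ignore missing values; a block feature is
#' missing only when all \code{w} values are.
#'
#' @param rows feature-table rows for one participant, time-sorted.
#' @param w window size in calls (default 4).
#' @return data frame: participant_id, window_index, n_calls_in_window,
#'   mean_rating, then the windowed feature columns.
#' @export
window_average <- function(rows, w = 4L) {
  stopifnot(w >= 1L)
  if (length(unique(rows$participant_id)) > 1L)
    stop("window_average expects rows from a single participant")
  rows <- rows[order(rows$call_time), , drop = FALSE]
  n_win <- nrow(rows) %/% w
  feat_cols <- setdiff(names(rows),
                       c("participant_id", "call_time", "provider_rating"))
  if (n_win == 0L) {
    out <- data.frame(participant_id = character(0), window_index = integer(0),
                      n_calls_in_window = integer(0), mean_rating = numeric(0))
    out[feat_cols] <- lapply(feat_cols, function(x) numeric(0))
    return(out)
  }
  res <- lapply(seq_len(n_win), function(b) {
    blk <- rows[((b - 1L) * w + 1L):(b * w), , drop = FALSE]
    mr <- mean(blk$provider_rating, na.rm = TRUE)
    fv <- vapply(feat_cols, function(cn) {
      v <- blk[[cn]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
    cbind(data.frame(participant_id = blk$participant_id[1], window_index = b,
                     n_calls_in_window = w,
                     mean_rating = if (is.nan(mr)) NA_real_ else mr,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, res)
}

#' Window-average every participant in a feature table
#' @param table a \code{call_feature_table}.
#' @param w window size in calls.
#' @return stacked windowed data frame across participants.
#' @export
window_average_cohort <- function(table, w = 4L) {
  parts <- split(as.data.frame(table), table$participant_id)
  out <- do.call(rbind, lapply(parts, window_average, w = w))
  rownames(out) <- NULL
  out
}

#' Match assessments to the nearest call within a time window
#'
#' Each assessment is matched to the temporally nearest call within
#' \code{max_gap_days}; ties go to the earlier call; unmatched assessments
#' are dropped with a message.
#'
#' @param calls list of call records (one participant) or a
#'   \code{speech_cohort}.
#' @param assessments data frame with columns \code{participant_id},
#'   \code{date} (same time scale as \code{call_time}), \code{scale_name},
#'   \code{score}.
#' @param max_gap_days maximum |assessment - call| gap, in days.
#' @return data frame pairing each matched assessment with its call's
#'   participant_id, call_time, scale_name, score.
#' @export
align_nearest_assessment <- function(calls, assessments, max_gap_days = 14) {
  if (inherits(calls, "speech_cohort")) {
    all_calls <- unlist(calls$participants, recursive = FALSE)
  } else all_calls <- calls
  ct <- vapply(all_calls, `[[`, 0, "call_time")
  cp <- vapply(all_calls, `[[`, "", "participant_id")
  out <- list()
  for (i in seq_len(nrow(assessments))) {
    a <- assessments[i, ]
    cand <- which(cp == a$participant_id)
    if (!length(cand)) next
    gap <- abs(ct[cand] - a$date)
    best <- cand[order(gap, ct[cand])][1]
    if (min(gap) > max_gap_days * 86400 * time_unit_scale(ct) ) {
      message("assessment unmatched (nearest call beyond window): ",
              a$participant_id, " @ ", a$date)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      participant_id = a$participant_id, assessment_date = a$date,
      scale_name = a$scale_name, score = a$score,
      call_time = ct[best], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(participant_id = character(0),
                      assessment_date = numeric(0), scale_name = character(0),
                      score = numeric(0), call_time = numeric(0)))
  do.call(rbind, out)
}

# Call times may be POSIX seconds or plain day counts; infer the scale a
# "day" takes on that axis.
time_unit_scale <- function(times) {
  if (length(times) && max(abs(times), na.rm = TRUE) > 1e6) 1 else 1 / 86400
}

#' Median-fill missing feature cells
#'
#' Fills each column's missing entries with that column's median (or with
#' externally supplied medians, e.g. computed on a training fold).
#' All-missing columns are dropped with a warning when no external medians
#' are given.
#'
#' @param X numeric matrix or data frame of features.
#' @param medians optional named vector of fill values (training-fold
#'   statistics); when supplied, columns are retained as-is.
#' @return list with \code{X} (imputed matrix) and \code{medians}.
#' @export
impute_median <- function(X, medians = NULL) {
  X <- as.matrix(X)
  if (is.null(medians)) {
    medians <- apply(X, 2, stats::median, na.rm = TRUE)
    all_na <- !is.finite(medians)
    if (any(all_na)) {
      warning("dropping all-missing feature column(s): ",
              paste(colnames(X)[all_na], collapse = ", "))
      X <- X[, !all_na, drop = FALSE]
      medians <- medians[!all_na]
    }
  } else {
    X <- X[, names(medians), drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- medians[j]
  }
  list(X = X, medians = medians)
}
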