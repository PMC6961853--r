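#' Spearman rank correlation with t-approximation p-value
#'
#' Pairwise-complete rank correlation using average ranks for ties; the
#' p-value comes from the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))}. Fewer than three complete
#' pairs, or a constant argument, gives missing results.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (!is.finite(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Population-level feature-rating correlation report
#'
#' Spearman correlation of every feature with the provider rating, pooled
#' over all rated calls, with a Bonferroni significance flag at
#' \code{alpha / n_features}. The report is sorted by |rho| descending.
#'
#' @param table a feature table (metadata columns plus feature columns) or a
#'   plain feature matrix/data frame.
#' @param ratings rating vector; taken from \code{table$provider_rating}
#'   when omitted.
#' @param alpha family-wise error level.
#' @return list of class \code{correlation_report}: \code{report} (data
#'   frame feature/rho/p/significant/n), \code{bonferroni_threshold},
#'   \code{mean_abs_rho}, \code{n_samples}, \code{alpha}.
#' @export
population_feature_correlations <- function(table, ratings = NULL,
                                            alpha = 0.05) {
  if (is.null(ratings)) ratings <- table$provider_rating
  feat_cols <- setdiff(names(table),
                       c("participant_id", "call_time", "provider_rating",
                         "window_index", "n_calls_in_window", "mean_rating"))
  if (sum(is.finite(ratings)) < 3L)
    stop("need at least 3 rated calls for a correlation report")
  res <- lapply(feat_cols, function(cn) spearman(table[[cn]], ratings))
  report <- data.frame(feature = feat_cols,
                       rho = vapply(res, `[[`, 0, "rho"),
                       p = vapply(res, `[[`, 0, "p"),
                       n = vapply(res, `[[`, 0L, "n"),
                       stringsAsFactors = FALSE)
  thr <- alpha / length(feat_cols)
  report$significant <- !is.na(report$p) & report$p < thr
  report <- report[order(-abs(report$rho)), ]
  rownames(report) <- NULL
  structure(list(report = report, bonferroni_threshold = thr,
                 mean_abs_rho = mean(abs(report$rho), na.rm = TRUE),
                 n_samples = sum(is.finite(ratings)), alpha = alpha),
            class = "correlation_report")
}

#' Per-individual feature-rating correlation profiles
#'
#' For every participant with at least \code{min_calls} rated calls, the
#' vector of within-individual Spearman correlations of each feature with
#' the provider rating. Profile similarity between two participants is the
#' Pearson correlation of their rho vectors (pairwise-complete); the mean
#' over all pairs summarizes how shared the feature-utility structure is
#' across people.
#'
#' @param table a \code{call_feature_table}.
#' @param min_calls minimum rated calls per qualifying participant
#'   (default 35).
#' @return list with \code{profiles} (matrix participants x features),
#'   \code{n_calls} (named vector), \code{pairwise_similarity} (matrix), and
#'   \code{mean_pairwise_similarity} (NA with fewer than two qualifiers).
#' @export
individual_profiles <- function(table, min_calls = 35L) {
  feat_cols <- setdiff(names(table),
                       c("participant_id", "call_time", "provider_rating"))
  parts <- split(as.data.frame(table), table$participant_id)
  keep <- vapply(parts, function(p) sum(is.finite(p$provider_rating)), 0L)
  parts <- parts[keep >= min_calls]
  if (!length(parts))
    return(list(profiles = NULL, n_calls = integer(0),
                pairwise_similarity = NULL,
                mean_pairwise_similarity = NA_real_))
  profiles <- t(vapply(parts, function(p) {
    vapply(feat_cols, function(cn)
      spearman(p[[cn]], p$provider_rating)$rho, 0)
  }, stats::setNames(numeric(length(feat_cols)), feat_cols)))
  np <- nrow(profiles)
  sim <- matrix(NA_real_, np, np, dimnames = list(rownames(profiles),
                                                  rownames(profiles)))
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      ok <- is.finite(profiles[i, ]) & is.finite(profiles[j, ])
      sim[i, j] <- sim[j, i] <- if (sum(ok) >= 3L)
        stats::cor(profiles[i, ok], profiles[j, ok]) else NA_real_
    }
  }
  mean_sim <- if (np >= 2L) mean(sim[upper.tri(sim)], na.rm = TRUE)
              else NA_real_
  list(profiles = profiles, n_calls = keep[keep >= min_calls],
       pairwise_similarity = sim, mean_pairwise_similarity = mean_sim)
}

# Fisher r-to-z comparison of two independent correlations.
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(!is.finite(c(r1, r2))) || n1 < 4 || n2 < 4) return(NA_real_)
  r1 <- clip(r1, -1 + 1e-12, 1 - 1e-12)
  r2 <- clip(r2, -1 + 1e-12, 1 - 1e-12)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

# Hotelling-Williams / Steiger t2 for comparing dependent correlations that
# share a variable; r12 is the correlation between the two non-shared
# variables. With disjoint chronological halves no such pairing exists, so
# r12 defaults to 0 (independence), which makes the test a conservative
# dependent-correlation analogue of the Fisher-z comparison.
williams_test <- function(r1, r2, n, r12 = 0) {
  if (any(!is.finite(c(r1, r2))) || n < 5) return(NA_real_)
  # r1^2 + r2^2 > 1 with r12 = 0 is outside the positive-definite region of
  # a correlation matrix; floor the determinant so extreme differences yield
  # an extreme statistic instead of an undefined one
  detR <- max(1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12, 1e-6)
  rbar <- (r1 + r2) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3
  if (denom <= 0) return(NA_real_)
  t2 <- (r1 - r2) * sqrt((n - 1) * (1 + r12) / denom)
  2 * stats::pt(-abs(t2), df = n - 3)
}

#' Temporal stability of feature-rating correlations within a participant
#'
#' Splits one participant's calls chronologically into halves, computes each
#' feature's feature-rating Spearman correlation in both halves, and tests
#' the difference per feature — by Fisher r-to-z for independent
#' correlations (default; the halves are disjoint) or by the
#' Hotelling-Williams dependent-correlation t2. The stable fraction is the
#' share of testable features with p >= alpha.
#'
#' @param rows feature-table rows for a single participant, time-sorted.
#' @param method \code{"fisher_z"} or \code{"williams"}.
#' @param min_half minimum calls required per half (default 10).
#' @param alpha stability significance level.
#' @return list with \code{per_feature} (data frame feature/rho_first/
#'   rho_second/p), \code{stable_fraction}, \code{n_first}, \code{n_second}.
#' @export
half_split_stability <- function(rows, method = c("fisher_z", "williams"),
                                 min_half = 10L, alpha = 0.05) {
  method <- match.arg(method)
  if (length(unique(rows$participant_id)) > 1L)
    stop("half_split_stability expects a single participant")
  rows <- rows[order(rows$call_time), , drop = FALSE]
  n <- nrow(rows)
  if (n < 2L * min_half)
    return(list(per_feature = NULL, stable_fraction = NA_real_,
                n_first = NA_integer_, n_second = NA_integer_))
  half <- n %/% 2L
  first <- rows[seq_len(half), , drop = FALSE]
  second <- rows[(half + 1L):n, , drop = FALSE]
  feat_cols <- setdiff(names(rows),
                       c("participant_id", "call_time", "provider_rating"))
  per <- lapply(feat_cols, function(cn) {
    s1 <- spearman(first[[cn]], first$provider_rating)
    s2 <- spearman(second[[cn]], second$provider_rating)
    p <- if (identical(s1$rho, s2$rho) && is.finite(s1$rho)) 1.0
         else if (method == "fisher_z") fisher_z_test(s1$rho, s1$n, s2$rho, s2$n)
         else williams_test(s1$rho, s2$rho, min(s1$n, s2$n))
    c(rho_first = s1$rho, rho_second = s2$rho, p = p)
  })
  df <- data.frame(feature = feat_cols, do.call(rbind, per),
                   stringsAsFactors = FALSE)
  testable <- is.finite(df$p)
  list(per_feature = df,
       stable_fraction = if (any(testable)) mean(df$p[testable] >= alpha)
                         else NA_real_,
       n_first = nrow(first), n_second = nrow(second))
}
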