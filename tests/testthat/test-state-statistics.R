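test_that("spearman matches the closed form, is symmetric, and monotone-invariant", {
  s <- spearman(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s$rho, -0.5)   # 1 - 6*6/(3*8)

  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)            # monotone identity
  expect_equal(spearman(c(5, 1, 3, 2), c(2, 8, 4, 6))$rho,
               spearman(c(2, 8, 4, 6), c(5, 1, 3, 2))$rho) # symmetry
  expect_equal(spearman(c(5, 1, 3, 2), exp(c(2, 8, 4, 6)))$rho,
               spearman(c(5, 1, 3, 2), c(2, 8, 4, 6))$rho) # monotone transform

  expect_true(is.na(spearman(1:5, rep(2, 5))$rho))         # constant input
  expect_true(is.na(spearman(c(1, 2), c(2, 1))$rho))       # too short
  # pairwise-complete handling
  expect_equal(spearman(c(1, 2, NA, 4), c(4, 3, 9, 1))$n, 3)

  # p-value agrees with the classical t approximation on untied data
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  s2 <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s2$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("population correlation report applies Bonferroni at alpha/n_features", {
  set.seed(11)
  n <- 40
  ratings <- sample(1:10, n, replace = TRUE)
  tbl <- data.frame(provider_rating = ratings,
                    exact = ratings,
                    noise = rnorm(n))
  rep <- population_feature_correlations(tbl)
  expect_equal(rep$bonferroni_threshold, 0.05 / 2)
  expect_equal(rep$report$rho[rep$report$feature == "exact"], 1)
  expect_true(rep$report$significant[rep$report$feature == "exact"])
  expect_equal(rep$report$feature[1], "exact")  # sorted by |rho|

  # 210 features at alpha 0.05 -> threshold 0.05/210
  tbl210 <- as.data.frame(matrix(rnorm(n * 210), n))
  names(tbl210) <- sprintf("f%03d", 1:210)
  tbl210$provider_rating <- ratings
  rep210 <- population_feature_correlations(tbl210)
  expect_equal(rep210$bonferroni_threshold, 0.05 / 210)
  # Bonferroni-significant set is a subset of the unadjusted p < alpha set
  r <- rep210$report
  expect_true(all(r$p[r$significant] < 0.05))

  expect_error(population_feature_correlations(
    data.frame(provider_rating = c(1, 2), f = c(1, 2))), "at least 3")
})

test_that("individual profiles separate shared from independent loadings", {
  # constructed: participants whose features track ratings with fixed signs
  make_part <- function(pid, signs, seed) {
    with_seed(seed, {
      state <- rnorm(40)
      feats <- lapply(seq_along(signs), function(j)
        signs[j] * state + rnorm(40, 0, 0.6))
      names(feats) <- sprintf("f%02d", seq_along(signs))
      feature_rows(pid, ratings = round(clip(5 + 2 * state, 1, 10)), feats)
    })
  }
  shared_signs <- rep(c(1, -1), 10)
  shared <- do.call(rbind, lapply(1:4, function(i)
    make_part(paste0("S", i), shared_signs, seed = 100 + i)))
  ps <- individual_profiles(shared, min_calls = 35)
  expect_gt(ps$mean_pairwise_similarity, 0.8)

  het <- do.call(rbind, lapply(1:6, function(i)
    make_part(paste0("H", i),
              with_seed(200 + i, sample(c(-1, 1), 20, replace = TRUE)),
              seed = 300 + i)))
  ph <- individual_profiles(het, min_calls = 35)
  expect_lt(abs(ph$mean_pairwise_similarity), 0.25)

  one <- individual_profiles(shared[shared$participant_id == "S1", ],
                             min_calls = 35)
  expect_true(is.na(one$mean_pairwise_similarity))

  # below-threshold participants are excluded
  small <- individual_profiles(shared, min_calls = 100)
  expect_true(is.na(small$mean_pairwise_similarity))
})

test_that("fisher-z half-split test matches its closed form and finds instability", {
  # closed form: r1=0.9 (n=50) vs r2=0 (n=50)
  z <- (atanh(0.9) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(fisher_z_test(0.9, 50, 0, 50), 2 * pnorm(-abs(z)))
  expect_lt(fisher_z_test(0.9, 50, 0, 50), 0.01)

  # identical halves -> all p = 1
  half <- feature_rows("A", ratings = rep(1:10, 2),
                       features = list(f1 = rep(seq(0.1, 1, 0.1), 2),
                                       f2 = rep(10:1, 2)))
  dup <- rbind(half, transform(half, call_time = call_time + 100))
  st <- half_split_stability(dup, min_half = 10)
  expect_true(all(st$per_feature$p == 1))
  expect_equal(st$stable_fraction, 1)

  # a feature whose coupling flips sign between halves is flagged
  # (moderate correlations ~0.65 keep both test variants well-defined)
  with_seed(5, {
    state <- rnorm(60)
    flip <- c(state[1:30], -state[31:60]) + rnorm(60, 0, 1.2)
    keep <- state + rnorm(60, 0, 1.2)
  })
  df <- feature_rows("A", ratings = round(clip(5 + 2 * state, 1, 10)),
                     features = list(flip = flip, keep = keep))
  st2 <- half_split_stability(df, min_half = 10)
  expect_lt(st2$per_feature$p[st2$per_feature$feature == "flip"], 0.05)
  expect_gt(st2$per_feature$p[st2$per_feature$feature == "keep"], 0.05)

  # williams variant behaves comparably on the flip case
  st3 <- half_split_stability(df, method = "williams", min_half = 10)
  expect_lt(st3$per_feature$p[st3$per_feature$feature == "flip"], 0.05)

  expect_true(is.na(half_split_stability(df[1:10, ],
                                         min_half = 10)$stable_fraction))
})
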