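test_that("latent states follow the configured AR(1) dynamics", {
  # degenerate: no dynamics, no noise -> constant at the participant mean
  p0 <- sim_params(ar_coefficient = 0, state_noise_sd = 0,
                   rating_noise_sd = 0, calls_per_participant = 20, seed = 1)
  tr <- simulate_latent_states(p0, 1)
  expect_equal(tr$states, rep(tr$mu, 20), tolerance = 1e-12)
  # with no rating noise, ratings are exactly the rounded clipped states
  expect_equal(tr$ratings, as.integer(round(clip(tr$states, 1, 10))))

  # AR(1) theory: lag-1 autocorrelation approx phi on a long series
  p9 <- sim_params(ar_coefficient = 0.9, state_noise_sd = 0.3,
                   state_mean_range = c(5.5, 5.5),
                   calls_per_participant = 10000, seed = 2)
  s <- simulate_latent_states(p9, 1)$states
  ac1 <- cor(s[-1], s[-length(s)])
  expect_lt(abs(ac1 - 0.9), 0.05)
})

test_that("transcripts encode state in affect usage and word count", {
  p <- sim_params(seed = 3)
  cats <- demo_cats()
  pct_at <- function(state, seed) {
    with_seed(seed, {
      txt <- replicate(8, generate_transcript(state, p,
                                              c(word = 1, affect = 1)))
      mean(sapply(txt, function(t)
        category_percentages(tokenize(t), cats)["posemo"]))
    })
  }
  expect_gt(pct_at(10, 31), pct_at(1, 32))

  # no slope, no noise -> fixed word count
  p0 <- sim_params(words_per_state_unit = 0, word_noise_sd = 0,
                   words_base = 50, seed = 4)
  txt <- with_seed(5, generate_transcript(7, p0, c(word = 1, affect = 1)))
  expect_equal(length(tokenize(txt)$tokens), 50)

  # zero affect slopes -> posemo percentage independent of state
  pn <- sim_params(pos_word_slope = 0, neg_word_slope = 0, seed = 6)
  with_seed(7, {
    states <- runif(150, 1, 10)
    pcts <- sapply(states, function(s)
      category_percentages(tokenize(generate_transcript(s, pn,
                                                        c(word = 1, affect = 1))),
                           cats)["posemo"])
  })
  expect_lt(abs(spearman(states, pcts)$rho), 0.15)
})

test_that("synthesized audio closes the loop with the acoustic extractor", {
  p <- sim_params(seed = 8)
  # state chosen so the F0 target is 180 Hz given f0_base_i
  au <- with_seed(9, synthesize_utterance_audio(5.5, p, c(f0 = 1, pause = 1),
                                                f0_base_i = 180))
  fs <- acoustic_feature_set(au)
  expect_lt(abs(fs[["f0_median"]] - 180), 4)

  # pause target 0.3 at the state midpoint
  expect_lt(abs(fs[["pause_fraction"]] - 0.30), 0.05)

  # short utterance with negligible pause budget has no pauses
  pq <- sim_params(pause_base = 0.02, pause_slope = 0, seed = 8)
  au2 <- with_seed(10, synthesize_utterance_audio(5.5, pq, c(f0 = 1, pause = 1),
                                                  f0_base_i = 150,
                                                  duration_s = 0.5))
  expect_equal(detect_pauses(au2)$pause_fraction, 0)
})

test_that("cohort simulation is reproducible from its seed", {
  p <- sim_params(n_participants = 2, calls_per_participant = 4, seed = 11)
  d1 <- tempfile("c1_"); d2 <- tempfile("c2_")
  simulate_cohort(p, d1)
  simulate_cohort(p, d2)
  m1 <- readLines(file.path(d1, "manifest.csv"))
  m2 <- readLines(file.path(d2, "manifest.csv"))
  expect_identical(gsub(d1, "", m1, fixed = TRUE),
                   gsub(d2, "", m2, fixed = TRUE))
  # audio is byte-identical too
  w1 <- readBin(file.path(d1, "audio", "P01_c001_q1.wav"), "raw", 1e6)
  w2 <- readBin(file.path(d2, "audio", "P01_c001_q1.wav"), "raw", 1e6)
  expect_identical(w1, w2)

  co <- read_cohort(file.path(d1, "manifest.csv"))
  expect_equal(unname(cohort_call_counts(co)), c(4L, 4L))
  expect_true(all(co$diagnoses %in% c("bipolar", "mdd", "schizophrenia",
                                      "schizoaffective")))
})

test_that("window averaging strengthens feature-rating correlation under noise", {
  # property over replicates: block-averaging both sides of a noisy
  # state-feature pair raises the observed correlation for a persistent state
  p <- sim_params(ar_coefficient = 0.85, state_noise_sd = 0.8,
                  state_mean_range = c(5, 6), calls_per_participant = 160)
  wins <- 0L
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    pr <- p; pr$seed <- 500 + r
    tr <- simulate_latent_states(pr, 1)
    feat <- with_seed(derive_seed(pr$seed, 99),
                      tr$states + rnorm(length(tr$states), 0, 2))
    df <- feature_rows("A", ratings = tr$ratings, features = list(f = feat))
    raw <- spearman(df$f, df$provider_rating)$rho
    w <- window_average(df, 8)
    avg <- spearman(w$f, w$mean_rating)$rho
    if (!is.na(avg) && !is.na(raw) && avg > raw) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
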