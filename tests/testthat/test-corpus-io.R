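test_that("WAV round-trip preserves samples, rate, and full-scale rescaling", {
  x <- sin(2 * pi * 220 * (0:7999) / 8000)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, sample_rate = 8000)
  a <- read_wav(path)
  expect_s3_class(a, "audio_segment")
  expect_length(a$samples, 8000)
  expect_equal(a$sample_rate, 8000)
  expect_lt(max(abs(a$samples - round(x * 32767) / 32768)), 1e-9)

  # full-scale 16-bit value 32767 maps to 32767/32768
  write_wav(rep(1, 100), path)
  expect_equal(read_wav(path)$samples[1], 32767 / 32768, tolerance = 1e-12)

  expect_error(read_wav(tempfile()), "not found")
  bad <- tempfile(fileext = ".wav")
  writeLines("not audio", bad)
  expect_error(read_wav(bad), "RIFF")
})

test_that("stereo WAV input is averaged to mono", {
  # hand-build a 2-channel 16-bit file with identical channels
  x <- as.integer(round(sin(2 * pi * 100 * (0:799) / 8000) * 10000))
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  interleaved <- as.integer(rbind(x, x))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(interleaved)), con, size = 4,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  for (v in c(1L, 2L)) writeBin(v, con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  for (v in c(4L, 16L)) writeBin(v, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(interleaved)), con, size = 4,
           endian = "little")
  writeBin(interleaved, con, size = 2, endian = "little")
  close(con)
  a <- read_wav(path)
  expect_length(a$samples, 800)
  expect_equal(a$samples, x / 32768, tolerance = 1e-12)
})

test_that("norm lexicon reading folds case, warns on duplicates, validates schema", {
  lex <- demo_norms()
  expect_gt(length(lex$words), 200)
  df <- data.frame(word = c("Happy", "happy", "blue"))
  for (nm in setdiff(colnames(lex$norms), "word")) df[[nm]] <- c(0.1, 0.9, 0.4)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(l2 <- read_norm_lexicon(path), "duplicate")
  expect_equal(unname(l2$norms["happy", "valence"]), 0.9)  # last wins
  expect_true("happy" %in% l2$words)

  df$valence <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_norm_lexicon(path), "valence")
})

test_that("category lexicon supports wildcards in both dic and yaml formats", {
  lex <- make_category_lexicon(list(posemo = c("happy", "joy*"),
                                    negemo = "sad"))
  expect_true(category_match("joyful", lex$posemo))
  expect_true(category_match("joy", lex$posemo))
  expect_false(category_match("happy", lex$negemo))
  expect_error(make_category_lexicon(list(posemo = "x", bad = list())),
               "empty category")

  dic <- demo_cats()
  expect_length(dic, 15)
  expect_true(category_match("gleesomething", dic$posemo))
})

test_that("cohort manifest reading groups prompts into time-sorted calls", {
  df <- data.frame(
    participant_id = "P1",
    call_time = rep(c(200, 100), each = 3),   # out of order on disk
    prompt_index = rep(1:3, 2),
    transcript = paste("call text", 1:6),
    audio_path = NA, provider_rating = rep(c(7, 4), each = 3),
    diagnosis = "mdd", rejected = FALSE)
  co <- cohort_from_manifest(df)
  expect_length(co$participants, 1)
  calls <- co$participants$P1
  expect_length(calls, 2)
  expect_equal(vapply(calls, `[[`, 0, "call_time"), c(100, 200))
  expect_equal(calls[[1]]$provider_rating, 4)
  expect_equal(vapply(calls[[1]]$responses, `[[`, 0L, "prompt_index"), 1:3)

  # missing required column
  expect_error(cohort_from_manifest(df[setdiff(names(df), "provider_rating")]),
               "provider_rating")
  # a call with != 3 prompts is malformed, and the error names the call
  expect_error(cohort_from_manifest(df[-1, ]), "P1")
})

test_that("cohort write/read round-trips calls, ratings, and diagnoses", {
  co <- tiny_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path, audio_root = dirname(attr(co, "manifest_path")))
  expect_equal(names(co2$participants), names(co$participants))
  expect_equal(co2$diagnoses, co$diagnoses)
  for (pid in names(co$participants)) {
    expect_equal(vapply(co2$participants[[pid]], `[[`, 0, "call_time"),
                 vapply(co$participants[[pid]], `[[`, 0, "call_time"))
    expect_equal(vapply(co2$participants[[pid]], `[[`, 0, "provider_rating"),
                 vapply(co$participants[[pid]], `[[`, 0, "provider_rating"))
    expect_equal(co2$participants[[pid]][[1]]$responses[[2]]$transcript,
                 co$participants[[pid]][[1]]$responses[[2]]$transcript)
  }
})

test_that("feature table writes 3 metadata + 210 feature columns and round-trips", {
  feats <- tiny_features()
  expect_equal(ncol(feats), 213)
  path <- tempfile(fileext = ".csv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(ncol(back), 213)
  fc <- call_feature_names()
  expect_equal(as.matrix(back[fc]), as.matrix(as.data.frame(feats)[fc]),
               tolerance = 1e-9)

  # inconsistent manifests across rows are rejected
  r1 <- feats[1, ]; attr(r1, "manifest") <- default_feature_manifest()
  r2 <- feats[2, ]; attr(r2, "manifest") <- rev(default_feature_manifest())
  expect_error(write_feature_table(list(r1, r2), path), "manifest")
})
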