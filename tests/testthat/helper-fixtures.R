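# Shared fixtures, built once per test run and memoized.

# internal helpers exercised directly in tests
category_match <- speechstate:::category_match
phrase_vector <- speechstate:::phrase_vector
fisher_z_test <- speechstate:::fisher_z_test
williams_test <- speechstate:::williams_test
derive_seed <- speechstate:::derive_seed
with_seed <- speechstate:::with_seed
clip <- speechstate:::clip

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

demo_norms <- function() fixture("norms", function()
  read_norm_lexicon(system.file("extdata", "demo_norms.csv",
                                package = "speechstate")))

demo_cats <- function() fixture("cats", function()
  read_category_lexicon(system.file("extdata", "demo_categories.dic",
                                    package = "speechstate")))

# a small fully-synthesized cohort with extracted features (3 x 12 calls)
tiny_cohort <- function() fixture("tiny_cohort", function()
  simulate_cohort(sim_params(n_participants = 3, calls_per_participant = 12,
                             seed = 42)))

tiny_features <- function() fixture("tiny_features", function()
  extract_cohort_features(tiny_cohort()))

# pure tone helper
tone_segment <- function(freq, dur = 1, sr = 8000, amp = 0.5)
  audio_segment(amp * sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)

# a tiny norm-lexicon from literal values
make_norm_lexicon <- function(words, valence) {
  df <- data.frame(word = words)
  for (nm in c("arousal", "valence", "positivity", "negativity", "objectivity",
               "concreteness", "age_of_acquisition", "pronounceability",
               "gender_ladenness")) df[[nm]] <- 0.5
  df$valence <- valence
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  read_norm_lexicon(path)
}

# write a minimal category YAML lexicon
make_category_lexicon <- function(cats) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cats, path)
  read_category_lexicon(path)
}

# manifest data frame -> cohort
cohort_from_manifest <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  read_cohort(path)
}

# one-participant feature table with explicit feature columns
feature_rows <- function(pid, ratings, features) {
  df <- data.frame(participant_id = pid, call_time = seq_along(ratings),
                   provider_rating = ratings, stringsAsFactors = FALSE)
  for (nm in names(features)) df[[nm]] <- features[[nm]]
  df
}
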