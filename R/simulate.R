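#' Simulation parameters for the synthetic longitudinal speech cohort
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a latent clinical state per participant following an AR(1) process on the
#' 1-10 scale, provider ratings as noisy rounded states, transcripts whose
#' word count and positive/negative word usage move with state, and
#' synthesized audio whose fundamental frequency and pause fraction move
#' with state. In \code{heterogeneous} loading mode each participant gets an
#' independent random sign/weight over the four state-driven channels
#' (word count, affect, F0, pauses), reproducing near-zero cross-participant
#' profile similarity; \code{shared} mode uses one common pattern.
#'
#' @param n_participants,calls_per_participant cohort dimensions.
#' @param state_mean_range range the participant mean state is drawn from.
#' @param ar_coefficient AR(1) coefficient of the latent state, in [0, 1).
#' @param state_noise_sd innovation s.d. of the latent state.
#' @param rating_noise_sd s.d. of provider-rating noise before rounding.
#' @param loading_mode \code{"heterogeneous"} or \code{"shared"}.
#' @param loading_strength global multiplier on the channel loadings.
#' @param words_base,words_per_state_unit,word_noise_sd word-count model:
#'   \code{N = max(5, round(words_base + words_per_state_unit * w * (state - 5.5)
#'   + noise))}.
#' @param base_affect_p,pos_word_slope,neg_word_slope affect-word model:
#'   per-word positive probability rises (and negative falls) linearly in
#'   state, clipped to [0.01, 0.99].
#' @param f0_base,f0_per_state_unit,f0_participant_sd audio F0 model (Hz);
#'   each participant's baseline F0 is jittered by
#'   \code{f0_participant_sd}.
#' @param pause_base,pause_slope pause-fraction model, clipped to
#'   [0.05, 0.7].
#' @param audio_duration_s duration of each synthesized response.
#' @param sample_rate audio sample rate in Hz (telephone-grade default).
#' @param seed master RNG seed; all per-participant and per-call substreams
#'   derive from it deterministically.
#' @return a list of class \code{sim_params}.
#' @export
sim_params <- function(n_participants = 12L, calls_per_participant = 60L,
                       state_mean_range = c(3.5, 7.5), ar_coefficient = 0.8,
                       state_noise_sd = 0.7, rating_noise_sd = 0.7,
                       loading_mode = c("heterogeneous", "shared"),
                       loading_strength = 1,
                       words_base = 118, words_per_state_unit = 10,
                       word_noise_sd = 15,
                       base_affect_p = 0.18, pos_word_slope = 0.05,
                       neg_word_slope = 0.05,
                       f0_base = 140, f0_per_state_unit = 4,
                       f0_participant_sd = 8,
                       pause_base = 0.30, pause_slope = 0.03,
                       audio_duration_s = 2.5, sample_rate = 8000,
                       seed = 0L) {
  loading_mode <- match.arg(loading_mode)
  stopifnot(ar_coefficient >= 0, ar_coefficient < 1, state_noise_sd >= 0,
            rating_noise_sd >= 0, audio_duration_s >= 0.5)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate one participant's latent state trajectory and ratings
#'
#' AR(1) around a participant mean drawn uniformly from
#' \code{state_mean_range}, clipped to [1, 10]; the provider rating is the
#' state plus Gaussian noise, rounded and clipped to the integer 1-10 scale.
#'
#' @param params a \code{\link{sim_params}}.
#' @param participant_index 1-based participant index (fixes the substream).
#' @return list with \code{participant_id}, \code{mu}, \code{states},
#'   \code{ratings}.
#' @export
simulate_latent_states <- function(params, participant_index) {
  with_seed(derive_seed(params$seed, participant_index * 7L + 1L), {
    mu <- stats::runif(1, params$state_mean_range[1], params$state_mean_range[2])
    n <- params$calls_per_participant
    s <- numeric(n)
    stat_sd <- if (params$ar_coefficient < 1)
      params$state_noise_sd / sqrt(max(1e-12, 1 - params$ar_coefficient^2))
      else params$state_noise_sd
    prev <- mu + stats::rnorm(1, 0, stat_sd)
    for (t in seq_len(n)) {
      prev <- mu + params$ar_coefficient * (prev - mu) +
        stats::rnorm(1, 0, params$state_noise_sd)
      s[t] <- clip(prev, 1, 10)
    }
    ratings <- as.integer(round(clip(s + stats::rnorm(n, 0, params$rating_noise_sd),
                                     1, 10)))
    list(participant_id = sprintf("P%02d", participant_index), mu = mu,
         states = s, ratings = ratings)
  })
}

# Per-participant channel loadings (word count, affect, F0, pauses).
participant_loadings <- function(params, participant_index) {
  if (params$loading_mode == "shared") {
    w <- c(word = 1, affect = 1, f0 = 1, pause = 1)
  } else {
    w <- with_seed(derive_seed(params$seed, participant_index * 7L + 2L), {
      sgn <- sample(c(-1, 1), 4, replace = TRUE)
      mag <- stats::runif(4, 0.5, 1)
      stats::setNames(sgn * mag, c("word", "affect", "f0", "pause"))
    })
  }
  w * params$loading_strength
}

demo_word_pools <- function() {
  tags <- utils::read.csv(system.file("extdata", "demo_word_tags.csv",
                                      package = "speechstate"),
                          stringsAsFactors = FALSE)
  list(pos = tags$word[tags$tag == "posemo"],
       neg = tags$word[tags$tag == "negemo"],
       neutral = tags$word[!(tags$tag %in% c("posemo", "negemo"))])
}

#' Generate a state-driven synthetic transcript
#'
#' Word count rises (or falls, per the participant loading) with state;
#' each word is positive with probability increasing, and negative with
#' probability decreasing, linearly in state. Words come from the bundled
#' demo lexicon; a period is inserted roughly every 12 words so the text has
#' sentences. The output is a statistical word salad sufficient for lexical
#' features, not fluent language.
#'
#' @param state latent state value.
#' @param params a \code{\link{sim_params}}.
#' @param weights channel-loading vector from the participant.
#' @param pools word pools (from the bundled tag table by default).
#' @return character scalar.
#' @export
generate_transcript <- function(state, params, weights = c(word = 1, affect = 1),
                                pools = demo_word_pools()) {
  dev <- state - 5.5
  n <- max(5L, round(params$words_base +
                     params$words_per_state_unit * weights[["word"]] * dev +
                     stats::rnorm(1, 0, params$word_noise_sd)))
  p_pos <- clip(params$base_affect_p +
                params$pos_word_slope * weights[["affect"]] * dev, 0.01, 0.99)
  p_neg <- clip(params$base_affect_p -
                params$neg_word_slope * weights[["affect"]] * dev, 0.01, 0.99)
  scale <- max(1, p_pos + p_neg + 0.01)
  p_pos <- p_pos / scale; p_neg <- p_neg / scale
  kind <- sample(c("pos", "neg", "neutral"), n, replace = TRUE,
                 prob = c(p_pos, p_neg, max(0.01, 1 - p_pos - p_neg)))
  words <- character(n)
  for (k in c("pos", "neg", "neutral")) {
    idx <- kind == k
    if (any(idx)) words[idx] <- sample(pools[[k]], sum(idx), replace = TRUE)
  }
  sent_len <- pmax(6L, round(stats::rnorm(ceiling(n / 12) + 1L, 12, 2)))
  breaks <- cumsum(sent_len)
  breaks <- breaks[breaks < n]
  words[breaks] <- paste0(words[breaks], ".")
  paste0(paste(words, collapse = " "), ".")
}

# Two-pole resonator filter.
resonate <- function(x, freq, bw, sr) {
  r <- exp(-pi * bw / sr)
  as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * freq / sr), -r^2),
                           method = "recursive"))
}

#' Synthesize a state-driven utterance
#'
#' Speech segments are an impulse train at the target F0 passed through two
#' vocal-tract-like resonators (700 and 1200 Hz) plus low-level noise;
#' silence gaps are inserted between segments so the pause fraction tracks
#' the state-driven target. Provides exact ground truth for the acoustic
#' extractor.
#'
#' @param state latent state value.
#' @param params a \code{\link{sim_params}}.
#' @param weights channel loadings (uses \code{f0} and \code{pause}).
#' @param f0_base_i participant baseline F0 (defaults to the population
#'   base).
#' @param duration_s total duration in seconds.
#' @return an \code{\link{audio_segment}}.
#' @export
synthesize_utterance_audio <- function(state, params,
                                       weights = c(f0 = 1, pause = 1),
                                       f0_base_i = NULL,
                                       duration_s = NULL) {
  sr <- params$sample_rate
  dur <- duration_s %||% params$audio_duration_s
  dev <- state - 5.5
  f0 <- clip((f0_base_i %||% params$f0_base) +
             params$f0_per_state_unit * weights[["f0"]] * dev, 80, 400)
  pause_target <- clip(params$pause_base -
                       params$pause_slope * weights[["pause"]] * dev,
                       0.05, 0.7)
  pause_time <- pause_target * dur
  speech_time <- dur - pause_time
  n_pauses <- if (pause_time >= 0.4) 2L else if (pause_time >= 0.18) 1L else 0L
  pause_len <- if (n_pauses) pause_time / n_pauses else 0
  n_seg <- n_pauses + 1L
  seg_len <- speech_time / n_seg
  make_speech <- function(len_s) {
    n <- round(len_s * sr)
    x <- numeric(n)
    x[unique(pmin(n, round(seq(1, n, by = sr / f0))))] <- 1
    y <- resonate(resonate(x, 700, 90, sr), 1200, 110, sr)
    y <- y / max(abs(y), 1e-9) * 0.4
    y + stats::rnorm(n, 0, 0.004)
  }
  pieces <- list()
  for (i in seq_len(n_seg)) {
    pieces[[length(pieces) + 1L]] <- make_speech(seg_len)
    if (i <= n_pauses)
      pieces[[length(pieces) + 1L]] <- numeric(round(pause_len * sr))
  }
  audio_segment(clip(unlist(pieces), -1, 1), sr)
}

#' Simulate a full on-disk synthetic cohort
#'
#' Writes a corpus_io-readable cohort (manifest.csv with inline transcripts,
#' WAV audio per response) driven by per-participant latent states.
#' Diagnoses are assigned uniformly at random from four labels, so diagnosis
#' carries no signal. Everything is reproducible from \code{params$seed}.
#'
#' @param params a \code{\link{sim_params}}.
#' @param dir output directory (created; defaults to a fresh tempdir
#'   subdirectory).
#' @param write_audio set FALSE to skip WAV synthesis (acoustic features
#'   will be missing downstream); useful for text-only experiments.
#' @return the cohort read back via \code{\link{read_cohort}}, with the
#'   manifest path in attribute \code{"manifest_path"} and the true latent
#'   states in attribute \code{"latent_states"}.
#' @export
simulate_cohort <- function(params = sim_params(),
                            dir = tempfile("cohort_"), write_audio = TRUE) {
  dir.create(file.path(dir, "audio"), showWarnings = FALSE, recursive = TRUE)
  pools <- demo_word_pools()
  dx_labels <- c("bipolar", "mdd", "schizophrenia", "schizoaffective")
  rows <- list()
  latent <- list()
  t0 <- as.numeric(as.POSIXct("2014-01-06", tz = "UTC"))
  for (i in seq_len(params$n_participants)) {
    traj <- simulate_latent_states(params, i)
    w <- participant_loadings(params, i)
    latent[[traj$participant_id]] <- traj
    pid <- traj$participant_id
    f0_base_i <- with_seed(derive_seed(params$seed, i * 7L + 3L),
                           stats::rnorm(1, params$f0_base,
                                        params$f0_participant_sd))
    dx <- with_seed(derive_seed(params$seed, i * 7L + 4L),
                    sample(dx_labels, 1))
    for (t in seq_len(params$calls_per_participant)) {
      st <- traj$states[t]
      call_time <- t0 + (i - 1) * 3600 + (t - 1) * 3.5 * 86400
      for (q in 1:3) {
        rec <- with_seed(derive_seed(params$seed, i * 1000003L + t * 101L + q), {
          txt <- generate_transcript(st, params, w, pools)
          ap <- NA_character_
          if (write_audio) {
            ap <- file.path("audio", sprintf("%s_c%03d_q%d.wav", pid, t, q))
            write_wav(synthesize_utterance_audio(st, params, w, f0_base_i),
                      file.path(dir, ap))
          }
          list(txt = txt, ap = ap)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, call_time = call_time, prompt_index = q,
          transcript = rec$txt, audio_path = rec$ap,
          provider_rating = traj$ratings[t], diagnosis = dx,
          rejected = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  cohort <- read_cohort(manifest_path, audio_root = dir)
  attr(cohort, "manifest_path") <- manifest_path
  attr(cohort, "latent_states") <- latent
  cohort
}
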