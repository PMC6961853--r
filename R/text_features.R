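#' Tokenize a transcript
#'
#' Splits on whitespace, strips surrounding punctuation, lowercases, and
#' records sentence boundaries at \code{. ! ?}. Spontaneous-speech
#' transcripts often lack punctuation; in that case the whole response is one
#' sentence, or — when \code{pseudo_sentence_len} is set — fixed-length
#' pseudo-sentences are used so that sentence-normalized formulas stay
#' meaningful.
#'
#' @param text character scalar (may be empty).
#' @param pseudo_sentence_len optional integer; when the text has no sentence
#'   punctuation, break it into pseudo-sentences of this many words.
#' @return a list of class \code{token_sequence} with \code{tokens}
#'   (character vector) and \code{sentences} (list of token-index ranges).
#' @export
tokenize <- function(text, pseudo_sentence_len = NULL) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text)))
    return(structure(list(tokens = character(0), sentences = list()),
                     class = "token_sequence"))
  text <- tolower(text)
  has_punct <- grepl("[.!?]", text)
  chunks <- if (has_punct) {
    s <- strsplit(text, "[.!?]+")[[1]]
    s[nzchar(trimws(s))]
  } else text
  tok_one <- function(chunk) {
    raw <- strsplit(trimws(chunk), "\\s+")[[1]]
    raw <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", raw)
    raw[nzchar(raw)]
  }
  sent_tokens <- lapply(chunks, tok_one)
  sent_tokens <- sent_tokens[lengths(sent_tokens) > 0]
  tokens <- unlist(sent_tokens, use.names = FALSE)
  if (is.null(tokens)) tokens <- character(0)
  if (!has_punct && !is.null(pseudo_sentence_len) && length(tokens)) {
    idx <- split(seq_along(tokens),
                 (seq_along(tokens) - 1L) %/% pseudo_sentence_len)
    sentences <- lapply(idx, range)
  } else {
    ends <- cumsum(lengths(sent_tokens))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    sentences <- Map(c, starts, ends)
  }
  structure(list(tokens = tokens, sentences = unname(sentences)),
            class = "token_sequence")
}

#' Heuristic syllable count
#'
#' Counts maximal vowel-letter groups (\code{aeiouy}), subtracts a silent
#' trailing \code{e} (when it forms its own group and the count stays
#' positive), with a minimum of one. A deterministic, dictionary-free
#' approximation adequate for readability indices.
#'
#' @param word character vector of lowercase words.
#' @return integer vector of syllable counts.
#' @export
count_syllables <- function(word) {
  word <- tolower(word)
  groups <- vapply(gregexpr("[aeiouy]+", word), function(m)
    if (m[1] == -1L) 0L else length(m), 0L)
  silent_e <- grepl("[^aeiouy]e$", word) & groups > 1L
  pmax(1L, groups - as.integer(silent_e))
}

#' Word-category percentages
#'
#' For each dictionary category, 100 times the fraction of tokens matching
#' that category's literal words or stem wildcards. An empty token list gives
#' 0 for every category.
#'
#' @param tokens a \code{token_sequence} or character vector.
#' @param lex a \code{category_lexicon}.
#' @return named numeric vector of percentages in \code{[0, 100]}.
#' @export
category_percentages <- function(tokens, lex) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  n <- length(tokens)
  vapply(lex, function(patterns) {
    if (n == 0L) return(0)
    100 * sum(category_match(tokens, patterns)) / n
  }, 0)
}

#' Norm functionals over in-vocabulary tokens
#'
#' For each of the nine psycholinguistic norms, the mean, min, max and
#' (population) standard deviation over the norm values of tokens found in
#' the lexicon. With no in-vocabulary token all functionals are missing;
#' with one token the standard deviation is 0.
#'
#' @param tokens a \code{token_sequence} or character vector.
#' @param lex a \code{norm_lexicon}.
#' @return list with \code{functionals} (named vector of 36 values, names
#'   \code{norm_<name>_<mean|min|max|std>}) and \code{coverage} (fraction of
#'   tokens in vocabulary).
#' @export
norm_functionals <- function(tokens, lex) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  nms <- norm_names()
  out_names <- as.vector(t(outer(nms, c("mean", "min", "max", "std"),
                                 function(a, b) paste0("norm_", a, "_", b))))
  out <- stats::setNames(rep(NA_real_, length(out_names)), out_names)
  idx <- match(tokens, lex$words)
  hit <- which(!is.na(idx))
  coverage <- if (length(tokens)) length(hit) / length(tokens) else 0
  if (length(hit) >= 1L) {
    vals <- lex$norms[idx[hit], , drop = FALSE]
    for (nm in nms) {
      v <- vals[, nm]
      out[paste0("norm_", nm, "_mean")] <- mean(v)
      out[paste0("norm_", nm, "_min")] <- min(v)
      out[paste0("norm_", nm, "_max")] <- max(v)
      out[paste0("norm_", nm, "_std")] <- pop_sd(v)
    }
  }
  list(functionals = out, coverage = coverage)
}

#' Readability and lexical-complexity features
#'
#' Classic sentence/word/syllable-based indices: Flesch reading ease,
#' Flesch-Kincaid grade, SMOG, Automated Readability Index and Coleman-Liau,
#' plus the difficult-word count, total word count, and mean syllables per
#' word. "Difficult" defaults to words of more than six syllables
#' (\code{difficult_min_syllables = 7}); the conventional polysyllable rule
#' (at least three) is available via \code{difficult_min_syllables = 3}.
#'
#' @param tokens a \code{token_sequence}.
#' @param difficult_min_syllables minimum syllable count for a word to count
#'   as difficult.
#' @return named numeric vector of the 8 complexity features (all missing
#'   for an empty response).
#' @export
readability <- function(tokens, difficult_min_syllables = 7L) {
  nm <- c("flesch_reading_ease", "fk_grade", "smog", "ari", "coleman_liau",
          "difficult_word_count", "word_count", "mean_syllables_per_word")
  out <- stats::setNames(rep(NA_real_, 8L), nm)
  tk <- tokens$tokens
  W <- length(tk)
  if (W == 0L) return(out)
  S <- max(1L, length(tokens$sentences))
  syl <- count_syllables(tk)
  Y <- sum(syl)
  C <- sum(nchar(gsub("[^a-z]", "", tk)))
  P <- sum(syl >= 3L)
  out["flesch_reading_ease"] <- 206.835 - 1.015 * (W / S) - 84.6 * (Y / W)
  out["fk_grade"] <- 0.39 * (W / S) + 11.8 * (Y / W) - 15.59
  out["smog"] <- 1.0430 * sqrt(30 * P / S) + 3.1291
  out["ari"] <- 4.71 * (C / W) + 0.5 * (W / S) - 21.43
  out["coleman_liau"] <- 0.0588 * (100 * C / W) - 0.296 * (100 * S / W) - 15.8
  out["difficult_word_count"] <- sum(syl >= difficult_min_syllables)
  out["word_count"] <- W
  out["mean_syllables_per_word"] <- Y / W
  out
}
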