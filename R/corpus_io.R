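#' Audio segment container
#'
#' Holds a mono waveform with samples in \code{[-1, 1]} and its sample rate.
#' Telephone-grade speech (8 kHz, 16-bit) is the package default, but any
#' PCM rate is accepted.
#'
#' @param samples numeric vector of samples in \code{[-1, 1]}.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class \code{audio_segment}.
#' @export
audio_segment <- function(samples, sample_rate = 8000) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_segment")
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for integer PCM (8/16/32-bit) and 32-bit float
#' data. Multichannel audio is averaged to mono; integer samples are rescaled
#' to \code{[-1, 1]} by the full-scale value \code{2^(bits-1)}.
#'
#' @param path path to a WAV file.
#' @return an \code{\link{audio_segment}}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0)
    stop("empty or malformed WAV file: ", path)
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$format == 1 && fmt$bits == 8) {
    x <- (readBin(data_raw, "integer", n, size = 1, signed = FALSE,
                  endian = "little") - 128) / 128
  } else if (fmt$format == 1 && fmt$bits %in% c(16, 32)) {
    x <- readBin(data_raw, "integer", n, size = bytes, signed = TRUE,
                 endian = "little") / 2^(fmt$bits - 1)
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits,
         " bit): ", path)
  }
  if (fmt$channels > 1) {
    n_frames <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0) stop("empty WAV file: ", path)
  audio_segment(x, fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param audio an \code{\link{audio_segment}} or numeric vector.
#' @param path output path.
#' @param sample_rate used when \code{audio} is a bare numeric vector.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(audio, path, sample_rate = 8000) {
  if (inherits(audio, "audio_segment")) {
    x <- audio$samples; sr <- audio$sample_rate
  } else {
    x <- as.numeric(audio); sr <- sample_rate
  }
  pcm <- as.integer(round(clip(x, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

norm_names <- function() {
  c("arousal", "valence", "positivity", "negativity", "objectivity",
    "concreteness", "age_of_acquisition", "pronounceability",
    "gender_ladenness")
}

#' Read a word-norm lexicon
#'
#' CSV with a \code{word} column plus the nine psycholinguistic norms
#' (arousal, valence, positivity, negativity, objectivity, concreteness,
#' age_of_acquisition, pronounceability, gender_ladenness). Lookup is
#' case-insensitive; duplicate words keep the last entry with a warning.
#'
#' @param path path to the CSV file.
#' @return an object of class \code{norm_lexicon}.
#' @export
read_norm_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("word", norm_names())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("norm lexicon is missing required column(s): ",
         paste(missing, collapse = ", "))
  words <- tolower(trimws(df$word))
  if (anyDuplicated(words)) {
    warning("duplicate words in norm lexicon; keeping last occurrence")
    keep <- !duplicated(words, fromLast = TRUE)
    df <- df[keep, , drop = FALSE]
    words <- words[keep]
  }
  m <- as.matrix(df[, norm_names()])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite norm values in lexicon")
  rownames(m) <- words
  structure(list(words = words, norms = m), class = "norm_lexicon")
}

#' Read a word-category lexicon
#'
#' Supports the classic \code{\%}-delimited dictionary layout (header block
#' mapping numeric ids to category names, then \code{word<TAB>id...} lines;
#' a trailing \code{*} on a word denotes a prefix wildcard) and a simpler
#' YAML layout (\code{category: [word, ...]}).
#'
#' @param path path to a \code{.dic} or \code{.yaml}/\code{.yml} file.
#' @return an object of class \code{category_lexicon}: a named list of
#'   category pattern sets, each with \code{$literal} and \code{$stem}.
#' @export
read_category_lexicon <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (!length(raw)) stop("category lexicon has no categories")
    cats <- lapply(raw, function(w) tolower(as.character(unlist(w))))
    names(cats) <- names(raw)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    pct <- which(lines == "%")
    if (length(pct) < 2) stop("malformed category dictionary (no % header): ", path)
    header <- lines[(pct[1] + 1):(pct[2] - 1)]
    body <- if (pct[2] < length(lines)) lines[(pct[2] + 1):length(lines)] else character(0)
    hp <- strsplit(header, "\t+|\\s{2,}| ")
    ids <- vapply(hp, `[`, "", 1)
    cat_names <- vapply(hp, function(p) p[length(p)], "")
    id_map <- stats::setNames(cat_names, ids)
    cats <- stats::setNames(vector("list", length(cat_names)), cat_names)
    cats <- lapply(cats, function(x) character(0))
    for (ln in body) {
      parts <- strsplit(ln, "\t+|\\s+")[[1]]
      word <- tolower(parts[1])
      for (id in parts[-1]) {
        nm <- id_map[[id]]
        if (is.null(nm)) stop("unknown category id '", id, "' in: ", ln)
        cats[[nm]] <- c(cats[[nm]], word)
      }
    }
  }
  empty <- names(cats)[lengths(cats) == 0]
  if (length(empty))
    stop("empty category in lexicon: ", paste(empty, collapse = ", "))
  if (anyDuplicated(names(cats))) stop("duplicate category names in lexicon")
  compiled <- lapply(cats, function(ws) {
    is_stem <- grepl("\\*$", ws)
    list(literal = unique(ws[!is_stem]),
         stem = unique(sub("\\*$", "", ws[is_stem])))
  })
  structure(compiled, class = "category_lexicon")
}

#' Test tokens against one category's patterns
#' @param tokens character vector of lowercased tokens.
#' @param patterns one element of a \code{category_lexicon}.
#' @return logical vector, one entry per token.
#' @keywords internal
category_match <- function(tokens, patterns) {
  hit <- tokens %in% patterns$literal
  for (stem in patterns$stem) hit <- hit | startsWith(tokens, stem)
  hit
}

parse_call_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!any(is.na(num))) return(num)
  t <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d"))
  if (any(is.na(t))) stop("unparseable call_time value(s): ",
                          paste(utils::head(x[is.na(t)], 3), collapse = ", "))
  as.numeric(t)
}

#' Read a cohort manifest
#'
#' The manifest is one row per (call, prompt): a CSV or JSON-lines table with
#' columns \code{participant_id}, \code{call_time}, \code{prompt_index},
#' \code{transcript} (or \code{transcript_path}), \code{audio_path},
#' \code{provider_rating}, and optionally \code{diagnosis} and
#' \code{rejected}. Rows sharing (participant_id, call_time) merge into one
#' call of exactly three prompts; calls are returned sorted by time within
#' participant.
#'
#' @param manifest_path path to the manifest file.
#' @param audio_root optional directory that relative \code{audio_path}
#'   values are resolved against (defaults to the manifest's directory).
#' @param assessments optional data frame with columns
#'   \code{participant_id}, \code{date}, \code{scale_name}, \code{score}.
#' @return an object of class \code{speech_cohort}.
#' @export
read_cohort <- function(manifest_path, audio_root = NULL, assessments = NULL) {
  ext <- tolower(tools::file_ext(manifest_path))
  if (ext %in% c("jsonl", "ndjson", "json")) {
    lines <- readLines(manifest_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    df <- do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  }
  required <- c("participant_id", "call_time", "prompt_index", "audio_path",
                "provider_rating")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!("transcript" %in% names(df)) && !("transcript_path" %in% names(df)))
    stop("cohort manifest is missing required column(s): transcript (or transcript_path)")
  if (is.null(audio_root)) audio_root <- dirname(manifest_path)
  if (!("rejected" %in% names(df))) df$rejected <- FALSE
  df$rejected <- as.logical(df$rejected) %in% TRUE
  if (!("diagnosis" %in% names(df))) df$diagnosis <- NA_character_
  if (!("transcript" %in% names(df))) df$transcript <- NA_character_
  if ("transcript_path" %in% names(df)) {
    need <- is.na(df$transcript) & !is.na(df$transcript_path)
    df$transcript[need] <- vapply(df$transcript_path[need], function(p)
      paste(readLines(file.path(audio_root, p), warn = FALSE), collapse = "\n"),
      character(1))
  }
  df$call_time <- parse_call_time(df$call_time)
  df$.row <- seq_len(nrow(df))

  key <- paste(df$participant_id, df$call_time, sep = "\r")
  participants <- list()
  diagnoses <- character(0)
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, , drop = FALSE]
    calls <- lapply(split(sub, sub$call_time), function(g) {
      if (nrow(g) != 3)
        stop("malformed call for participant '", pid, "' at time ",
             g$call_time[1], ": expected 3 prompt rows, found ", nrow(g))
      if (anyDuplicated(g$prompt_index) || !setequal(g$prompt_index, 1:3))
        stop("malformed call for participant '", pid, "' at time ",
             g$call_time[1], ": prompt_index must be exactly {1,2,3}")
      g <- g[order(g$prompt_index), , drop = FALSE]
      rating <- unique(g$provider_rating[!is.na(g$provider_rating)])
      rating <- if (length(rating)) rating[1] else NA_real_
      if (!is.na(rating) && (rating < 1 || rating > 10))
        stop("provider_rating out of range [1,10] for participant '", pid, "'")
      responses <- lapply(seq_len(3), function(i) {
        ap <- g$audio_path[i]
        if (!is.na(ap) && nzchar(ap) && !grepl("^/", ap))
          ap <- file.path(audio_root, ap)
        list(prompt_index = i, transcript = g$transcript[i],
             audio_path = ap, rejected = g$rejected[i])
      })
      list(participant_id = pid, call_time = g$call_time[1],
           provider_rating = rating, responses = responses,
           .row = min(g$.row))
    })
    ord <- order(vapply(calls, `[[`, 0, "call_time"),
                 vapply(calls, `[[`, 0, ".row"))
    participants[[pid]] <- unname(calls[ord])
    dx <- unique(sub$diagnosis[!is.na(sub$diagnosis)])
    diagnoses[pid] <- if (length(dx)) dx[1] else NA_character_
  }
  structure(list(participants = participants, diagnoses = diagnoses,
                 assessments = assessments),
            class = "speech_cohort")
}

#' @export
print.speech_cohort <- function(x, ...) {
  n_calls <- sum(vapply(x$participants, length, 0L))
  cat("speech_cohort:", length(x$participants), "participants,",
      n_calls, "calls\n")
  invisible(x)
}

#' Number of calls per participant
#' @param cohort a \code{speech_cohort}.
#' @return named integer vector.
#' @export
cohort_call_counts <- function(cohort) {
  vapply(cohort$participants, length, 0L)
}

#' Write a cohort manifest
#'
#' Inverse of \code{\link{read_cohort}}: writes the flat one-row-per-prompt
#' manifest CSV. Audio files themselves are not copied.
#'
#' @param cohort a \code{speech_cohort}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- list()
  for (pid in names(cohort$participants)) {
    for (call in cohort$participants[[pid]]) {
      for (resp in call$responses) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, call_time = call$call_time,
          prompt_index = resp$prompt_index, transcript = resp$transcript,
          audio_path = resp$audio_path %||% NA_character_,
          provider_rating = call$provider_rating,
          diagnosis = cohort$diagnoses[[pid]] %||% NA_character_,
          rejected = resp$rejected, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a call-feature table
#'
#' One row per call: \code{participant_id}, \code{call_time},
#' \code{provider_rating}, then the 210 named features in manifest order.
#' Missing values become empty cells.
#'
#' @param rows a feature table data frame (from
#'   \code{\link{extract_cohort_features}}) or a list of single-call rows
#'   sharing one manifest.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    manifests <- lapply(rows, attr, "manifest")
    if (length(unique(vapply(manifests, paste, "", collapse = "|"))) > 1)
      stop("inconsistent feature manifests across rows")
    df <- do.call(rbind, rows)
    attr(df, "manifest") <- manifests[[1]]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a call-feature table written by \code{\link{write_feature_table}}
#' @param path CSV path.
#' @return data frame with metadata columns followed by feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- intersect(c("participant_id", "call_time", "provider_rating"), names(df))
  feat <- setdiff(names(df), meta)
  df[feat] <- lapply(df[feat], as.numeric)
  df
}
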