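#' Build a latent-semantic-analysis space
#'
#' Builds a term-document count matrix over the corpus (documents are
#' responses), applies log-entropy (default) or tf-idf weighting, and
#' factors it by truncated SVD. Word vectors are the left singular vectors
#' scaled by their singular values. The exact LAPACK SVD is used, so the
#' space is deterministic.
#'
#' @param corpus list of \code{token_sequence} objects (or character token
#'   vectors), one per document.
#' @param k target dimensionality; the default (NULL) uses
#'   \code{min(50, min(|V|, D) - 1)}. An explicit \code{k} larger than
#'   \code{min(|V|, D)} is a parameter error.
#' @param weighting \code{"log-entropy"} or \code{"tf-idf"}.
#' @return an object of class \code{lsa_space} with \code{vocabulary},
#'   \code{word_vectors} (|V| x k), \code{k}, \code{weighting}.
#' @export
build_lsa_space <- function(corpus, k = NULL,
                            weighting = c("log-entropy", "tf-idf")) {
  weighting <- match.arg(weighting)
  toks <- lapply(corpus, function(d)
    if (inherits(d, "token_sequence")) d$tokens else as.character(d))
  toks <- toks[lengths(toks) > 0]
  if (!length(toks)) stop("corpus has no non-empty documents")
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  D <- length(toks)
  X <- matrix(0, nrow = length(vocab), ncol = D)
  for (j in seq_len(D)) {
    tab <- table(toks[[j]])
    X[match(names(tab), vocab), j] <- as.numeric(tab)
  }
  k_max <- max(1L, min(length(vocab), D))
  if (is.null(k)) k <- max(1L, min(50L, k_max - 1L))
  else if (k > k_max) stop("k = ", k, " exceeds min(|V|, D) = ", k_max)
  k <- as.integer(k)
  W <- switch(weighting,
    "log-entropy" = {
      gf <- rowSums(X)
      P <- X / ifelse(gf == 0, 1, gf)
      ent <- rowSums(ifelse(P > 0, P * log(P), 0))
      g <- 1 + ent / log(max(2, D))
      log(1 + X) * g
    },
    "tf-idf" = {
      dfreq <- rowSums(X > 0)
      X * log(D / pmax(1, dfreq))
    })
  sv <- svd(W, nu = k, nv = 0)
  wv <- sv$u * rep(sv$d[seq_len(k)], each = nrow(sv$u))
  rownames(wv) <- vocab
  structure(list(vocabulary = vocab, word_vectors = wv, k = k,
                 weighting = weighting),
            class = "lsa_space")
}

#' Project a phrase into an LSA space
#' @param tokens character vector.
#' @param space an \code{lsa_space}.
#' @return numeric vector of length \code{space$k}, or NULL if no token is
#'   in vocabulary.
#' @keywords internal
phrase_vector <- function(tokens, space) {
  idx <- match(tokens, space$vocabulary)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NULL)
  colMeans(space$word_vectors[idx, , drop = FALSE])
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  clip(sum(a * b) / (na * nb), -1, 1)
}

#' Semantic-coherence features of a response
#'
#' Splits the response into phrases (sentences when punctuation exists,
#' otherwise non-overlapping fixed-length word windows), projects each
#' phrase as the mean of its in-vocabulary word vectors, and measures the
#' cosine similarity between consecutive phrases. Phrases with no
#' in-vocabulary content are skipped. Fewer than two usable phrases gives
#' missing features.
#'
#' @param tokens a \code{token_sequence}.
#' @param space an \code{lsa_space}.
#' @param phrase_mode \code{"auto"} (sentences if more than one exists, else
#'   windows), \code{"sentence"}, or \code{"window"}.
#' @param window_len window length in words for the window mode.
#' @return list with \code{mean_coherence}, \code{std_coherence}
#'   (population formula), \code{n_phrase_pairs}.
#' @export
coherence_features <- function(tokens, space,
                               phrase_mode = c("auto", "sentence", "window"),
                               window_len = 10L) {
  phrase_mode <- match.arg(phrase_mode)
  tk <- tokens$tokens
  miss <- list(mean_coherence = NA_real_, std_coherence = NA_real_,
               n_phrase_pairs = 0L)
  if (!length(tk)) return(miss)
  use_sent <- switch(phrase_mode,
                     sentence = TRUE, window = FALSE,
                     auto = length(tokens$sentences) > 1L)
  phrases <- if (use_sent) {
    lapply(tokens$sentences, function(r) tk[r[1]:r[2]])
  } else {
    idx <- split(seq_along(tk), (seq_along(tk) - 1L) %/% window_len)
    lapply(idx, function(i) tk[i])
  }
  vecs <- Filter(Negate(is.null), lapply(phrases, phrase_vector, space = space))
  if (length(vecs) < 2L) return(miss)
  sims <- vapply(seq_len(length(vecs) - 1L), function(i)
    cosine_sim(vecs[[i]], vecs[[i + 1L]]), 0)
  sims <- sims[is.finite(sims)]
  if (!length(sims)) return(miss)
  list(mean_coherence = mean(sims), std_coherence = pop_sd(sims),
       n_phrase_pairs = length(sims))
}

#' Save an LSA space to a directory (vocabulary text file + dense matrix CSV)
#' @param space an \code{lsa_space}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_lsa_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(space$vocabulary, file.path(dir, "vocabulary.txt"))
  utils::write.table(space$word_vectors, file.path(dir, "word_vectors.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  writeLines(c(paste0("k: ", space$k), paste0("weighting: ", space$weighting)),
             file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load an LSA space saved by \code{\link{write_lsa_space}}
#' @param dir directory path.
#' @return an \code{lsa_space}.
#' @export
read_lsa_space <- function(dir) {
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  wv <- as.matrix(utils::read.table(file.path(dir, "word_vectors.csv"), sep = ","))
  dimnames(wv) <- list(vocab, NULL)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(vocabulary = vocab, word_vectors = wv, k = meta$k,
                 weighting = meta$weighting),
            class = "lsa_space")
}
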