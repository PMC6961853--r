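# Generates the bundled synthetic demo lexicons under inst/extdata/.
# Words are invented (pronounceable pseudo-words) so the package ships no
# proprietary dictionary content; norms are assigned so that affect-tagged
# words carry coherent valence/positivity/negativity values.
set.seed(20240901)

onsets <- c("b", "br", "d", "dr", "f", "fl", "g", "gl", "h", "k", "kr", "l",
            "m", "n", "p", "pl", "r", "s", "sk", "sl", "t", "tr", "v", "z")
nuclei <- c("a", "e", "i", "o", "u", "ai", "ee", "oa", "ou")
codas  <- c("", "l", "m", "n", "r", "s", "t", "nd", "rk", "sh")

make_word <- function(n_syll) {
  parts <- vapply(seq_len(n_syll), function(i) {
    paste0(sample(onsets, 1), sample(nuclei, 1),
           if (i == n_syll) sample(codas, 1) else "")
  }, character(1))
  paste0(parts, collapse = "")
}

make_pool <- function(n, syll_range) {
  out <- character(0)
  while (length(out) < n) {
    w <- make_word(sample(syll_range, 1))
    if (nchar(w) >= 3 && !(w %in% out)) out <- c(out, w)
  }
  out
}

categories <- c("posemo", "negemo", "anxiety", "anger", "sad", "social",
                "family", "religion", "health", "body", "death", "assent",
                "swear", "money", "work")

cat_words <- list()
used <- character(0)
for (cat in categories) {
  pool <- character(0)
  while (length(pool) < 14) {
    w <- make_word(sample(1:3, 1))
    if (nchar(w) >= 3 && !(w %in% used)) { pool <- c(pool, w); used <- c(used, w) }
  }
  cat_words[[cat]] <- pool
}
# a handful of stem families per affect category to exercise wildcard patterns
stem_extra <- list(
  posemo = c("glees", "gleesa", "gleeso"),
  negemo = c("drulm", "drulma", "drulmi"),
  religion = c("zorel", "zorela", "zorelum")
)
for (cat in names(stem_extra)) {
  cat_words[[cat]] <- c(cat_words[[cat]], stem_extra[[cat]])
  used <- c(used, stem_extra[[cat]])
}

neutral <- character(0)
while (length(neutral) < 80) {
  w <- make_word(sample(1:5, 1))
  if (nchar(w) >= 3 && !(w %in% used) && !(w %in% neutral)) neutral <- c(neutral, w)
}

all_words <- c(unlist(cat_words, use.names = FALSE), neutral)
tag <- rep(c(rep(names(cat_words), lengths(cat_words)), rep("neutral", length(neutral))),
           times = 1)
tag <- c(rep(names(cat_words), lengths(cat_words)), rep("neutral", length(neutral)))

rnorm01 <- function(n, m, s) pmin(0.98, pmax(0.02, rnorm(n, m, s)))
n <- length(all_words)
val_mean <- ifelse(tag == "posemo", 0.82,
            ifelse(tag %in% c("negemo", "sad", "anger", "anxiety", "death", "swear"), 0.18, 0.5))
norms <- data.frame(
  word = all_words,
  arousal = rnorm01(n, ifelse(tag %in% c("anger", "anxiety", "swear"), 0.75, 0.45), 0.12),
  valence = rnorm01(n, val_mean, 0.07),
  positivity = rnorm01(n, ifelse(tag == "posemo", 0.8, 0.3), 0.1),
  negativity = rnorm01(n, ifelse(tag %in% c("negemo", "sad", "anger", "anxiety"), 0.8, 0.25), 0.1),
  objectivity = rnorm01(n, ifelse(tag == "neutral", 0.7, 0.35), 0.12),
  concreteness = rnorm01(n, ifelse(tag %in% c("body", "money", "work"), 0.75, 0.45), 0.15),
  age_of_acquisition = rnorm01(n, 0.3 + 0.08 * nchar(all_words) / 4, 0.1),
  pronounceability = rnorm01(n, 0.85 - 0.05 * nchar(all_words) / 4, 0.08),
  gender_ladenness = rnorm01(n, 0.5, 0.15),
  stringsAsFactors = FALSE
)
norms[-1] <- lapply(norms[-1], function(v) round(v, 4))
write.csv(norms, "inst/extdata/demo_norms.csv", row.names = FALSE, quote = FALSE)

# LIWC-style .dic: % header mapping ids to names, then word<TAB>id lines.
# Stem families are collapsed to wildcard patterns.
lines <- c("%")
for (i in seq_along(categories)) lines <- c(lines, paste0(i, "\t", categories[i]))
lines <- c(lines, "%")
stems <- c(posemo = "glees*", negemo = "drulm*", religion = "zorel*")
for (i in seq_along(categories)) {
  cat <- categories[i]
  ws <- cat_words[[cat]]
  if (cat %in% names(stems)) {
    fam <- stem_extra[[cat]]
    ws <- c(setdiff(ws, fam), stems[[cat]])
  }
  lines <- c(lines, paste0(ws, "\t", i))
}
writeLines(lines, "inst/extdata/demo_categories.dic")

# word pools used by the transcript generator (tag table)
write.csv(data.frame(word = all_words, tag = tag, stringsAsFactors = FALSE),
          "inst/extdata/demo_word_tags.csv", row.names = FALSE, quote = FALSE)
cat("words:", n, "\n")
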