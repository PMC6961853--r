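---
title: "Methods: speech features and clinical-state models in speechstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech features and clinical-state models in speechstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechstate)
```

`speechstate` turns repeated patient phone calls — three open-ended spoken
responses per call, each with a transcript and telephone-grade audio, plus a
provider's 1–10 global assessment rating — into longitudinal models of
clinical state. This vignette documents the science inside each stage: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic cohort does and does not emulate, and the design
decisions taken where the design was genuinely open.

## The feature space

Each response is summarized by 70 features, so a call (three responses)
yields 210. The blocks:

**Norm functionals (36).** Nine per-word psycholinguistic norms — arousal,
valence, positivity, negativity, objectivity, concreteness, age of
acquisition, pronounceability, gender ladenness — are looked up for every
in-vocabulary token and summarized by mean, min, max, and standard
deviation. The standard deviation uses the population formula (÷n), so a
single-word response yields 0 rather than an undefined value. Out-of-vocabulary
tokens change no functional; coverage is reported alongside so downstream
users can see how much of a response the lexicon explains. There is no
norm extrapolation to unseen words: lookup-only keeps the feature meaning
transparent.

**Category percentages (15).** A dictionary of word categories
(positive/negative emotion, anxiety, anger, sadness, social, family,
religion, health, body, death, assent, swearing, money, work) is applied as
literal words and prefix wildcards (`ador*` matches `adore`, `adoring`);
each feature is 100 × matched/total tokens. The package reads the classic
`%`-delimited dictionary format and a YAML alternative. The bundled
dictionary is synthetic — invented, pronounceable pseudo-words with assigned
norms — so the package ships no proprietary lexicon content; real analyses
should point `feature_resources()` at a licensed dictionary and norm table.

**Readability and complexity (8).** Flesch reading ease, Flesch–Kincaid
grade, SMOG, Automated Readability Index, Coleman–Liau, the difficult-word
count, total word count, and mean syllables per word. Syllables come from a
deterministic heuristic (maximal `aeiouy` groups, silent terminal *e*
subtracted when it forms its own group, minimum one); it is approximate by
design — dictionary-free and stable — and its errors are shared across all
calls, which matters more for longitudinal correlation than absolute
accuracy. Difficult words default to *more than six syllables*, with the
conventional polysyllable rule (≥3) available via
`difficult_min_syllables = 3`; the unusual default is retained because it is
the definition this feature set historically used, and at the >6 threshold
the count acts as a rare-event complexity marker. Spontaneous speech
transcripts often lack punctuation; sentence-normalized formulas then treat
the response as one sentence, or as fixed-length pseudo-sentences (default
15 words) when `pseudo_sentence_len` is set.

**Semantic coherence (2).** A latent-semantic-analysis space is built from
the cohort's own responses: term–document counts, log-entropy weighting
(tf-idf optional), truncated SVD (exact LAPACK, hence deterministic), word
vectors `U_k Σ_k`, dimensionality `k = min(50, min(|V|, D) − 1)`. Phrases
are sentences when punctuation exists, else non-overlapping 10-word
windows; a phrase vector is the mean of its in-vocabulary word vectors;
the coherence series is the cosine similarity of consecutive phrase
vectors, summarized by mean and standard deviation. Phrases with no
in-vocabulary content are skipped rather than treated as zero vectors,
avoiding undefined cosines. Coherence is computed within a response (not
across the whole call): responses answer different prompts, and mixing them
would measure topic shift rather than disorganization. Training the space
on the study corpus itself keeps the pipeline self-contained; a pretrained
space can be loaded through `read_lsa_space()`.

**Acoustics (9).** F0 mean, median, and standard deviation (intonation
variability), F1 and F2 means, median harmonics-to-noise ratio, pause
fraction, mean pause duration, and voiced-frame fraction. The algorithms
are the standard ones, implemented in-package and validated against
synthesized signals with known parameters:

* *Pitch*: framewise (40 ms window / 10 ms hop) normalized autocorrelation,
  unbiased by the lag window, peak in the 75–500 Hz lag range with
  parabolic interpolation; frames are unvoiced below a 0.45 peak
  correlation or at negligible relative energy. Two guards prevent octave
  errors: among near-tied local maxima the shortest lag wins, and a
  clearly periodic local maximum near half the chosen lag is preferred —
  at 8 kHz a ±1-sample period jitter can make the two-period lag correlate
  slightly better than the true period.
* *Formants*: per voiced frame, 0.97 pre-emphasis, Hamming window, LPC of
  order `2 + sr/1000` by the autocorrelation method, polynomial roots;
  resonances with bandwidth < 400 Hz in `[90, sr/2 − 50]` Hz, sorted
  ascending, averaged over frames. Voiced frames are subsampled to at most
  40 per response to bound cost.
* *Harmonicity*: `10·log10(r/(1−r))` at the F0 lag per voiced frame
  (`r` clipped to `[1e−6, 1−1e−6]`), median over frames. A noiseless
  harmonic signal scores > 20 dB; a signal plus equal-power noise scores
  ≈ 0 dB.
* *Pauses*: RMS-energy voice-activity detection (25 ms / 10 ms), speech
  threshold at 5 % of the 95th-percentile frame energy (so all thresholds
  are relative — features are invariant to recording gain), pauses are
  internal non-speech runs ≥ 150 ms; leading/trailing silence is excluded.
  With no word alignments available, inter-speech-segment pauses stand in
  for inter-word pauses.

Telephone audio (8 kHz, 16-bit mono) is the default everywhere, but the
extractors accept any PCM rate.

## Correlation structure statistics

Feature–rating association uses Spearman rank correlation (average ranks on
ties; p from the t approximation), pooled over all rated calls for the
population report — significance is Bonferroni-corrected at
`alpha / n_features` — and within participants for individual profiles.
Profile similarity between two participants is the Pearson correlation of
their 210-entry rho vectors; its mean over pairs quantifies how shared the
feature-utility structure is across people.

Temporal stability splits a participant's calls chronologically in half and
tests each feature's first-half vs second-half correlation. The halves are
disjoint samples, so the default test is the Fisher r-to-z comparison for
independent correlations. A Hotelling–Williams dependent-correlation
variant is provided for users who prefer that framing; because no pairing
correlation exists across disjoint halves it assumes independence
(`r12 = 0`) and floors the correlation-matrix determinant, making it a
conservative analogue rather than a literal dependent-correlation test.
The stable fraction is the share of testable features with p ≥ 0.05.

## State-tracking models

Features and ratings are averaged over non-overlapping 4-call windows
(trailing remainders dropped — partial windows would break the
independence of adjacent samples); clinical state moves on the timescale
of weeks, and block averaging suppresses call-level noise on both sides.
Window means ignore missing cells and go missing only when a whole block
is missing.

The regressor is a linear epsilon-insensitive support-vector machine.
Hyperparameters (cost × epsilon, 12 combinations) are tuned in an inner
cross-validation layer inside each training fold, minimizing mean absolute
error — the natural loss for epsilon-insensitive regression. Inner folds
are participant-grouped (population model, 5 folds, seeded shuffle) or
sequential blocks (personalized model), so tuning never sees the outer
test data. Within every training fold, and only there, missing features
are median-imputed and all features z-standardized; the same statistics
transform the test fold. Standardization is essential — the 210 features
mix percentages, Hz, dB, and counts, and an unscaled linear margin would be
dominated by the largest unit. Predictions of the 1–10 rating are clipped
to the scale. When the epsilon tube swallows every training target the SVR
has no support vectors and the fitted function is flat; the implementation
then predicts the training mean explicitly.

Evaluation is the per-participant Spearman correlation between predicted
and actual window ratings (participants with fewer than three evaluable
windows are excluded and counted), averaged across participants for both
model families so the two are comparable; a pooled-samples aggregation is
available as an option. The population baseline is the no-correlation
reference; the personalized baseline predicts each window by the
participant's leave-one-out mean rating. Improvement over baseline is a
t-test on per-participant correlation differences, two-tailed by default.
Forecasting pairs window *t* features with window *t+1* ratings; under an
AR(1) latent state with autocorrelation below one, forecasting correlation
is expected to fall below concurrent correlation.

The personalized model requires 35 calls per participant before windowing —
roughly the point where within-person training curves plateau — and skips
(with a message) participants below it. Diagnosis classification aggregates
each participant to mean features, runs leave-one-subject-out linear SVC,
and reports unweighted average recall with a 200-permutation label test.

## The synthetic cohort

The generator produces the statistical structure the analysis assumes,
with every extractor supplied ground truth:

* **Latent state**: per participant, an AR(1) process
  `s_t = μ_i + φ(s_{t−1} − μ_i) + ε_t` clipped to [1, 10], with
  `μ_i ~ U(3.5, 7.5)`, `φ = 0.8`, innovation sd 0.7 — a persistent,
  slowly-moving clinical state whose week-scale swings span roughly ±2
  scale points. Provider ratings are the state plus N(0, 0.7) noise,
  rounded and clipped: imperfect but strongly informative, in line with
  single-item global ratings.
* **Text**: word count `118 + 10·w_word·(s − 5.5) + N(0, 15)` (the base of
  ~118 words matches a short free-speech response), and per-word
  positive/negative probabilities `0.18 ± 0.05·w_affect·(s − 5.5)`,
  clipped. Words come from the bundled synthetic lexicon; sentence breaks
  every ~12 words. Transcripts are statistical word salads — sufficient
  for every lexical feature, with no claim to fluent language, discourse
  structure, or topical content.
* **Audio**: impulse-train excitation at
  `F0 = f0_base_i + 4·w_f0·(s − 5.5)` Hz (participant baselines jittered
  N(140, 8) to mimic natural voice differences) through resonators at 700
  and 1200 Hz, plus low-level noise; silence gaps sized so the pause
  fraction tracks `0.30 − 0.03·w_pause·(s − 5.5)`. Durations default to
  2.5 s — long enough for stable pitch, formant, and pause statistics while
  keeping a full cohort synthesizable in seconds.
* **Loadings**: in `heterogeneous` mode each participant draws independent
  random signs and magnitudes `w` over the four channels (word count,
  affect, F0, pauses), reproducing the empirical observation that *which*
  features track state is individual-specific (near-zero cross-participant
  profile similarity) while *within*-person structure is stable. In
  `shared` mode all participants use the same positive pattern, the regime
  in which population-level models work. The generator's signal-to-noise is
  calibrated so that shared-loading population structure is learnable —
  the qualitative contrast between the modes, not any particular
  correlation value, is the point.
* Diagnoses are assigned uniformly at random from four labels, so the
  diagnosis classifier should perform at chance — matching the observation
  that these features track state, not diagnostic category.
* All randomness flows through one master seed with deterministic
  per-participant and per-call substreams; a cohort is byte-reproducible
  from its parameters.

What passing tests on this cohort show: the pipeline recovers planted
monotone state–feature couplings through the full
transcript/audio → feature → window → model chain, honors all
cross-validation boundaries, and reproduces the qualitative
personalized-vs-population contrast. What they cannot show: performance on
real speech, where transcripts are fluent and topical, acoustic channels
are far noisier, lexicon coverage is partial, and provider ratings have
richer error structure.

## Problem sizes and numerical choices

The packaged analyses use a 12 × 60-call heterogeneous cohort for the
personalized-vs-population comparison (12 qualifying participants at the
35-call threshold, 15 windows each), a 20 × 48 shared cohort for
population-level structure, and a 24 × 6 cohort for the chance-level
diagnosis check — sizes chosen to estimate per-participant rank
correlations with usable precision while keeping a full run in the
minutes range on a single CPU. Other numerical details: ties in ranks use
average ranks; cosines are clipped to [−1, 1]; zero-variance columns get
unit scale rather than dividing by zero; SVR tolerance is 0.01 (rank-based
evaluation is insensitive to tighter convergence); WAV integer rescaling
uses the 2^(bits−1) convention, so full-scale 16-bit is 32767/32768.

## Known limitations

Syllable counts and therefore readability indices are heuristic; the
bundled lexicons are synthetic demos, not instruments; no speech-to-text is
included (transcripts are inputs); jitter/shimmer and spectral features
beyond the nine listed are out of scope, as are word embeddings, neural
models, and hierarchical/nonlinear temporal models. The Williams-variant
stability test is a conservative approximation, as documented above.
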