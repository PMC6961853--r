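# speechstate

Tracking mental-health clinical state from longitudinal speech samples.

People with serious mental illness (bipolar disorder, major depression,
schizophrenia, schizoaffective disorder) move through clinical states that
are hard to measure between visits. When patients leave short spoken
responses by phone and a provider rates how the patient is doing on a 1–10
global-assessment scale, the speech itself carries usable signal:
affect-laden word choice, lexical complexity, semantic coherence, pitch,
formants, harmonicity, and pausing all co-vary with clinical state.
`speechstate` implements that analysis as a reusable R pipeline, and ships a
synthetic longitudinal cohort generator so every stage can be exercised —
and validated against known ground truth — without any patient data.

## What the package computes

**Features.** Each call holds three open-ended responses (transcript +
mono WAV). Per response the package extracts 70 features:

| block | count | examples |
|---|---|---|
| psycholinguistic norm functionals | 36 | valence mean/min/max/std, arousal, concreteness, … |
| dictionary category percentages | 15 | positive-emotion %, negative-emotion %, religion %, … |
| readability / complexity | 8 | Flesch reading ease, SMOG, difficult-word count, word count |
| LSA semantic coherence | 2 | mean and std of consecutive-phrase cosine similarity |
| acoustic | 9 | F0 mean/median/std, F1/F2 means, HNR median, pause fraction/duration, voiced fraction |

Three responses give the 210-dimensional per-call feature row.

**Statistics.** Pooled Spearman correlation of every feature with the
provider rating (Bonferroni-corrected at `alpha / n_features`),
per-individual correlation profiles and their cross-participant similarity,
and chronological half-split stability tests (Fisher r-to-z by default, a
Hotelling–Williams variant optionally).

**Models.** L2-regularized linear support-vector regression with two-layer
cross-validation (inner grid over cost `{0.01, 0.1, 1, 10}` and epsilon
`{0.01, 0.1, 1}`, mean-absolute-error loss), on 4-call non-overlapping
window averages of features and ratings:

* *population*: leave-one-subject-out across participants;
* *personalized*: leave-one-window-out within a participant (requiring 35
  calls), against the participant's leave-one-out mean rating as baseline;
* *concurrent* (window *t* → rating *t*) and *forecasting* (window *t* →
  rating *t+1*) variants, evaluated by per-participant Spearman rho;
* leave-one-subject-out diagnosis classification with a label-permutation
  test (reported as unweighted average recall).

Median imputation and z-standardization are fit on training folds only.

## Worked example

```r
library(speechstate)

# a small synthetic cohort: 4 participants x 16 weekly calls, each call is
# three transcripts + three 8 kHz WAV responses driven by a latent AR(1)
# clinical state; shared loadings mean every participant's speech encodes
# state the same way, the regime where a population model can learn
params <- sim_params(n_participants = 4, calls_per_participant = 16,
                     loading_mode = "shared", seed = 5)
cohort <- simulate_cohort(params)
feats  <- extract_cohort_features(cohort)
dim(feats)
#> [1]  64 213     # 64 calls: participant_id, call_time, provider_rating + 210 features

rep <- population_feature_correlations(feats)
head(rep$report[, c("feature", "rho")], 3)
#>       feature       rho
#> 1 q1__f0_mean 0.8971564
#> 2 q2__f0_mean 0.8971564
#> 3 q3__f0_mean 0.8971564

cfg <- model_config(window_size = 2, min_samples_personalized = 16, seed = 5)
win <- window_average_cohort(feats, cfg$window_size)
pop <- fit_predict_population(win, cfg)
evaluate(pop, baseline_predictions(win, "zero_correlation"))
#> mean Spearman rho = 0.560 over 4 participants (32 samples)
#> vs baseline (mean rho 0.000): p = 0.009954
```

At this toy scale the fundamental-frequency features happen to rank first
(all three responses of a call share one latent state, so their features
tie); on study-scale cohorts the affect features dominate. The same stages
are scriptable through `run_command("all", config)` or the thin CLI at
`inst/cli/speechstate.R`.

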