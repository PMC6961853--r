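Package: speechstate
Title: Clinical-State Tracking from Longitudinal Speech Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for tracking mental-health clinical state from
    repeated patient phone-call speech samples. Extracts a 210-dimensional
    per-call feature vector (psycholinguistic norm functionals, dictionary
    word-category percentages, readability and complexity indices, latent
    semantic analysis coherence, and nine acoustic features covering pitch,
    formants, harmonicity and pauses), analyzes feature-rating correlations
    and their within- and between-person structure, and trains population
    (leave-one-subject-out) and personalized (leave-one-sample-out) linear
    support-vector regression models of provider-rated clinical state for
    concurrent and forecasting assessment. Includes a synthetic longitudinal
    cohort generator with latent AR(1) clinical states driving transcripts
    and synthesized audio, providing ground truth for every extractor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
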