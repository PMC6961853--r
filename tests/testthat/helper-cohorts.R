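# Study-scale synthetic cohorts used by the acceptance suite. Built lazily
# and memoized so the cost is paid once per test run.

acc_hetero <- function() fixture("acc_hetero", function() {
  co <- simulate_cohort(sim_params(seed = 0))  # 12 x 60, heterogeneous
  list(cohort = co, features = extract_cohort_features(co))
})

acc_shared <- function() fixture("acc_shared", function() {
  co <- simulate_cohort(sim_params(n_participants = 20,
                                   calls_per_participant = 48,
                                   loading_mode = "shared", seed = 0))
  list(cohort = co, features = extract_cohort_features(co))
})

acc_classification <- function() fixture("acc_classification", function() {
  co <- simulate_cohort(sim_params(n_participants = 24,
                                   calls_per_participant = 6, seed = 0))
  list(cohort = co, features = extract_cohort_features(co))
})
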