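# Synthetic cohorts reused across test files, built once per run. Seeds are
# fixed study conditions, not tuning knobs.
.cohorts <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cohorts)) {
    assign(name, builder(), envir = .cohorts)
  }
  get(name, envir = .cohorts)
}

# the main cohort: 10 opsin + 6 control PH agents, 10 sessions x 60 trials
ph_cohort_raw <- function() {
  cached("ph_raw", function() {
    simulate_sessions(config = generator_config(seed = 11))
  })
}

ph_cohort <- function() {
  cached("ph", function() prepare_sessions(ph_cohort_raw()))
}

ph_truth <- function() attr(ph_cohort_raw(), "ground_truth")

ph_fits <- function() {
  cached("ph_fits", function() {
    suppressWarnings(fit_ph_by_subject(ph_cohort()))
  })
}

eq4_cohort <- function() {
  cached("eq4", function() {
    prepare_sessions(
      simulate_mvt_logistic_agent(config = generator_config(seed = 12))
    )
  })
}

mvt_cohort <- function() {
  cached("mvt", function() {
    prepare_sessions(simulate_mvt_agent(0.3, config = generator_config(seed = 99)))
  })
}

mvt_shuffled <- function() {
  cached("mvt_shuffled", function() {
    prepare_sessions(shuffle_dataset(mvt_cohort(), seed = 100))
  })
}
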