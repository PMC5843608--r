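# Shared setup for the numbered analysis scripts: seeds, cohort builders,
# and output locations. Each script can be run on its own from the
# repository root (Rscript analysis/0X_*.R); cohorts are cached under
# scratch/ so later scripts reuse earlier simulations.

suppressMessages({
  library(foragehazard)
  library(dplyr)
})

SEED_MAIN <- 11      # proportional-hazards cohort (10 opsin + 6 control)
SEED_EQ4 <- 12       # belief-driven (MVT-logistic) cohort
SEED_MVT <- 99       # threshold-rule cohort
SEED_SHUFFLE <- 100  # shuffling null
SEED_TUNE <- 7000    # threshold self-consistency iteration

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cached_sessions <- function(path, builder) {
  if (file.exists(path)) {
    read_sessions(path)
  } else {
    ss <- builder()
    write_sessions(ss, path)
    ss
  }
}

main_cohort <- function() {
  cached_sessions("scratch/sessions_main.csv", function() {
    simulate_sessions(config = generator_config(seed = SEED_MAIN))
  })
}

main_truth <- function() {
  path <- "scratch/truth_main.json"
  if (!file.exists(path)) {
    truth <- attr(simulate_sessions(config = generator_config(seed = SEED_MAIN)),
                  "ground_truth")
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

eq4_cohort <- function() {
  cached_sessions("scratch/sessions_eq4.csv", function() {
    simulate_mvt_logistic_agent(config = generator_config(seed = SEED_EQ4))
  })
}

mvt_cohort <- function() {
  cached_sessions("scratch/sessions_mvt.csv", function() {
    simulate_mvt_agent(0.3, config = generator_config(seed = SEED_MVT))
  })
}
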