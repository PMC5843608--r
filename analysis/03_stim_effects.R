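#!/usr/bin/env Rscript

# Photostimulation effect statistics on the main cohort: per-subject
# difference in pokes per trial, the opsin-vs-control comparison, the
# streak (carry-over) regression, time-to-leave and travel-time contrasts
# with the travel-analysis exclusion rules, and the constancy check of the
# stimulation effect across the trial.

source("analysis/00_common.R")

cohort <- prepare_sessions(main_cohort())
se <- stim_effect_summary(cohort)
print(se)

readr::write_csv(se$per_subject, "results/03_stim_effects_by_subject.csv")
readr::write_csv(se$excluded_fractions, "results/03_travel_exclusions.csv")
cat("\nTables: results/03_stim_effects_by_subject.csv, results/03_travel_exclusions.csv\n")
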