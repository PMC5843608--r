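#!/usr/bin/env Rscript

# Poke-vigor microstructure: the omission duty cycle (ODC) as a readout of
# the latent hazard of leaving. Profiles aligned on the trial's last
# reward, the before/after reset contrasts, the ODC-hazard correlation,
# and the two stimulation regressions (marginal on position; conditional
# on the model hazard, which should absorb the stimulation effect).

source("analysis/00_common.R")

cohort <- prepare_sessions(main_cohort())
fits <- suppressWarnings(fit_ph_by_subject(cohort))

al <- align_last_reward(cohort, fits)
print(al)
readr::write_csv(al$profile, "results/05_odc_profile.csv")
readr::write_csv(al$contrasts, "results/05_odc_contrasts.csv")

links <- odc_model_links(cohort, fits)
print(links)
cat(sprintf("  stim on ODC given position: rank-sum p = %.4g\n",
            links$tests$position$rank_sum$p))
cat(sprintf("  stim on ODC given hazard:   opsin signed-rank p = %.4g\n",
            links$tests$hazard$signed_rank_opsin$p))
readr::write_csv(links$coefs, "results/05_odc_stim_coefs.csv")
cat("Tables: results/05_odc_profile.csv, results/05_odc_contrasts.csv, results/05_odc_stim_coefs.csv\n")
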