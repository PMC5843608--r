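test_that("duty cycle is duration over duration plus preceding interval", {
  ss <- toy_sessions(list(
    list(outcomes = c(1, 0, 0), side = "L", dur = 0.45, ipi = 0.15)
  ))
  rec <- compute_odc(ss)
  # first poke has no predecessor; the rewarded first poke is excluded too
  expect_equal(rec$poke_index, c(2L, 3L))
  expect_equal(rec$odc, c(0.75, 0.75), tolerance = 1e-9)
  expect_equal(rec$rel_position, c(1L, 2L))
  bad <- ss
  bad$poke_in_s[3] <- bad$poke_out_s[2] - 0.01   # overlapping pokes
  expect_error(compute_odc(bad), "non-positive")
})

test_that("rewarded pokes and unrewarded trials are handled explicitly", {
  ss <- toy_sessions(list(
    list(outcomes = c(0, 1, 0), side = "L"),
    list(outcomes = c(0, 0, 0), side = "R")
  ))
  rec <- compute_odc(ss)
  expect_false(any(rec$poke_index == 2 & rec$trial_index == 1))
  expect_true(all(is.na(rec$rel_position[rec$trial_index == 2])))
  expect_true(all(rec$odc > 0 & rec$odc < 1))
})

test_that("the ODC-hazard slope recovers the generator's coupling", {
  rec <- compute_odc(ph_cohort())
  expect_gt(nrow(rec), 20000)
  slope <- unname(coef(lm(odc ~ true_hazard, data = rec))[2])
  expect_lt(abs(slope - (-0.5)) / 0.5, 0.15)
})

test_that("vigor falls and hazard rises within a run", {
  rec <- compute_odc(ph_cohort())
  expect_lt(cor(rec$odc, rec$n_since_reward), 0)
  expect_gt(cor(rec$true_hazard, rec$n_since_reward), 0)
})

test_that("rewards reset both the hazard and the duty cycle", {
  al <- align_last_reward(ph_cohort(), ph_fits())
  expect_gt(mean(al$contrasts$odc_contrast), 0)
  expect_lt(mean(al$contrasts$hazard_contrast), 0)
  expect_lt(al$tests$odc$p, 0.05)
  expect_lt(al$tests$hazard$p, 0.05)
  expect_true(all(al$profile$rel_position %in% c(-5:-1, 1:5)))
})

test_that("a decoupled generator shows no reward reset in the ODC", {
  ss <- prepare_sessions(simulate_sessions(
    agent_params(odc_slope = 0),
    generator_config(n_opsin_subjects = 4, n_control_subjects = 0,
                     sessions_per_subject = 2, trials_per_session = 200,
                     seed = 44)
  ))
  fits <- suppressWarnings(fit_ph_by_subject(ss))
  al <- align_last_reward(ss, fits)
  expect_lt(abs(mean(al$contrasts$odc_contrast)), 0.02)
})

test_that("conditioning on the hazard absorbs the stimulation effect", {
  links <- odc_model_links(ph_cohort(), ph_fits())
  expect_lt(links$r_pooled, -0.5)
  expect_lt(links$r_within, -0.5)
  op <- links$coefs$genotype == "opsin"
  expect_gt(mean(links$coefs$stim_coef_position[op]), 0)
  expect_lt(links$tests$position$rank_sum$p, 0.05)
  expect_gt(links$tests$hazard$signed_rank_opsin$p, 0.05)
  # control subjects: both coefficients centred on zero
  ctrl <- !op
  expect_lt(abs(mean(links$coefs$stim_coef_position[ctrl])), 0.01)
  expect_lt(abs(mean(links$coefs$stim_coef_hazard[ctrl])), 0.01)
})
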