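test_that("theoretical reward maxima equal the finite geometric sums", {
  ps <- patch_statistics(mvt_cohort())
  expect_equal(sort(unique(ps$by_type$max_rewards)),
               c(2.7078, 4.0617, 5.4156), tolerance = 1e-4)
  # simulated rewards never exceed the maxima (within Monte-Carlo error)
  expect_true(all(ps$by_type$mean_rewards <
                    ps$by_type$max_rewards + 3 * 0.05))
})

test_that("ANOVAs use subject means as units", {
  ps <- patch_statistics(mvt_cohort())
  S <- ps$n_subjects
  expect_equal(ps$anova_pokes$df, c(2, 3 * S - 3))
  expect_equal(nrow(ps$subject_means), 3 * S)
  one <- mvt_cohort()
  one <- one[one$subject_id == "m01", ]
  expect_warning(ps1 <- patch_statistics(one), "fewer than 2")
  expect_null(ps1$anova_pokes)
})

test_that("average reward rate is rewards over the session span", {
  # single trial: 8 pokes of 0.6 s, 4 rewards, dwell chosen so the span
  # from ROI entry to ROI exit is exactly 20 s
  ss <- toy_sessions(list(
    list(outcomes = c(1, 1, 0, 1, 0, 1, 0, 0), side = "L",
         dwell = 20 - 8 * 0.6)
  ))
  rc <- reward_rate_comparison(ss)
  expect_equal(rc$average_rate, 4 / 20, tolerance = 1e-9)
})

test_that("rate at leaving divides the leaving belief by the final poke", {
  ss <- toy_sessions(list(list(outcomes = c(0, 0, 0), side = "L")))
  rc <- reward_rate_comparison(ss)
  expect_equal(rc$rate_at_leaving,
               next_reward_probability(c(0, 0, 0)) / 0.4, tolerance = 1e-9)
  bad <- ss
  bad$poke_out_s[nrow(bad)] <- bad$poke_in_s[nrow(bad)]
  expect_error(reward_rate_comparison(bad), "zero-duration")
})

test_that("stimulation effect separates opsin from control subjects", {
  se <- stim_effect_summary(ph_cohort())
  d <- se$per_subject
  expect_gt(mean(d$delta_pokes[d$genotype == "opsin"]),
            mean(d$delta_pokes[d$genotype == "control"]))
  expect_lt(se$group_test$p, 0.05)
  expect_error(stim_effect_summary(within(ph_cohort(), protocol <- NA)),
               "protocol")
})

test_that("carry-over and constancy checks are null for a memoryless agent", {
  se <- stim_effect_summary(ph_cohort())
  # position within a streak of same-condition trials has no effect
  expect_gt(se$sequence_regression$p, 0.05)
  # stimulation effect does not drift with the time of the last reward
  expect_lt(abs(se$last_reward_cor$r), 0.1)
})

test_that("travel exclusions are error-adjacent or timed out", {
  trials <- list(
    list(outcomes = c(0, 0, 0), side = "L"),
    list(outcomes = c(0, 0, 0), side = "R"),
    list(outcomes = c(0, 0), side = "R", correct = 0L),   # error trial
    list(outcomes = c(0, 0, 0), side = "L", timeout = 1L),
    list(outcomes = c(0, 0, 0), side = "R"),
    list(outcomes = c(0, 0, 0), side = "L"),
    list(outcomes = c(0, 0, 0), side = "R")
  )
  trials[[1]]$photostim <- 1L
  trials[[5]]$photostim <- 1L
  se <- suppressWarnings(stim_effect_summary(toy_sessions(trials)))
  ex <- se$excluded_fractions
  # control trials are 2, 4, 6, 7: trial 2 precedes an error, trial 4 timed
  # out, trial 7 ends the session; only trial 6 yields a T2
  expect_equal(ex$excluded_fraction[ex$photostim == 0], 3 / 4)
  expect_equal(ex$excluded_fraction[ex$photostim == 1], 0)
})

test_that("a tuned threshold agent forages at its average reward rate", {
  sc <- mvt_self_consistency(
    generator_config(n_opsin_subjects = 4, n_control_subjects = 0,
                     sessions_per_subject = 4, trials_per_session = 60,
                     seed = 7000)
  )
  expect_lt(sc$relative_gap, 0.10)
})
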