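small_cfg <- function(seed, trials = 200, n_opsin = 2, n_control = 1,
                      sessions = 1) {
  generator_config(n_opsin_subjects = n_opsin,
                   n_control_subjects = n_control,
                   sessions_per_subject = sessions,
                   trials_per_session = trials, seed = seed)
}

test_that("identical seeds reproduce identical session logs", {
  a <- simulate_sessions(config = small_cfg(21))
  b <- simulate_sessions(config = small_cfg(21))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "ground_truth"), attr(b, "ground_truth"))
  c <- simulate_sessions(config = small_cfg(22))
  expect_false(identical(a$poke_in_s, c$poke_in_s))
})

test_that("generated logs obey the task's structural rules", {
  ss <- simulate_sessions(config = small_cfg(23, trials = 300))
  tr <- ss[!duplicated(trial_key_cols(ss)), ]
  for (sid in unique(tr$subject_id)) {
    d <- tr[tr$subject_id == sid, ]
    same_as_prev <- d$side[-1] == d$side[-nrow(d)]
    expect_true(all(same_as_prev == (d$correct[-1] == 0)))
  }
  # error trials carry no rewards and 1-2 pokes
  err <- ss[ss$correct == 0, ]
  expect_true(all(err$rewarded == 0))
  expect_true(all(tapply(err$poke_index, trial_key_cols(err), max) <= 2))
  # pokes live inside the ROI window and times are monotone
  expect_true(all(ss$poke_in_s >= ss$roi_enter_s - 1e-9))
  expect_true(all(ss$poke_out_s <= ss$roi_exit_s + 1e-9))
  # stimulated fraction of correct trials near one half
  ct <- tr[tr$correct == 1, ]
  expect_lt(abs(mean(ct$photostim) - 0.5), 3 * 0.5 / sqrt(nrow(ct)))
})

test_that("potential trials match the schedule's per-poke reward rates", {
  sched <- reward_schedule()
  set.seed(31)
  O <- generate_potential_trial(1, sched, n_trials = 10000)
  expect_equal(nrow(O), 20L)
  expect_lt(abs(mean(O[1, ]) - 0.5), 0.015)
  # per-poke frequencies across the first five pokes, all three types
  for (ti in 1:3) {
    O <- generate_potential_trial(ti, sched, n_trials = 10000)
    p <- reward_probability(1:5, ti, sched)
    se <- sqrt(p * (1 - p) / 10000)
    expect_true(all(abs(rowMeans(O[1:5, ]) - p) <= 3 * se + 1e-9))
  }
  # certain rewards, no decay: every poke pays
  certain <- reward_schedule(scaling_factors = c(1, 1, 1),
                             decay_constant = 1e12)
  expect_true(all(generate_potential_trial(3, certain, n_trials = 50) == 1))
})

test_that("a flat hazard of one half yields geometric trial lengths", {
  agent <- agent_params(baseline_hazard = rep(0.5, 15), beta_stim = 0,
                       beta_side = 0, subject_sd = 0, beta_stim_sd = 0,
                       error_prob = 0)
  norew <- reward_schedule(scaling_factors = rep(1e-9, 3))
  ss <- simulate_sessions(agent, small_cfg(24, trials = 10000, n_opsin = 1,
                                           n_control = 0), norew)
  len <- tapply(ss$poke_index, trial_key_cols(ss), max)
  expect_equal(mean(len), 2.0, tolerance = 0.05)
})

test_that("a negative stimulation coefficient lengthens stimulated trials", {
  ss <- simulate_sessions(
    agent_params(beta_stim = -0.3, beta_stim_sd = 0, subject_sd = 0),
    small_cfg(25, trials = 4000, n_opsin = 1, n_control = 0)
  )
  tr <- ss[!duplicated(trial_key_cols(ss)) & ss$correct == 1, ]
  len <- tapply(ss[ss$correct == 1, ]$poke_index,
                trial_key_cols(ss[ss$correct == 1, ]), max)
  stim <- tr$photostim[match(names(len), trial_key_cols(tr))]
  expect_gt(mean(len[stim == 1]), mean(len[stim == 0]))
})

test_that("duty cycle is negatively coupled to the latent hazard", {
  ss <- simulate_sessions(config = small_cfg(26, trials = 1000))
  rec <- compute_odc(ss)
  expect_true(all(rec$odc > 0 & rec$odc < 1))
  expect_lt(cor(rec$odc, rec$true_hazard), -0.5)
  # decoupled generator: no association
  ss0 <- simulate_sessions(agent_params(odc_slope = 0),
                           small_cfg(27, trials = 1000))
  rec0 <- compute_odc(ss0)
  expect_lt(abs(cor(rec0$odc, rec0$true_hazard)), 0.05)
})

test_that("threshold agents leave by the belief rule", {
  sched <- reward_schedule()
  # high threshold: every correct trial ends at its first omission
  hi <- simulate_mvt_agent(0.9, sched, small_cfg(28, trials = 300),
                           threshold_sd = 0)
  hi <- hi[hi$correct == 1, ]
  key <- trial_key_cols(hi)
  for (kk in unique(key)) {
    o <- hi$rewarded[key == kk]
    expect_true(all(o[-length(o)] == 1))   # only the final poke is an omission
  }
  # vanishing threshold: every correct trial runs to the 20-poke cap
  lo <- simulate_mvt_agent(1e-9, sched, small_cfg(29, trials = 100),
                           threshold_sd = 0)
  lo <- lo[lo$correct == 1, ]
  expect_true(all(tapply(lo$poke_index, trial_key_cols(lo), max) == 20))
})

test_that("threshold agents poke more in better patches", {
  ss <- mvt_cohort()
  ps <- patch_statistics(ss)
  m <- ps$by_type$mean_pokes
  expect_true(m[3] > m[2] && m[2] > m[1])
})

test_that("shuffling preserves lengths but destroys reward-length coupling", {
  real <- mvt_cohort()
  sh <- shuffle_dataset(real, seed = 77)
  expect_true(all(sh$correct == 1))
  expect_true(all(sh$photostim == 0))
  for (sid in unique(real$subject_id)[1:3]) {
    r <- real[real$subject_id == sid & real$correct == 1, ]
    s <- sh[sh$subject_id == sid, ]
    len_r <- tapply(r$poke_index, trial_key_cols(r), max)
    len_s <- tapply(s$poke_index, trial_key_cols(s), max)
    ks <- suppressWarnings(ks.test(len_r, len_s))
    expect_gt(ks$p.value, 0.001)
  }
  expect_identical(
    as.data.frame(shuffle_dataset(real, seed = 78)),
    as.data.frame(shuffle_dataset(real, seed = 78))
  )
})
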