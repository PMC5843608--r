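test_that("observation rows mirror manual run segmentation", {
  ss <- toy_sessions(list(
    list(outcomes = c(1, 0, 0, 1, 0, 0, 0), side = "L"),
    list(outcomes = c(1, 1), side = "R"),
    list(outcomes = c(0, 0), side = "L")
  ))
  obs <- build_observations(ss)
  t1 <- obs[obs$trial_index == 1, ]
  expect_equal(nrow(t1), 5L)
  expect_equal(t1$n_since_reward, c(1L, 2L, 1L, 2L, 3L))
  expect_equal(t1$leave, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(t1$last_reward_position, c(1L, 1L, 4L, 4L, 4L))
  expect_equal(nrow(obs[obs$trial_index == 2, ]), 0L)  # reward-final trial
  t3 <- obs[obs$trial_index == 3, ]
  expect_equal(t3$n_since_reward, c(1L, 2L))
  expect_equal(t3$last_reward_position, c(0L, 0L))
  expect_equal(t3$leave, c(0L, 1L))
  # p_next carries the belief after each poke
  expect_equal(t3$p_next[1], next_reward_probability(0), tolerance = 1e-12)
  expect_equal(t3$p_next[2], next_reward_probability(c(0, 0)),
               tolerance = 1e-12)
})

test_that("error trials and rewarded pokes contribute no observations", {
  ss <- toy_sessions(list(
    list(outcomes = c(0, 0, 0), side = "L"),
    list(outcomes = c(0, 0), side = "L", correct = 0L)
  ))
  obs <- build_observations(ss)
  expect_equal(unique(obs$trial_index), 1L)
})

test_that("covariate-free fit equals the per-bin empirical leave fractions", {
  obs <- tibble::tibble(
    n_since_reward = rep(1:3, c(100, 60, 20)),
    leave = c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(30, 30)),
              rep(1, 20)),
    photostim = 0L, side = 0L, last_reward_position = 0L
  )
  expect_warning(
    expect_message(f <- fit_ph(obs), "constant"),
    "clamped"
  )
  expect_equal(f$baseline_hazard, c(0.10, 0.50, 1 - 1e-6), tolerance = 1e-6)
  expect_true(all(is.na(f$betas)))
  expect_equal(f$n_events, 60)

  # random covariate-free data: fitted baseline is the closed-form MLE
  set.seed(55)
  obs2 <- tibble::tibble(
    n_since_reward = sample(1:5, 2000, replace = TRUE,
                            prob = c(0.4, 0.3, 0.15, 0.1, 0.05)),
    photostim = 0L, side = 0L, last_reward_position = 0L
  )
  obs2$leave <- rbinom(2000, 1, plogis((obs2$n_since_reward - 3)))
  f2 <- suppressMessages(fit_ph(obs2))
  emp <- tapply(obs2$leave, pmin(obs2$n_since_reward, f2$n_cap), mean)
  expect_equal(unname(f2$baseline_hazard), as.vector(emp), tolerance = 1e-6)
})

test_that("degenerate observation sets are rejected", {
  obs <- tibble::tibble(n_since_reward = 1:5, leave = 1L, photostim = 0L,
                        side = 0L, last_reward_position = 0L)
  expect_error(fit_ph(obs), "at least one")
  obs$leave <- 0L
  expect_error(fit_ph(obs), "at least one")
})

test_that("hazard obeys the odds-scaling arithmetic", {
  f <- structure(
    list(baseline_hazard = c(0.1, 0.5), n_cap = 2L,
         betas = c(photostim = -log(2), side = log(3),
                   last_reward_position = 0)),
    class = "ph_fit"
  )
  expect_equal(hazard_of(f, 1), 0.1)
  expect_equal(hazard_of(f, 1, photostim = 1), 1 / 19, tolerance = 1e-12)
  expect_equal(hazard_of(f, 2, side = 1), 0.75, tolerance = 1e-12)
  # beyond the cap: top pooled bin
  expect_equal(hazard_of(f, 7), 0.5)
})

test_that("stimulation coefficient is recovered across the cohort", {
  fits <- ph_fits()
  truth <- ph_truth()
  bs <- vapply(fits, function(f) f$betas[["photostim"]], numeric(1))
  g <- truth$genotype[match(names(bs), truth$subject_id)]
  expect_lt(abs(mean(bs[g == "opsin"]) - (-0.3)), 0.05)
  expect_lt(mean(bs[g == "opsin"]), 0)
})

test_that("constant covariates are dropped and flagged", {
  obs <- build_observations(toy_sessions(lapply(1:30, function(i) {
    list(outcomes = rbinom(4, 1, 0.3), side = c("L", "R")[i %% 2 + 1])
  })))
  expect_message(f <- suppressWarnings(fit_ph(obs)), "photostim")
  expect_true(is.na(f$betas[["photostim"]]))
})

test_that("adding the true covariate never hurts in-sample likelihood", {
  ss <- ph_cohort()
  obs <- build_observations(ss)
  obs1 <- obs[obs$subject_id == "m01", ]
  with_cov <- suppressWarnings(suppressMessages(fit_ph(obs1)))
  without <- obs1
  without$photostim <- 0L
  no_cov <- suppressWarnings(suppressMessages(fit_ph(without,
                                                     n_cap = with_cov$n_cap)))
  expect_gte(with_cov$log_likelihood, no_cov$log_likelihood)
})

test_that("simulation from a flat-hazard fit is geometric", {
  f <- structure(
    list(baseline_hazard = rep(0.5, 3), n_cap = 3L,
         betas = c(photostim = 0, side = 0, last_reward_position = 0)),
    class = "ph_fit"
  )
  src <- sessions_from_outcomes(rep(strrep("0", 3), 10000))
  src$potential_outcomes <- strrep("0", 20)
  sim <- simulate_from_fit(f, src, seed = 61)
  expect_equal(mean(sim$n_pokes), 2.0, tolerance = 0.05)
  sim2 <- simulate_from_fit(f, src, seed = 61)
  expect_identical(as.data.frame(sim), as.data.frame(sim2))
})

test_that("fit-simulate-refit recovers the generating model", {
  fits <- ph_fits()
  f <- fits[["m01"]]
  src <- ph_cohort()
  src <- src[src$subject_id == "m01", ]
  sim <- simulate_from_fit(f, src, seed = 62, n_reps = 80)
  obs <- build_observations(
    sessions_from_outcomes(sim$outcomes, photostim = sim$photostim,
                           side = sim$side)
  )
  ref <- suppressWarnings(suppressMessages(fit_ph(obs, n_cap = f$n_cap)))
  expect_lt(max(abs(ref$baseline_hazard - f$baseline_hazard)), 0.03)
  expect_lt(abs(ref$betas[["photostim"]] - f$betas[["photostim"]]), 0.05)
})

test_that("the MVT-logistic fit recovers a belief-driven agent", {
  # fit on unfiltered trials: the more-than-two-pokes filter truncates the
  # decision process and would bias the recovered coefficients
  eq4 <- prepare_sessions(
    simulate_mvt_logistic_agent(config = generator_config(seed = 12)),
    min_pokes = 1
  )
  f <- fit_mvt_logistic(build_observations(eq4))
  expect_lt(abs(f$beta1 - (-8)) / 8, 0.15)
  expect_lt(abs(f$beta0 - 1), 0.15)
})

test_that("win-stay is flat for resetting agents, falling for belief agents", {
  ws_ph <- win_stay_curve(ph_cohort())
  ws_eq4 <- win_stay_curve(eq4_cohort())
  # resetting: staying after a reward is certain at every position
  expect_true(all(ws_ph$stay_prob == 1))
  expect_lt(abs(win_stay_slope(ws_ph)), 0.01)
  expect_lt(win_stay_slope(ws_eq4), -0.02)
})

test_that("model comparison scores held-out halves per subject", {
  ss <- ph_cohort()
  cm <- suppressWarnings(compare_models(
    ss[ss$subject_id %in% c("m01", "m02"), ]
  ))
  expect_equal(nrow(cm), 2L)
  expect_true(all(cm$ll_ph < 0 & cm$ll_mvt < 0))
  expect_true(all(cm$winner %in% c("ph", "mvt_logistic")))
})
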