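test_that("reward probability follows the decaying schedule with a hard cap", {
  sched <- reward_schedule()
  expect_equal(reward_probability(1, 3, sched), 1.0)
  expect_equal(reward_probability(6, 1, sched), 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(reward_probability(21, 2, sched), 0)
  # non-increasing in poke number for every type
  for (i in 1:3) {
    p <- reward_probability(1:25, i, sched)
    expect_true(all(diff(p) <= 0))
  }
  expect_error(reward_probability(1, 4, sched), "type_index")
  expect_error(reward_probability(0, 1, sched), ">= 1")
})

test_that("posterior over patch types matches hand-computed Bayes updates", {
  sched <- reward_schedule()
  expect_equal(posterior_over_types(integer(0), sched), rep(1 / 3, 3))
  expect_equal(posterior_over_types(1, sched), c(2, 3, 4) / 9,
               tolerance = 1e-12)
  expect_equal(posterior_over_types(0, sched), c(2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  # an omission is impossible when every type pays with certainty
  certain <- reward_schedule(scaling_factors = c(1, 1, 1),
                             decay_constant = 1e9)
  expect_error(posterior_over_types(0, certain), "zero likelihood")
  expect_error(posterior_over_types(rep(0, 21), sched), "longer")
})

test_that("posterior is a proper distribution for random histories", {
  sched <- reward_schedule()
  set.seed(401)
  for (i in 1:200) {
    h <- rbinom(sample(1:20, 1), 1, 0.4)
    post <- tryCatch(posterior_over_types(h, sched), error = function(e) NULL)
    if (is.null(post)) next
    expect_true(all(post >= 0))
    expect_equal(sum(post), 1, tolerance = 1e-12)
  }
})

test_that("next-reward probability matches hand enumeration and the schedule", {
  sched <- reward_schedule()
  expect_equal(next_reward_probability(integer(0), sched), 0.75)
  expect_equal(next_reward_probability(1, sched),
               exp(-0.2) * (0.25 + 0.5625 + 1) / 2.25, tolerance = 1e-12)
  expect_equal(next_reward_probability(0, sched),
               exp(-0.2) * (0.5 * 2 / 3 + 0.75 * 1 / 3), tolerance = 1e-12)
  # degenerate prior on one type reduces exactly to the schedule
  for (i in 1:3) {
    prior <- replace(rep(0, 3), i, 1)
    dsched <- reward_schedule(type_prior = prior)
    for (len in c(0, 3, 7)) {
      h <- rep(1, len)   # rewards are possible under every type
      expect_identical(next_reward_probability(h, dsched),
                       reward_probability(len + 1, i, dsched))
    }
  }
})

test_that("next-reward probability agrees with the brute-force oracle", {
  sched <- reward_schedule()
  set.seed(402)
  checked <- 0
  for (i in 1:300) {
    h <- rbinom(sample(0:20, 1), 1, 0.35)
    expected <- bf_next_reward(h, sched)
    if (!is.finite(expected)) next
    expect_equal(next_reward_probability(h, sched), expected,
                 tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 250)
})

test_that("run segmentation brackets omission stretches by rewards", {
  r <- segment_runs(c(1, 0, 0, 1, 0, 0, 0))
  expect_equal(r$n_omissions, c(0L, 2L, 3L))
  expect_equal(r$terminal, c("reward", "reward", "leave"))
  expect_equal(r$last_reward_position, c(0L, 1L, 4L))

  r <- segment_runs(c(0, 0, 0))
  expect_equal(r$n_omissions, 3L)
  expect_equal(r$terminal, "leave")

  r <- segment_runs(c(1, 1))
  expect_equal(r$n_omissions, c(0L, 0L, 0L))
  expect_equal(r$terminal, c("reward", "reward", "leave_after_reward"))

  expect_error(segment_runs(integer(0)), "no pokes")
})

test_that("segmentation round-trips pokes and has exactly one terminal run", {
  set.seed(403)
  for (i in 1:200) {
    o <- rbinom(sample(1:20, 1), 1, 0.4)
    r <- segment_runs(o)
    expect_equal(sum(r$n_omissions) + sum(o), length(o))
    expect_equal(sum(r$terminal %in% c("leave", "leave_after_reward")), 1L)
    expect_identical(r$run_index, seq_len(nrow(r)) - 1L)
  }
})

test_that("session preparation relabels, truncates, and filters trials", {
  # 80 alternating trials of 4 pokes, one 2-poke trial inserted at slot 5,
  # one side repeat at slot 10
  trials <- lapply(1:80, function(i) {
    list(outcomes = rep(0, 4), side = c("L", "R")[i %% 2 + 1])
  })
  trials[[5]]$outcomes <- rep(0, 2)
  trials[[10]]$side <- trials[[9]]$side
  ss <- toy_sessions(trials)
  prep <- prepare_sessions(ss)
  kept <- unique(prep$trial_index)
  expect_true(all(kept <= 60))           # truncated before the poke filter
  expect_false(5 %in% kept)              # two-poke trial dropped
  expect_equal(length(kept), 59)
  # alternation labels: trial 10 repeats trial 9's side -> error; trial 11
  # then shares trial 10's side -> also error; first trial correct by
  # convention
  lab <- prep[!duplicated(prep$trial_index), c("trial_index", "correct")]
  expect_equal(lab$correct[lab$trial_index == 10], 0L)
  expect_equal(lab$correct[lab$trial_index == 11], 0L)
  expect_equal(lab$correct[lab$trial_index == 1], 1L)
  expect_true(all(lab$correct[!lab$trial_index %in% c(10, 11)] == 1L))
})
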