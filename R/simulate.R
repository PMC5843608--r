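#' Ground-truth parameters of a synthetic foraging agent
#'
#' Parameterizes the generative agent used by [simulate_sessions()]: a
#' discrete-time baseline hazard of leaving (indexed by omissions since the
#' last reward), log-odds covariate coefficients that scale the hazard
#' multiplicatively on the odds scale, a duty-cycle model that couples poke
#' vigor to the latent hazard, and the timing distributions of the task.
#'
#' Individual subjects drawn by [simulate_sessions()] vary around these
#' values: each subject receives a frailty shift of the whole baseline
#' hazard on the log-odds scale (`subject_sd`), and opsin subjects receive
#' an individual stimulation coefficient drawn around `beta_stim`
#' (`beta_stim_sd`); control subjects have a stimulation coefficient of
#' exactly zero. Between-subject variability is what makes the across-mice
#' regressions of the analysis meaningful.
#'
#' @param baseline_hazard Vector of leaving probabilities for omission
#'   1, 2, ... since the last reward; positions beyond its length use the
#'   final value. Default: logistic in n with midpoint 6 and scale 1.5,
#'   capped at 15 — a rising hazard.
#' @param beta_stim Log-odds effect of photostimulation on the hazard
#'   (negative values mean longer staying).
#' @param beta_side Log-odds effect of poking at the right port.
#' @param beta_lastpos Log-odds effect per unit of the last-reward-position
#'   covariate.
#' @param subject_sd SD of the per-subject frailty shift of the baseline
#'   hazard (log-odds scale).
#' @param beta_stim_sd SD of the per-subject stimulation coefficient around
#'   `beta_stim` (opsin subjects only).
#' @param odc_intercept,odc_slope,odc_sd Omission-duty-cycle model: each
#'   poke's expected ODC is `odc_intercept - odc_slope * hazard`, with
#'   Gaussian noise `odc_sd`, clipped to (0, 1).
#' @param cycle_time_mean,cycle_time_sd Mean and SD (seconds, natural
#'   scale) of the log-normal poke cycle length; a poke's duration is
#'   `ODC * cycle` and its preceding inter-poke interval `(1 - ODC) * cycle`.
#' @param dwell_mean,dwell_sd Mean and SD (seconds) of the log-normal
#'   time-to-leave (last poke to ROI exit); draws exceeding `timeout` flag
#'   the trial as a timeout and are capped.
#' @param travel_mean,travel_sd Mean and SD (seconds) of the log-normal
#'   travel time between ports.
#' @param error_prob Probability that a trial is an error (revisit of the
#'   same port; always unrewarded, 1-2 pokes).
#' @param stim_fraction Fraction of correct trials that are photostimulated.
#' @param timeout Seconds of post-poke dwell after which a trial times out.
#'
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(baseline_hazard = stats::plogis((1:15 - 6) / 1.5),
                         beta_stim = -0.3,
                         beta_side = 0.1,
                         beta_lastpos = 0,
                         subject_sd = 0.5,
                         beta_stim_sd = 0.05,
                         odc_intercept = 0.9,
                         odc_slope = 0.5,
                         odc_sd = 0.03,
                         cycle_time_mean = 0.5,
                         cycle_time_sd = 0.15,
                         dwell_mean = 3.8,
                         dwell_sd = 2.0,
                         travel_mean = 3.32,
                         travel_sd = 1.70,
                         error_prob = 0.05,
                         stim_fraction = 0.5,
                         timeout = 10) {
  stopifnot(
    all(baseline_hazard > 0), all(baseline_hazard < 1),
    length(baseline_hazard) >= 1,
    odc_intercept > 0, odc_intercept < 1,
    odc_intercept - odc_slope > 0, odc_intercept - odc_slope < 1,
    cycle_time_mean > 0, dwell_mean > 0, travel_mean > 0,
    error_prob >= 0, error_prob < 1,
    stim_fraction >= 0, stim_fraction <= 1,
    timeout > 0
  )
  structure(as.list(environment()), class = "agent_params")
}

#' Configuration of a synthetic experiment
#'
#' Mirrors the study's cohort structure: opsin-expressing and control
#' subjects, a fixed number of daily sessions each, and a photostimulation
#' protocol (`"stim_poking"`: stimulation delivered while poking and
#' entering the hazard; `"stim_travel"`: stimulation flagged on trials but
#' affecting nothing, the ground truth for a travel-time null).
#'
#' @param n_opsin_subjects,n_control_subjects Cohort sizes.
#' @param sessions_per_subject,trials_per_session Session structure.
#' @param protocol `"stim_poking"` or `"stim_travel"`.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_opsin_subjects = 10,
                             n_control_subjects = 6,
                             sessions_per_subject = 10,
                             trials_per_session = 60,
                             protocol = c("stim_poking", "stim_travel"),
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  protocol <- match.arg(protocol)
  stopifnot(
    n_opsin_subjects >= 0, n_control_subjects >= 0,
    n_opsin_subjects + n_control_subjects >= 1,
    sessions_per_subject >= 1, trials_per_session >= 1
  )
  structure(
    list(
      n_opsin_subjects = as.integer(n_opsin_subjects),
      n_control_subjects = as.integer(n_control_subjects),
      sessions_per_subject = as.integer(sessions_per_subject),
      trials_per_session = as.integer(trials_per_session),
      protocol = protocol,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Log-normal draws parameterized by natural-scale mean and SD.
rlnorm_ms <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw a potential trial: the full 20-poke outcome sequence
#'
#' Samples the complete reward/omission sequence a patch of the given type
#' would deliver if the forager poked up to the schedule's cap. Outcome `n`
#' is Bernoulli with the schedule's per-poke reward probability. Uses R's
#' current random-number stream; call `set.seed()` for reproducibility.
#'
#' @param type_index Patch type 1..3.
#' @param schedule A [reward_schedule()].
#' @param n_trials Number of sequences to draw.
#'
#' @return An integer matrix with `max_pokes` rows and `n_trials` columns
#'   (a plain vector when `n_trials = 1`).
#' @export
generate_potential_trial <- function(type_index, schedule = reward_schedule(),
                                     n_trials = 1) {
  p <- reward_probability(seq_len(schedule$max_pokes), type_index, schedule)
  out <- matrix(stats::rbinom(schedule$max_pokes * n_trials, 1L, p),
                nrow = schedule$max_pokes)
  if (n_trials == 1) out[, 1] else out
}

# --- shared per-session machinery ------------------------------------------

# Trial-level scaffolding common to all agents: error flags, sides, types,
# stimulation flags, and the potential outcome matrix (reward probability is
# zero in error trials).
draw_trial_scaffold <- function(n_trials, schedule, error_prob, stim_fraction) {
  K <- schedule$max_pokes
  is_error <- c(FALSE, stats::rbinom(n_trials - 1L, 1L, error_prob) == 1L)
  correct <- as.integer(!is_error)
  start_side <- stats::rbinom(1L, 1L, 0.5)
  side01 <- (start_side + cumsum(correct)) %% 2L
  type <- sample.int(3L, n_trials, replace = TRUE, prob = schedule$type_prior)
  stim <- stats::rbinom(n_trials, 1L, stim_fraction) * correct
  P <- schedule$scaling_factors[type][col(matrix(0, K, n_trials))] *
    exp(-(seq_len(K) - 1) / schedule$decay_constant)
  P <- matrix(P, nrow = K)
  P[, is_error] <- 0
  O <- matrix(stats::rbinom(K * n_trials, 1L, as.vector(P)), nrow = K)
  list(is_error = is_error, correct = correct, side01 = side01, type = type,
       stim = stim, O = O)
}

# Position of each poke within its run (omissions since last reward + 1) and
# the index of the most recent reward before each poke (0 if none).
run_position_matrices <- function(O) {
  K <- nrow(O)
  Seq <- matrix(seq_len(K), K, ncol(O))
  LRincl <- apply(Seq * O, 2, cummax)
  LRincl <- matrix(LRincl, nrow = K)
  LRprev <- rbind(0L, LRincl[-K, , drop = FALSE])
  list(n_run = Seq - LRprev, last_reward = LRprev)
}

# First index where flag is TRUE, else K (the poke cap ends the trial).
first_true_or_cap <- function(flag) {
  K <- nrow(flag)
  hit <- apply(flag, 2, function(z) if (any(z)) which(z)[1L] else K)
  as.integer(hit)
}

# Subjective next-reward probability after each poke, for every trial of a
# potential-outcome matrix (columns). Element [k, t] is the probability that
# poke k+1 of trial t would be rewarded given outcomes 1..k.
belief_path_matrix <- function(O, schedule) {
  K <- nrow(O)
  nt <- ncol(O)
  pk <- vapply(1:3, function(i) reward_probability(seq_len(K), i, schedule),
               numeric(K))
  W <- array(0, dim = c(K, nt, 3))
  for (i in 1:3) {
    L <- ifelse(O == 1, pk[, i], 1 - pk[, i])
    CL <- apply(log(pmax(L, 1e-300)), 2, cumsum)
    W[, , i] <- schedule$type_prior[i] * exp(matrix(CL, nrow = K))
  }
  tot <- W[, , 1] + W[, , 2] + W[, , 3]
  p_next_type <- rbind(pk[-1, , drop = FALSE], 0)   # probability at poke k+1
  out <- matrix(0, K, nt)
  for (i in 1:3) out <- out + p_next_type[, i] * W[, , i] / tot
  out
}

# Assemble the poke-level tibble for one session. O and HAZ are
# max_pokes x n_trials matrices; lengths gives realized pokes per trial.
assemble_session <- function(subject_id, session_id, genotype, protocol,
                             scaffold, lengths, HAZ, agent, schedule) {
  K <- nrow(scaffold$O)
  nt <- length(lengths)
  cy <- matrix(rlnorm_ms(K * nt, agent$cycle_time_mean, agent$cycle_time_sd),
               K)
  odc <- matrix(stats::rnorm(K * nt, agent$odc_intercept -
                               agent$odc_slope * HAZ, agent$odc_sd), K)
  odc <- pmin(pmax(odc, 0.01), 0.99)
  dur <- odc * cy
  ipi <- (1 - odc) * cy
  cum <- apply(dur + ipi, 2, cumsum)
  cum <- matrix(cum, nrow = K)
  dwell_raw <- rlnorm_ms(nt, agent$dwell_mean, agent$dwell_sd)
  timeout <- as.integer(dwell_raw > agent$timeout)
  dwell <- pmin(dwell_raw, agent$timeout)
  travel <- rlnorm_ms(nt, agent$travel_mean, agent$travel_sd)
  span <- cum[cbind(lengths, seq_len(nt))] + dwell
  roi_enter <- cumsum(travel) + c(0, cumsum(span)[-nt])
  roi_exit <- roi_enter + span

  idx <- rep(seq_len(nt), lengths)
  k <- sequence(lengths)
  flat <- cbind(k, idx)
  out_t <- roi_enter[idx] + cum[flat]
  in_t <- out_t - dur[flat]
  tibble(
    subject_id = subject_id,
    session_id = session_id,
    genotype = genotype,
    protocol = protocol,
    trial_index = idx,
    trial_type = ifelse(scaffold$is_error[idx], NA_integer_,
                        scaffold$type[idx]),
    side = c("L", "R")[scaffold$side01[idx] + 1L],
    correct = scaffold$correct[idx],
    photostim = scaffold$stim[idx],
    roi_enter_s = round(roi_enter[idx], 6),
    roi_exit_s = round(roi_exit[idx], 6),
    timeout = timeout[idx],
    poke_index = as.integer(k),
    poke_in_s = round(in_t, 6),
    poke_out_s = round(out_t, 6),
    rewarded = as.integer(scaffold$O[flat]),
    potential_outcomes = apply(scaffold$O, 2, paste, collapse = "")[idx],
    true_hazard = HAZ[flat]
  )
}

subject_frame <- function(config) {
  n_sub <- config$n_opsin_subjects + config$n_control_subjects
  tibble(
    subject_id = sprintf("m%02d", seq_len(n_sub)),
    genotype = rep(c("opsin", "control"),
                   c(config$n_opsin_subjects, config$n_control_subjects))
  )
}

#' Simulate a cohort of proportional-hazards foraging agents
#'
#' Generates a full synthetic experiment: each subject forages with a
#' discrete-time hazard of leaving that rises with consecutive omissions,
#' resets after each reward, and is scaled on the odds scale by
#' photostimulation (opsin subjects only, under the `"stim_poking"`
#' protocol), port side, and the last-reward-position covariate. Poke
#' timing follows the duty-cycle model, so vigor carries information about
#' the latent hazard. Correct trials alternate sides; error trials repeat
#' the previous side and are never rewarded.
#'
#' @param agent An [agent_params()].
#' @param config A [generator_config()]; its seed drives all randomness.
#' @param schedule A [reward_schedule()].
#'
#' @return A poke-level tibble (see [write_sessions()] for the schema, plus
#'   the synthetic-truth columns `potential_outcomes` and `true_hazard`).
#'   The per-subject ground truth (frailty shift and stimulation
#'   coefficient) is attached as the `"ground_truth"` attribute.
#' @export
simulate_sessions <- function(agent = agent_params(), config,
                              schedule = reward_schedule()) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(config, "generator_config"))
  set.seed(config$seed)
  subs <- subject_frame(config)
  n_sub <- nrow(subs)
  shift <- stats::rnorm(n_sub, 0, agent$subject_sd)
  beta_stim_s <- ifelse(subs$genotype == "opsin",
                        stats::rnorm(n_sub, agent$beta_stim,
                                     agent$beta_stim_sd),
                        0)
  nm <- length(agent$baseline_hazard)
  stim_active <- config$protocol == "stim_poking"
  K <- schedule$max_pokes
  out <- vector("list", n_sub * config$sessions_per_subject)
  ii <- 0L
  for (s in seq_len(n_sub)) {
    eta0 <- stats::qlogis(agent$baseline_hazard) + shift[s]
    for (ses in seq_len(config$sessions_per_subject)) {
      sc <- draw_trial_scaffold(config$trials_per_session, schedule,
                                agent$error_prob, agent$stim_fraction)
      pos <- run_position_matrices(sc$O)
      eta <- matrix(eta0[pmin(pos$n_run, nm)], K) +
        agent$beta_lastpos * pos$last_reward
      covar <- beta_stim_s[s] * sc$stim * stim_active +
        agent$beta_side * sc$side01
      eta <- eta + matrix(covar, K, length(covar), byrow = TRUE)
      LAM <- stats::plogis(eta)
      U <- matrix(stats::runif(K * ncol(LAM)), K)
      len <- first_true_or_cap(sc$O == 0 & U < LAM)
      n_err <- sum(sc$is_error)
      if (n_err) len[sc$is_error] <- sample(1:2, n_err, replace = TRUE)
      ii <- ii + 1L
      out[[ii]] <- assemble_session(subs$subject_id[s],
                                    sprintf("s%02d", ses),
                                    subs$genotype[s], config$protocol,
                                    sc, len, LAM, agent, schedule)
    }
  }
  res <- bind_rows(out)
  attr(res, "ground_truth") <- tibble(
    subject_id = subs$subject_id, genotype = subs$genotype,
    beta_stim = beta_stim_s, baseline_shift = shift
  )
  res
}

#' Simulate threshold-rule (marginal value theorem) foraging agents
#'
#' Each agent tracks the subjective next-reward probability (Bayesian
#' belief over patch types) and leaves after the first omission at which
#' that probability drops below its threshold. Photostimulation flags are
#' assigned but have no behavioral effect. Per-subject threshold jitter
#' (`threshold_sd`) provides the between-subject variability that the
#' across-mice comparisons assume.
#'
#' @param threshold Leaving threshold on the next-reward probability.
#' @param schedule A [reward_schedule()].
#' @param config A [generator_config()].
#' @param agent An [agent_params()]; supplies timing parameters only.
#' @param threshold_sd SD of the per-subject threshold jitter.
#'
#' @return A poke-level tibble as in [simulate_sessions()].
#' @export
simulate_mvt_agent <- function(threshold = 0.3, schedule = reward_schedule(),
                               config, agent = agent_params(),
                               threshold_sd = 0.03) {
  stopifnot(threshold > 0, threshold < 1,
            inherits(config, "generator_config"))
  set.seed(config$seed)
  subs <- subject_frame(config)
  thr_s <- pmin(pmax(stats::rnorm(nrow(subs), threshold, threshold_sd),
                     1e-6), 1 - 1e-6)
  nm <- length(agent$baseline_hazard)
  K <- schedule$max_pokes
  out <- vector("list", nrow(subs) * config$sessions_per_subject)
  ii <- 0L
  for (s in seq_len(nrow(subs))) {
    for (ses in seq_len(config$sessions_per_subject)) {
      sc <- draw_trial_scaffold(config$trials_per_session, schedule,
                                agent$error_prob, agent$stim_fraction)
      pnext <- belief_path_matrix(sc$O, schedule)
      len <- first_true_or_cap(sc$O == 0 & pnext < thr_s[s])
      n_err <- sum(sc$is_error)
      if (n_err) len[sc$is_error] <- sample(1:2, n_err, replace = TRUE)
      pos <- run_position_matrices(sc$O)
      HAZ <- matrix(agent$baseline_hazard[pmin(pos$n_run, nm)], K)
      ii <- ii + 1L
      out[[ii]] <- assemble_session(subs$subject_id[s],
                                    sprintf("s%02d", ses),
                                    subs$genotype[s], config$protocol,
                                    sc, len, HAZ, agent, schedule)
    }
  }
  res <- bind_rows(out)
  attr(res, "ground_truth") <- tibble(
    subject_id = subs$subject_id, genotype = subs$genotype,
    threshold = thr_s
  )
  res
}

#' Simulate agents whose leaving follows the MVT-logistic rule
#'
#' A stochastic alternative to the hazard-resetting agent: after every poke
#' (rewarded or not) the agent leaves with probability given by a logistic
#' function of the subjective next-reward probability,
#' `odds(leave) = exp(beta0 + beta1 * P_rew(n + 1) + beta2 * side)`.
#' Because the belief declines over the whole trial rather than resetting
#' with rewards, these agents show a falling win-stay curve.
#'
#' @param beta0,beta1,beta2 Intercept, belief coefficient, and side
#'   coefficient on the log-odds of leaving.
#' @param schedule A [reward_schedule()].
#' @param config A [generator_config()].
#' @param agent An [agent_params()]; supplies timing parameters only.
#'
#' @return A poke-level tibble as in [simulate_sessions()].
#' @export
simulate_mvt_logistic_agent <- function(beta0 = 1, beta1 = -8, beta2 = 0,
                                        schedule = reward_schedule(),
                                        config, agent = agent_params()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subs <- subject_frame(config)
  K <- schedule$max_pokes
  out <- vector("list", nrow(subs) * config$sessions_per_subject)
  ii <- 0L
  for (s in seq_len(nrow(subs))) {
    for (ses in seq_len(config$sessions_per_subject)) {
      sc <- draw_trial_scaffold(config$trials_per_session, schedule,
                                agent$error_prob, agent$stim_fraction)
      pnext <- belief_path_matrix(sc$O, schedule)
      LAM <- stats::plogis(beta0 + beta1 * pnext +
                             matrix(beta2 * sc$side01, K,
                                    length(sc$side01), byrow = TRUE))
      U <- matrix(stats::runif(K * ncol(LAM)), K)
      len <- first_true_or_cap(U < LAM)
      n_err <- sum(sc$is_error)
      if (n_err) len[sc$is_error] <- sample(1:2, n_err, replace = TRUE)
      ii <- ii + 1L
      out[[ii]] <- assemble_session(subs$subject_id[s],
                                    sprintf("s%02d", ses),
                                    subs$genotype[s], config$protocol,
                                    sc, len, LAM, agent, schedule)
    }
  }
  res <- bind_rows(out)
  attr(res, "ground_truth") <- tibble(
    subject_id = subs$subject_id, genotype = subs$genotype,
    beta0 = beta0, beta1 = beta1, beta2 = beta2
  )
  res
}

#' Shuffling null: fresh reward sequences paired with observed trial lengths
#'
#' For each subject, draws fresh potential trials (types sampled from the
#' schedule's prior) and truncates each to a length sampled with
#' replacement from that subject's empirical distribution of correct-trial
#' lengths, destroying the coupling between a trial's reward structure and
#' when the forager left while preserving the length distribution. Poke
#' timing is resampled from the subject's marginal pools of durations,
#' inter-poke intervals, dwells and travels.
#'
#' @param sessions A poke-level session log.
#' @param schedule A [reward_schedule()].
#' @param seed Integer seed.
#'
#' @return A poke-level tibble with the same schema (photostimulation
#'   cleared; all trials correct).
#' @export
shuffle_dataset <- function(sessions, schedule = reward_schedule(), seed) {
  assert_sessions(sessions)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  sessions <- dplyr::filter(sessions, .data$correct == 1)
  if (!nrow(sessions)) stop("no correct trials to shuffle", call. = FALSE)
  out <- list()
  for (sid in unique(sessions$subject_id)) {
    dat <- sessions[sessions$subject_id == sid, ]
    dat <- dat[order(dat$session_id, dat$trial_index, dat$poke_index), ]
    key <- paste(dat$session_id, dat$trial_index)
    len_emp <- as.integer(table(key)[unique(key)])
    dur_pool <- dat$poke_out_s - dat$poke_in_s
    ipi_pool <- unlist(lapply(split(dat$poke_in_s - c(0, head(dat$poke_out_s, -1)),
                                    key), function(x) x[-1]), use.names = FALSE)
    ipi_pool <- ipi_pool[ipi_pool > 0]
    if (!length(ipi_pool)) ipi_pool <- 0.1
    last_rows <- !duplicated(key, fromLast = TRUE)
    dwell_pool <- pmax(dat$roi_exit_s[last_rows] - dat$poke_out_s[last_rows],
                       1e-3)
    genotype <- dat$genotype[1]
    protocol <- dat$protocol[1]

    nt <- length(len_emp)
    type <- sample.int(3L, nt, replace = TRUE, prob = schedule$type_prior)
    O <- vapply(type, function(ti) generate_potential_trial(ti, schedule),
                integer(schedule$max_pokes))
    O <- matrix(O, nrow = schedule$max_pokes)
    len <- sample(len_emp, nt, replace = TRUE)
    len <- pmin(len, schedule$max_pokes)

    idx <- rep(seq_len(nt), len)
    k <- sequence(len)
    dur <- sample(dur_pool, length(k), replace = TRUE)
    ipi <- sample(ipi_pool, length(k), replace = TRUE)
    dwell <- sample(dwell_pool, nt, replace = TRUE)
    travel <- rlnorm_ms(nt, 3.32, 1.7)
    step <- dur + ipi
    cum <- unlist(lapply(split(step, idx), cumsum), use.names = FALSE)
    span <- tapply(step, idx, sum) + dwell
    roi_enter <- cumsum(travel) + c(0, cumsum(span)[-nt])
    roi_exit <- roi_enter + span
    out_t <- roi_enter[idx] + cum
    side01 <- seq_len(nt) %% 2L

    out[[sid]] <- tibble(
      subject_id = sid, session_id = "shuffled", genotype = genotype,
      protocol = protocol, trial_index = idx,
      trial_type = type[idx],
      side = c("L", "R")[side01[idx] + 1L],
      correct = 1L, photostim = 0L,
      roi_enter_s = round(roi_enter[idx], 6),
      roi_exit_s = round(roi_exit[idx], 6),
      timeout = 0L,
      poke_index = as.integer(k),
      poke_in_s = round(out_t - dur, 6),
      poke_out_s = round(out_t, 6),
      rewarded = as.integer(O[cbind(k, idx)]),
      potential_outcomes = apply(O, 2, paste, collapse = "")[idx],
      true_hazard = NA_real_
    )
  }
  bind_rows(out)
}
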