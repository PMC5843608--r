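# Trial-level summary of the correct trials of a session log: one row per
# trial with pokes, rewards, final-poke duration, leaving belief, and the
# time/position of the last reward. Internal workhorse for the statistics.
trial_summary <- function(sessions, schedule) {
  assert_sessions(sessions)
  s <- sessions[sessions$correct == 1, ]
  if (!nrow(s)) stop("no correct trials", call. = FALSE)
  s <- s[order(s$subject_id, s$session_id, s$trial_index, s$poke_index), ]
  key <- factor(trial_key(s), levels = unique(trial_key(s)))
  p_leave <- vapply(split(s$rewarded, key), function(o) {
    bp <- belief_path(o, schedule)
    bp[length(bp)]
  }, numeric(1))
  lasts <- !duplicated(key, fromLast = TRUE)
  firsts <- !duplicated(key)
  lr_pos <- tapply(s$poke_index * s$rewarded, key, max)
  # time of the last reward relative to trial start (NA when unrewarded)
  lr_time <- vapply(split(seq_len(nrow(s)), key), function(ix) {
    rw <- ix[s$rewarded[ix] == 1]
    if (!length(rw)) return(NA_real_)
    s$poke_out_s[max(rw)] - s$roi_enter_s[ix[1]]
  }, numeric(1))
  tibble(
    subject_id = s$subject_id[firsts],
    session_id = s$session_id[firsts],
    trial_index = s$trial_index[firsts],
    genotype = s$genotype[firsts],
    trial_type = s$trial_type[firsts],
    photostim = s$photostim[firsts],
    side = s$side[firsts],
    timeout = s$timeout[firsts],
    roi_enter_s = s$roi_enter_s[firsts],
    roi_exit_s = s$roi_exit_s[firsts],
    n_pokes = as.integer(tapply(s$poke_index, key, max)),
    n_rewards = as.integer(tapply(s$rewarded, key, sum)),
    last_poke_out_s = s$poke_out_s[lasts],
    final_duration = (s$poke_out_s - s$poke_in_s)[lasts],
    p_leaving = unname(p_leave),
    last_reward_position = as.integer(lr_pos),
    last_reward_time = unname(lr_time)
  )
}

one_way_anova <- function(df, value) {
  fit <- stats::aov(stats::reformulate("factor(trial_type)", value), df)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = unname(tab$Df))
}

#' Per-patch-type statistics and the MVT optimality pattern
#'
#' Computes, for each patch type, the mean rewards per trial, the
#' theoretical maximum (the finite sum of the decaying schedule up to the
#' poke cap), the mean pokes per trial, and the mean subjective reward
#' probability at leaving, all as averages of subject means. One-way
#' ANOVAs across subject-by-type means test whether pokes and leaving
#' probability vary by type — a near-optimal forager pokes more in better
#' patches but leaves at a type-independent probability.
#'
#' @param sessions Prepared session log with known trial types (synthetic
#'   data, or supplied externally).
#' @param schedule A [reward_schedule()].
#'
#' @return A list of class `patch_summary`: `by_type` tibble (means across
#'   subjects and theoretical maxima), `anova_pokes`, `anova_leaving`
#'   (each `list(F, p, df)`), and `subject_means`.
#' @export
patch_statistics <- function(sessions, schedule = reward_schedule()) {
  tr <- trial_summary(sessions, schedule)
  tr <- tr[!is.na(tr$trial_type), ]
  sub <- tr %>%
    group_by(.data$subject_id, .data$trial_type) %>%
    summarise(pokes = mean(.data$n_pokes), rewards = mean(.data$n_rewards),
              p_leaving = mean(.data$p_leaving), .groups = "drop")
  n_sub <- length(unique(sub$subject_id))
  maxima <- schedule$scaling_factors *
    sum(exp(-(seq_len(schedule$max_pokes) - 1) / schedule$decay_constant))
  by_type <- sub %>%
    group_by(.data$trial_type) %>%
    summarise(mean_pokes = mean(.data$pokes),
              mean_rewards = mean(.data$rewards),
              mean_p_leaving = mean(.data$p_leaving), .groups = "drop") %>%
    mutate(max_rewards = maxima[.data$trial_type])
  if (n_sub >= 2) {
    anova_pokes <- one_way_anova(sub, "pokes")
    anova_leaving <- one_way_anova(sub, "p_leaving")
  } else {
    warning("fewer than 2 subjects: ANOVA omitted", call. = FALSE)
    anova_pokes <- anova_leaving <- NULL
  }
  structure(
    list(by_type = by_type, anova_pokes = anova_pokes,
         anova_leaving = anova_leaving, subject_means = sub,
         n_subjects = n_sub),
    class = "patch_summary"
  )
}

#' @export
print.patch_summary <- function(x, ...) {
  cat("<patch_summary>", x$n_subjects, "subjects\n")
  print(x$by_type)
  if (!is.null(x$anova_pokes)) {
    cat(sprintf("pokes/trial ANOVA:   F(%d,%d) = %.3f, p = %.4g\n",
                x$anova_pokes$df[1], x$anova_pokes$df[2], x$anova_pokes$F,
                x$anova_pokes$p))
    cat(sprintf("leaving-prob ANOVA:  F(%d,%d) = %.3f, p = %.4g\n",
                x$anova_leaving$df[1], x$anova_leaving$df[2],
                x$anova_leaving$F, x$anova_leaving$p))
  }
  invisible(x)
}

#' Reward rate at leaving vs. average reward rate
#'
#' The marginal value theorem's core equality: an optimal forager leaves a
#' patch when the instantaneous reward rate drops to the environment's
#' long-term average. The average rate is total rewards divided by total
#' session span (first ROI entry to last ROI exit, travel and error time
#' included), per session, averaged within subject. The rate at leaving is
#' each trial's subjective next-reward probability after the final poke
#' divided by the final poke's duration, averaged over trials then
#' subjects. A Wilcoxon signed-rank test compares the two across subjects.
#'
#' @param sessions Prepared session log.
#' @param schedule A [reward_schedule()].
#'
#' @return A list of class `rate_comparison`: `average_rate`,
#'   `rate_at_leaving` (grand means, rewards/s), `per_subject` tibble,
#'   `test` (signed-rank statistic and p-value).
#' @export
reward_rate_comparison <- function(sessions, schedule = reward_schedule()) {
  assert_sessions(sessions)
  tr <- trial_summary(sessions, schedule)
  if (any(tr$final_duration <= 0)) {
    stop("zero-duration final poke encountered", call. = FALSE)
  }
  span <- sessions %>%
    group_by(.data$subject_id, .data$session_id) %>%
    summarise(span = max(.data$roi_exit_s) - min(.data$roi_enter_s),
              .groups = "drop")
  avg <- tr %>%
    group_by(.data$subject_id, .data$session_id) %>%
    summarise(rewards = sum(.data$n_rewards), .groups = "drop") %>%
    left_join(span, by = c("subject_id", "session_id")) %>%
    group_by(.data$subject_id) %>%
    summarise(average_rate = mean(.data$rewards / .data$span),
              .groups = "drop")
  leaving <- tr %>%
    group_by(.data$subject_id) %>%
    summarise(rate_at_leaving = mean(.data$p_leaving / .data$final_duration),
              .groups = "drop")
  per_subject <- left_join(avg, leaving, by = "subject_id")
  test <- if (nrow(per_subject) >= 2) {
    wt <- stats::wilcox.test(per_subject$rate_at_leaving,
                             per_subject$average_rate, paired = TRUE,
                             exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    NULL
  }
  structure(
    list(average_rate = mean(per_subject$average_rate),
         rate_at_leaving = mean(per_subject$rate_at_leaving),
         per_subject = per_subject, test = test),
    class = "rate_comparison"
  )
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("<rate_comparison>\n")
  cat(sprintf("  average reward rate:  %.4f rewards/s\n", x$average_rate))
  cat(sprintf("  rate at leaving:      %.4f rewards/s\n", x$rate_at_leaving))
  if (!is.null(x$test)) {
    cat(sprintf("  signed-rank p = %.4g (n = %d subjects)\n", x$test$p,
                nrow(x$per_subject)))
  }
  invisible(x)
}

#' Photostimulation effect summary
#'
#' The battery of stimulation analyses: per-subject difference in pokes per
#' trial (stimulated minus control), the opsin-vs-control rank-sum
#' comparison of those differences, a regression of pokes on the trial's
#' position within a streak of same-condition trials (a carry-over check),
#' time-to-leave (T1: last poke to ROI exit) and travel (T2: ROI exit to
#' next ROI entry) by condition with paired signed-rank tests, the
#' per-condition fraction of trials excluded from the travel analysis
#' (error-adjacent or timed out), and the constancy check: the correlation
#' between a trial's last-reward time and the stimulation effect on
#' subsequent poking (stimulated-trial residuals from a control-trial
#' regression of post-reward pokes on last-reward time).
#'
#' @param sessions Prepared session log carrying a `protocol` column.
#' @param schedule A [reward_schedule()] (for the trial summaries).
#' @param max_streak Streak lengths included in the sequence-length
#'   regression.
#'
#' @return A list of class `stim_effect_summary`; see the fields set below.
#' @export
stim_effect_summary <- function(sessions, schedule = reward_schedule(),
                                max_streak = 5) {
  assert_sessions(sessions)
  if (!"protocol" %in% names(sessions) || anyNA(sessions$protocol)) {
    stop("`sessions` must carry a protocol column", call. = FALSE)
  }
  tr <- trial_summary(sessions, schedule)
  tr$t1 <- tr$roi_exit_s - tr$last_poke_out_s

  subjects <- tr %>%
    group_by(.data$subject_id) %>%
    summarise(genotype = first(.data$genotype), .groups = "drop")

  delta <- tr %>%
    group_by(.data$subject_id, .data$genotype) %>%
    summarise(
      delta_pokes = mean(.data$n_pokes[.data$photostim == 1]) -
        mean(.data$n_pokes[.data$photostim == 0]),
      t1_stim = mean(.data$t1[.data$photostim == 1]),
      t1_control = mean(.data$t1[.data$photostim == 0]),
      .groups = "drop"
    )
  group_test <- if (length(unique(delta$genotype)) == 2) {
    wt <- stats::wilcox.test(delta_pokes ~ genotype, data = delta,
                             exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    NULL
  }

  # streak position: consecutive same-condition correct trials
  tr <- tr %>%
    group_by(.data$subject_id, .data$session_id) %>%
    arrange(.data$trial_index, .by_group = TRUE) %>%
    mutate(
      streak_id = cumsum(c(1L, diff(.data$photostim) != 0)),
      streak_pos = stats::ave(rep(1L, n()),
                              .data$streak_id, FUN = cumsum)
    ) %>%
    ungroup()
  seq_df <- tr[tr$streak_pos <= max_streak, ]
  seq_fml <- if (length(unique(seq_df$subject_id)) > 1) {
    n_pokes ~ streak_pos + factor(subject_id)
  } else {
    n_pokes ~ streak_pos
  }
  seq_fit <- stats::lm(seq_fml, data = seq_df)
  sc <- summary(seq_fit)$coefficients
  sequence_regression <- list(slope = sc["streak_pos", "Estimate"],
                              p = sc["streak_pos", "Pr(>|t|)"])

  # travel: requires current and next trials correct, no timeout
  tr2 <- tr %>%
    group_by(.data$subject_id, .data$session_id) %>%
    arrange(.data$trial_index, .by_group = TRUE) %>%
    mutate(
      next_enter = dplyr::lead(.data$roi_enter_s),
      next_contiguous = dplyr::lead(.data$trial_index) ==
        .data$trial_index + 1L,
      t2 = .data$next_enter - .data$roi_exit_s,
      t2_ok = !is.na(.data$next_contiguous) & .data$next_contiguous &
        .data$timeout == 0
    ) %>%
    ungroup()
  t2_by <- tr2 %>%
    group_by(.data$subject_id, .data$photostim) %>%
    summarise(t2 = mean(.data$t2[.data$t2_ok]),
              excluded_fraction = mean(!.data$t2_ok), .groups = "drop")

  paired_test <- function(stim_vals, control_vals) {
    if (length(stim_vals) < 2) return(NULL)
    wt <- stats::wilcox.test(stim_vals, control_vals, paired = TRUE,
                             exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  t1_test <- paired_test(delta$t1_stim, delta$t1_control)
  t2_wide <- t2_by %>%
    dplyr::summarise(
      t2_stim = .data$t2[.data$photostim == 1],
      t2_control = .data$t2[.data$photostim == 0],
      .by = "subject_id"
    )
  t2_test <- paired_test(t2_wide$t2_stim, t2_wide$t2_control)

  # constancy of the stimulation effect across the trial: stimulated-trial
  # residuals from each subject's control-trial regression of post-reward
  # pokes on last-reward time, pooled and correlated with that time.
  lr <- tr[!is.na(tr$last_reward_time), ]
  lr$post_pokes <- lr$n_pokes - lr$last_reward_position
  resids <- list()
  for (sid in unique(lr$subject_id)) {
    d <- lr[lr$subject_id == sid, ]
    ctrl <- d[d$photostim == 0, ]
    stim <- d[d$photostim == 1, ]
    if (nrow(ctrl) < 5 || nrow(stim) < 5) next
    cf <- stats::lm(post_pokes ~ last_reward_time, data = ctrl)
    stim$resid <- stim$post_pokes - stats::predict(cf, stim)
    resids[[sid]] <- stim[, c("last_reward_time", "resid")]
  }
  resids <- bind_rows(resids)
  last_reward_cor <- if (nrow(resids) >= 10) {
    ct <- stats::cor.test(resids$last_reward_time, resids$resid)
    list(r = unname(ct$estimate), p = ct$p.value)
  } else {
    NULL
  }

  structure(
    list(
      per_subject = delta,
      group_test = group_test,
      sequence_regression = sequence_regression,
      t1_stim = mean(delta$t1_stim), t1_control = mean(delta$t1_control),
      t1_test = t1_test,
      t2_stim = mean(t2_wide$t2_stim), t2_control = mean(t2_wide$t2_control),
      t2_test = t2_test,
      excluded_fractions = t2_by[, c("subject_id", "photostim",
                                     "excluded_fraction")],
      last_reward_cor = last_reward_cor
    ),
    class = "stim_effect_summary"
  )
}

#' @export
print.stim_effect_summary <- function(x, ...) {
  cat("<stim_effect_summary>\n")
  d <- x$per_subject
  for (g in unique(d$genotype)) {
    cat(sprintf("  delta pokes (stim - control), %s: %.3f (n = %d)\n", g,
                mean(d$delta_pokes[d$genotype == g]),
                sum(d$genotype == g)))
  }
  if (!is.null(x$group_test)) {
    cat(sprintf("  opsin vs control rank-sum p = %.4g\n", x$group_test$p))
  }
  cat(sprintf("  sequence-length slope = %.4f (p = %.3g)\n",
              x$sequence_regression$slope, x$sequence_regression$p))
  cat(sprintf("  T1 stim %.2f s vs control %.2f s (p = %.3g)\n",
              x$t1_stim, x$t1_control,
              if (is.null(x$t1_test)) NA else x$t1_test$p))
  cat(sprintf("  T2 stim %.2f s vs control %.2f s (p = %.3g)\n",
              x$t2_stim, x$t2_control,
              if (is.null(x$t2_test)) NA else x$t2_test$p))
  if (!is.null(x$last_reward_cor)) {
    cat(sprintf("  last-reward-time vs stim-effect r = %.4f (p = %.3g)\n",
                x$last_reward_cor$r, x$last_reward_cor$p))
  }
  invisible(x)
}

#' Tune a threshold agent to its own realized average reward rate
#'
#' The marginal value theorem equates the instantaneous reward probability
#' at leaving with the environment's average reward rate (times the cost of
#' a poke, here the mean final-poke duration, to convert rewards/s into a
#' probability). This routine finds that self-consistent operating point by
#' fixed-point iteration: simulate a threshold agent, measure its realized
#' average rate and mean final-poke duration, reset the threshold to their
#' product, repeat; then evaluate the tuned agent on a fresh seed. At the
#' fixed point the rate at leaving matches the average rate.
#'
#' @param config A [generator_config()]; iteration `i` uses `seed + i`.
#' @param schedule A [reward_schedule()].
#' @param agent An [agent_params()] supplying timing parameters.
#' @param threshold_init Starting threshold.
#' @param n_iter Fixed-point iterations.
#' @param threshold_sd Per-subject threshold jitter (see
#'   [simulate_mvt_agent()]).
#'
#' @return A list: the tuned `threshold`, the evaluation run's
#'   `average_rate`, `rate_at_leaving`, their `relative_gap`, and the full
#'   [reward_rate_comparison()] of the evaluation run.
#' @export
mvt_self_consistency <- function(config, schedule = reward_schedule(),
                                 agent = agent_params(),
                                 threshold_init = 0.3, n_iter = 3,
                                 threshold_sd = 0.03) {
  stopifnot(inherits(config, "generator_config"))
  reseed <- function(k) {
    generator_config(config$n_opsin_subjects, config$n_control_subjects,
                     config$sessions_per_subject, config$trials_per_session,
                     config$protocol, seed = config$seed + k)
  }
  run <- function(thr, k) {
    ss <- prepare_sessions(simulate_mvt_agent(thr, schedule, reseed(k),
                                              agent, threshold_sd))
    tr <- trial_summary(ss, schedule)
    list(rc = reward_rate_comparison(ss, schedule),
         final_dur = mean(tr$final_duration))
  }
  thr <- threshold_init
  for (i in seq_len(n_iter)) {
    r <- run(thr, i)
    thr <- r$rc$average_rate * r$final_dur
  }
  ev <- run(thr, n_iter + 1L)
  gap <- abs(ev$rc$rate_at_leaving - ev$rc$average_rate) /
    ev$rc$average_rate
  list(threshold = thr, average_rate = ev$rc$average_rate,
       rate_at_leaving = ev$rc$rate_at_leaving, relative_gap = gap,
       comparison = ev$rc)
}
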