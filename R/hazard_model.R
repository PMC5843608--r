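#' Build stay/leave decision observations from session logs
#'
#' One observation per omission poke of each correct trial: the Bernoulli
#' rows the discrete-time leaving models are fit on. Rewarded pokes carry
#' no stay/leave outcome (leaving decisions are only defined after
#' omissions), so trials whose final poke was rewarded contribute stay rows
#' but no leave event; error trials are excluded entirely.
#'
#' @param sessions A prepared poke-level session log (see
#'   [prepare_sessions()]).
#' @param schedule A [reward_schedule()]; used to compute each
#'   observation's subjective next-reward probability `p_next` (the
#'   belief for the hypothetical next poke, given the trial history up to
#'   and including the current poke).
#' @param censor_cap If `TRUE` (default), a trial-final omission at the
#'   schedule's poke cap is censored rather than scored as a leave: when a
#'   simulated trial is terminated mechanically at the cap, the trial ends
#'   whichever way the final stay/leave decision went, so that decision is
#'   unobservable and its likelihood contribution is 1. Earlier rows of the
#'   trial are kept.
#'
#' @return A tibble with one row per omission poke: `subject_id`,
#'   `session_id`, `trial_index`, `poke_index`, `n_since_reward` (position
#'   within the current run), `leave` (1 only for the final omission of an
#'   omission-terminated trial), `last_reward_position` (0 if none yet),
#'   `side` (0 = L, 1 = R), `photostim`, and `p_next`.
#' @export
build_observations <- function(sessions, schedule = reward_schedule(),
                               censor_cap = TRUE) {
  assert_sessions(sessions)
  s <- sessions[sessions$correct == 1, ]
  if (!nrow(s)) {
    stop("no correct trials; did you run prepare_sessions()?", call. = FALSE)
  }
  s <- s[order(s$subject_id, s$session_id, s$trial_index, s$poke_index), ]
  key <- trial_key(s)
  lr_incl <- stats::ave(s$poke_index * s$rewarded, key, FUN = cummax)
  is_last <- !duplicated(key, fromLast = TRUE)
  p_next <- unlist(lapply(split(s$rewarded, factor(key, levels = unique(key))),
                          belief_path, schedule = schedule),
                   use.names = FALSE)
  keep <- s$rewarded == 0
  if (censor_cap) {
    keep <- keep & !(is_last & s$poke_index >= schedule$max_pokes)
  }
  tibble(
    subject_id = s$subject_id[keep],
    session_id = s$session_id[keep],
    trial_index = s$trial_index[keep],
    poke_index = s$poke_index[keep],
    n_since_reward = as.integer(s$poke_index - lr_incl)[keep],
    leave = as.integer(is_last[keep]),
    last_reward_position = as.integer(lr_incl)[keep],
    side = as.integer(s$side == "R")[keep],
    photostim = as.integer(s$photostim)[keep],
    p_next = p_next[keep]
  )
}

PROB_CLAMP <- 1e-6

clamp_prob <- function(p) pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)

# Choose the top pooled baseline bin: the first position with fewer than
# min_bin observations opens the pooled bin; the pool is widened downward
# until it holds at least min_bin observations.
choose_n_cap <- function(n_since, min_bin) {
  max_n <- max(n_since)
  counts <- tabulate(n_since, nbins = max_n)
  small <- which(counts < min_bin)
  if (!length(small)) return(max_n)
  m <- small[1]
  while (m > 1 && sum(counts[m:max_n]) < min_bin) m <- m - 1L
  as.integer(m)
}

#' Fit the discrete-time proportional-hazards leaving model
#'
#' Maximum-likelihood logistic regression of the per-omission leave
#' indicator on a one-hot baseline over the omission's position within its
#' run (positions above the cap are pooled into the top bin) plus the three
#' scalar covariates: photostimulation, side, and last-reward position. On
#' the odds scale the covariates scale the baseline hazard
#' multiplicatively, which is the discrete-time Cox proportional-hazards
#' model. With no informative covariates the fitted baseline equals the
#' per-bin empirical leave fraction exactly (the closed-form Bernoulli
#' MLE). Covariates that are constant in the data are dropped with a
#' message and reported as `NA`. Perfect separation is handled by clamping
#' fitted baseline probabilities to `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param observations Output of [build_observations()].
#' @param min_bin Minimum observations per baseline bin before pooling into
#'   the top bin.
#' @param n_cap Optional explicit top bin; overrides the pooling rule.
#'
#' @return An object of class `ph_fit`: `baseline_hazard` (probabilities
#'   for run positions `1..n_cap`), `betas` (named coefficients), `n_cap`,
#'   `log_likelihood`, `n_observations`, `n_events`.
#' @export
fit_ph <- function(observations, min_bin = 5, n_cap = NULL) {
  obs <- observations
  stopifnot(all(c("n_since_reward", "leave") %in% names(obs)))
  if (all(obs$leave == 1) || all(obs$leave == 0)) {
    stop("need at least one leave event and one stay to fit", call. = FALSE)
  }
  if (is.null(n_cap)) n_cap <- choose_n_cap(obs$n_since_reward, min_bin)
  nbin <- factor(pmin(obs$n_since_reward, n_cap), levels = seq_len(n_cap))
  covs <- c("photostim", "side", "last_reward_position")
  covs_in <- covs[vapply(covs, function(v) {
    v %in% names(obs) && stats::var(obs[[v]]) > 0
  }, logical(1))]
  dropped <- setdiff(covs, covs_in)
  if (length(dropped)) {
    message("dropping constant/absent covariate(s): ",
            paste(dropped, collapse = ", "))
  }
  df <- data.frame(leave = obs$leave, nbin = nbin,
                   obs[intersect(covs_in, names(obs))])
  fml <- stats::reformulate(c("0", "nbin", covs_in), response = "leave")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  lam0 <- stats::plogis(unname(cf[paste0("nbin", seq_len(n_cap))]))
  if (anyNA(lam0)) {
    stop("empty baseline bin below the cap; supply `n_cap` explicitly",
         call. = FALSE)
  }
  clamped <- lam0 < PROB_CLAMP | lam0 > 1 - PROB_CLAMP
  lam0 <- clamp_prob(lam0)
  if (separated || any(clamped)) {
    warning("separation in baseline bins; probabilities clamped to [",
            PROB_CLAMP, ", ", 1 - PROB_CLAMP, "]", call. = FALSE)
  }
  betas <- stats::setNames(rep(NA_real_, length(covs)), covs)
  betas[covs_in] <- unname(cf[covs_in])
  out <- structure(
    list(baseline_hazard = lam0, betas = betas, n_cap = as.integer(n_cap),
         log_likelihood = NA_real_, n_observations = nrow(obs),
         n_events = sum(obs$leave)),
    class = "ph_fit"
  )
  p <- predict_hazard(out, obs)
  out$log_likelihood <- sum(obs$leave * log(p) + (1 - obs$leave) * log(1 - p))
  out
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("<ph_fit> discrete-time proportional-hazards leaving model\n")
  cat("  baseline hazard (n = 1..", x$n_cap, "): ",
      paste(signif(x$baseline_hazard, 3), collapse = ", "), "\n", sep = "")
  cat("  betas:", paste(names(x$betas), signif(x$betas, 3), sep = " = ",
                        collapse = ", "), "\n")
  cat("  log-likelihood", signif(x$log_likelihood, 6), "on",
      x$n_observations, "observations (", x$n_events, "leave events )\n")
  invisible(x)
}

#' Hazard of leaving implied by a fitted model
#'
#' The covariates scale the baseline odds:
#' `odds(lambda) = exp(beta . x) * odds(lambda0(n))`. Positions beyond the
#' fit's cap use the top pooled bin.
#'
#' @param fit A `ph_fit`.
#' @param n Run position(s): omissions since the last reward (>= 1).
#' @param photostim,side,last_reward_position Covariate values (recycled).
#'
#' @return Vector of probabilities.
#' @export
hazard_of <- function(fit, n, photostim = 0, side = 0,
                      last_reward_position = 0) {
  stopifnot(inherits(fit, "ph_fit"), all(n >= 1))
  b <- ifelse(is.na(fit$betas), 0, fit$betas)
  eta <- stats::qlogis(fit$baseline_hazard[pmin(n, fit$n_cap)]) +
    b[["photostim"]] * photostim + b[["side"]] * side +
    b[["last_reward_position"]] * last_reward_position
  clamp_prob(stats::plogis(eta))
}

#' Fit the MVT-logistic alternative leaving model
#'
#' Logistic regression of the leave indicator on the subjective next-reward
#' probability and side:
#' `odds(leave) = exp(beta0 + beta1 * p_next + beta2 * side)`. This is the
#' stochastic formulation of the marginal value theorem's prediction that
#' leaving is governed by the instantaneous (belief-based) reward
#' probability, with no reward resetting.
#'
#' @param observations Output of [build_observations()] (must carry
#'   `p_next`).
#'
#' @return An object of class `mvt_logistic_fit` with `beta0`, `beta1`,
#'   `beta2`, `log_likelihood`, `n_observations`.
#' @export
fit_mvt_logistic <- function(observations) {
  obs <- observations
  stopifnot(all(c("p_next", "leave", "side") %in% names(obs)))
  if (all(obs$leave == 1) || all(obs$leave == 0)) {
    stop("need at least one leave event and one stay to fit", call. = FALSE)
  }
  has_side <- stats::var(obs$side) > 0
  fml <- if (has_side) leave ~ p_next + side else leave ~ p_next
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = obs,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  cf <- stats::coef(fit)
  out <- structure(
    list(beta0 = unname(cf[["(Intercept)"]]),
         beta1 = unname(cf[["p_next"]]),
         beta2 = if (has_side) unname(cf[["side"]]) else NA_real_,
         log_likelihood = NA_real_, n_observations = nrow(obs)),
    class = "mvt_logistic_fit"
  )
  p <- predict_hazard(out, obs)
  out$log_likelihood <- sum(obs$leave * log(p) + (1 - obs$leave) * log(1 - p))
  out
}

#' @export
print.mvt_logistic_fit <- function(x, ...) {
  cat("<mvt_logistic_fit> leave ~ subjective next-reward probability\n")
  cat("  beta0 =", signif(x$beta0, 4), " beta1 =", signif(x$beta1, 4),
      " beta2 (side) =", signif(x$beta2, 4), "\n")
  cat("  log-likelihood", signif(x$log_likelihood, 6), "on",
      x$n_observations, "observations\n")
  invisible(x)
}

#' Per-observation leave probability under a fitted model
#'
#' @param fit A `ph_fit` or `mvt_logistic_fit`.
#' @param observations Observation rows as from [build_observations()].
#' @return Vector of clamped probabilities.
#' @export
predict_hazard <- function(fit, observations) UseMethod("predict_hazard")

#' @export
predict_hazard.ph_fit <- function(fit, observations) {
  hazard_of(fit, observations$n_since_reward, observations$photostim,
            observations$side, observations$last_reward_position)
}

#' @export
predict_hazard.mvt_logistic_fit <- function(fit, observations) {
  b2 <- if (is.na(fit$beta2)) 0 else fit$beta2
  clamp_prob(stats::plogis(fit$beta0 + fit$beta1 * observations$p_next +
                             b2 * observations$side))
}

# potential outcome matrix (max_pokes x n_trials) for the correct trials of
# a session log: the stored full sequence when available, otherwise the
# observed outcomes extended by sampling from the posterior predictive.
potential_matrix <- function(trials, schedule) {
  K <- schedule$max_pokes
  if (!is.null(trials$potential_outcomes) &&
      !anyNA(trials$potential_outcomes)) {
    O <- vapply(strsplit(trials$potential_outcomes, ""),
                function(x) as.integer(x), integer(K))
    return(matrix(O, nrow = K))
  }
  vapply(trials$outcomes, function(o) {
    o <- as.integer(o)
    while (length(o) < K) {
      p <- next_reward_probability(o, schedule)
      o <- c(o, stats::rbinom(1L, 1L, p))
    }
    o
  }, integer(K))
}

trial_scaffold_from_sessions <- function(sessions) {
  s <- sessions[sessions$correct == 1, ]
  s <- s[order(s$subject_id, s$session_id, s$trial_index, s$poke_index), ]
  key <- factor(trial_key(s), levels = unique(trial_key(s)))
  firsts <- !duplicated(key)
  tibble(
    subject_id = s$subject_id[firsts],
    session_id = s$session_id[firsts],
    trial_index = s$trial_index[firsts],
    genotype = s$genotype[firsts],
    photostim = s$photostim[firsts],
    side = as.integer(s$side == "R")[firsts],
    potential_outcomes = if ("potential_outcomes" %in% names(s)) {
      s$potential_outcomes[firsts]
    } else {
      rep(NA_character_, sum(firsts))
    },
    outcomes = unname(split(as.integer(s$rewarded), key)),
    n_pokes_source = as.integer(table(key))
  )
}

#' Simulate leaving decisions from a fitted model
#'
#' Replays each correct trial's potential outcome sequence through the
#' fitted decision rule as a sequence of probabilistic coin flips: under a
#' `ph_fit`, a leave decision is taken after each omission with the
#' model's hazard (run position resets after rewards) and the trial ends at
#' the first leave or at the poke cap; under an `mvt_logistic_fit` the
#' decision follows every poke, driven by the subjective next-reward
#' probability. Covariates (photostimulation, side) are taken from the
#' source trials. When the source log carries the full potential sequences
#' (synthetic data) they are reused; otherwise observed outcomes are
#' extended by posterior-predictive sampling.
#'
#' @param fit A `ph_fit` or `mvt_logistic_fit`.
#' @param sessions Source session log supplying the potential trials.
#' @param schedule A [reward_schedule()].
#' @param seed Integer seed.
#' @param n_reps Simulated replicates per source trial.
#'
#' @return A trial-level tibble: source trial identifiers, covariates,
#'   replicate number, simulated `n_pokes` and `n_rewards`, and the source
#'   trial's observed length `n_pokes_source`.
#' @export
simulate_from_fit <- function(fit, sessions, schedule = reward_schedule(),
                              seed, n_reps = 1) {
  stopifnot(inherits(fit, "ph_fit") || inherits(fit, "mvt_logistic_fit"))
  assert_sessions(sessions)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  trials <- trial_scaffold_from_sessions(sessions)
  O <- potential_matrix(trials, schedule)
  K <- nrow(O)
  nt <- ncol(O)
  if (inherits(fit, "ph_fit")) {
    pos <- run_position_matrices(O)
    LAM <- matrix(hazard_of(
      fit,
      n = as.vector(pos$n_run),
      photostim = rep(trials$photostim, each = K),
      side = rep(trials$side, each = K),
      last_reward_position = as.vector(pos$last_reward)
    ), nrow = K)
    omission_only <- TRUE
  } else {
    pnext <- belief_path_matrix(O, schedule)
    LAM <- matrix(predict_hazard(fit, tibble(
      p_next = as.vector(pnext),
      side = rep(trials$side, each = K)
    )), nrow = K)
    omission_only <- FALSE
  }
  reps <- lapply(seq_len(n_reps), function(r) {
    U <- matrix(stats::runif(K * nt), K)
    flag <- if (omission_only) (O == 0) & (U < LAM) else U < LAM
    len <- first_true_or_cap(flag)
    tibble(
      subject_id = trials$subject_id,
      session_id = trials$session_id,
      trial_index = trials$trial_index,
      genotype = trials$genotype,
      photostim = trials$photostim,
      side = trials$side,
      rep = r,
      n_pokes = len,
      n_rewards = colSums(O * (row(O) <= rep(len, each = K))),
      outcomes = substr(apply(O, 2, paste, collapse = ""), 1, len),
      n_pokes_source = trials$n_pokes_source
    )
  })
  bind_rows(reps)
}

#' Cross-validated comparison of the two leaving models
#'
#' For each subject, both models are fit on a training half of the trials
#' and scored by mean held-out log-likelihood per observation on the test
#' half; the model with the larger score wins. The default split is
#' deterministic odd/even by trial index.
#'
#' @param sessions Prepared session log.
#' @param schedule A [reward_schedule()].
#' @param split `"odd_even"`: odd trial indices train, even test.
#'
#' @return A tibble with one row per subject: held-out scores `ll_ph` and
#'   `ll_mvt` (mean log-likelihood per observation) and the `winner`.
#'   Subjects whose halves are degenerate (no events, or no variation) are
#'   skipped with a warning.
#' @export
compare_models <- function(sessions, schedule = reward_schedule(),
                           split = "odd_even") {
  split <- match.arg(split)
  assert_sessions(sessions)
  obs_all <- build_observations(sessions, schedule)
  out <- list()
  for (sid in unique(obs_all$subject_id)) {
    obs <- obs_all[obs_all$subject_id == sid, ]
    train <- obs[obs$trial_index %% 2 == 1, ]
    test <- obs[obs$trial_index %% 2 == 0, ]
    ok <- nrow(train) > 0 && nrow(test) > 0 &&
      any(train$leave == 1) && any(train$leave == 0) &&
      any(test$leave == 1) && any(test$leave == 0)
    if (!ok) {
      warning("subject ", sid, " skipped: degenerate train/test half",
              call. = FALSE)
      next
    }
    f_ph <- suppressWarnings(suppressMessages(fit_ph(train)))
    f_mvt <- fit_mvt_logistic(train)
    score <- function(f) {
      p <- predict_hazard(f, test)
      mean(test$leave * log(p) + (1 - test$leave) * log(1 - p))
    }
    ll_ph <- score(f_ph)
    ll_mvt <- score(f_mvt)
    out[[sid]] <- tibble(
      subject_id = sid, ll_ph = ll_ph, ll_mvt = ll_mvt,
      winner = if (ll_ph >= ll_mvt) "ph" else "mvt_logistic"
    )
  }
  bind_rows(out)
}

#' Win-stay curve: probability of poking again after a reward
#'
#' For each poke position `k`, the probability that the forager made at
#' least one further poke given a reward at `k`. Under a hazard-resetting
#' (proportional-hazards) strategy the curve is flat near 1 — rewards reset
#' the decision process regardless of how late they arrive — whereas a
#' belief-driven strategy leaves a declining curve, because a late "lucky"
#' reward does not restore the low belief.
#'
#' @param sessions Session log (correct trials are used).
#' @param positions Poke positions to tabulate; the default stops one short
#'   of the 20-poke cap, where trial end is forced rather than chosen.
#'
#' @return Tibble with `position`, `n` (rewards observed there), and
#'   `stay_prob`.
#' @export
win_stay_curve <- function(sessions, positions = 1:19) {
  assert_sessions(sessions)
  s <- sessions[sessions$correct == 1, ]
  s <- s[order(s$subject_id, s$session_id, s$trial_index, s$poke_index), ]
  key <- trial_key(s)
  n_pokes <- stats::ave(s$poke_index, key, FUN = max)
  rewarded <- s$rewarded == 1 & s$poke_index %in% positions
  stay <- s$poke_index < n_pokes
  tab <- tapply(stay[rewarded], s$poke_index[rewarded],
                function(x) c(n = length(x), p = mean(x)))
  pos <- as.integer(names(tab))
  m <- do.call(rbind, tab)
  tibble(position = pos, n = as.integer(m[, "n"]), stay_prob = m[, "p"])
}

#' Slope of the win-stay curve over reward position
#'
#' Weighted least-squares slope of stay probability on poke position; the
#' summary statistic contrasted between hazard-resetting and belief-driven
#' agents.
#'
#' @param curve Output of [win_stay_curve()].
#' @return The slope (probability per poke position).
#' @export
win_stay_slope <- function(curve) {
  stopifnot(all(c("position", "n", "stay_prob") %in% names(curve)))
  unname(stats::coef(stats::lm(stay_prob ~ position, data = curve,
                               weights = curve$n))[2])
}

#' Fit the leaving model separately for every subject
#'
#' @param sessions Prepared session log.
#' @param schedule A [reward_schedule()].
#' @param ... Passed to [fit_ph()].
#' @return Named list of `ph_fit` objects, one per subject.
#' @export
fit_ph_by_subject <- function(sessions, schedule = reward_schedule(), ...) {
  obs <- build_observations(sessions, schedule)
  ids <- unique(obs$subject_id)
  fits <- lapply(ids, function(sid) {
    suppressMessages(fit_ph(obs[obs$subject_id == sid, ], ...))
  })
  stats::setNames(fits, ids)
}
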