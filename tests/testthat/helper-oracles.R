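# Independent brute-force implementation of the subjective next-reward
# probability: explicit sum over the three patch types with per-poke
# likelihood products. Shares no code with the package.
bf_next_reward <- function(outcomes, schedule) {
  A <- schedule$scaling_factors
  tau <- schedule$decay_constant
  cap <- schedule$max_pokes
  prior <- schedule$type_prior
  prob <- function(n, i) if (n > cap) 0 else A[i] * exp(-(n - 1) / tau)
  num <- 0
  den <- 0
  for (i in 1:3) {
    lik <- prior[i]
    if (length(outcomes)) {
      for (j in seq_along(outcomes)) {
        p <- prob(j, i)
        lik <- lik * (if (outcomes[j] == 1) p else 1 - p)
      }
    }
    den <- den + lik
    num <- num + lik * prob(length(outcomes) + 1, i)
  }
  num / den
}

`%or%` <- function(a, b) if (is.null(a)) b else a

trial_key_cols <- function(s) {
  paste(s$subject_id, s$session_id, s$trial_index)
}

# Hand-built poke table from a list of trial specs (outcomes, side, ...),
# with simple deterministic timing.
toy_sessions <- function(trials, subject_id = "t01", session_id = "s01",
                         genotype = "opsin", protocol = "stim_poking") {
  t0 <- 0
  rows <- vector("list", length(trials))
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    L <- length(tr$outcomes)
    dur <- rep(tr$dur %or% 0.4, L)
    ipi <- rep(tr$ipi %or% 0.2, L)
    roi_enter <- t0 + (tr$travel %or% 2)
    out <- roi_enter + cumsum(dur + ipi)
    roi_exit <- out[L] + (tr$dwell %or% 1)
    rows[[ti]] <- tibble::tibble(
      subject_id = subject_id, session_id = session_id,
      genotype = genotype, protocol = protocol,
      trial_index = ti, trial_type = tr$type %or% NA_integer_,
      side = tr$side, correct = tr$correct %or% 1L,
      photostim = tr$photostim %or% 0L,
      roi_enter_s = roi_enter, roi_exit_s = roi_exit,
      timeout = tr$timeout %or% 0L,
      poke_index = seq_len(L), poke_in_s = out - dur, poke_out_s = out,
      rewarded = as.integer(tr$outcomes)
    )
    t0 <- roi_exit
  }
  dplyr::bind_rows(rows)
}

# Vectorized poke table from realized outcome strings (e.g. the `outcomes`
# column of simulate_from_fit), sides alternating so every trial is correct.
sessions_from_outcomes <- function(outcomes, photostim = 0L, side = NULL,
                                   subject_id = "x01",
                                   session_id = "s01") {
  nt <- length(outcomes)
  len <- nchar(outcomes)
  photostim <- rep_len(as.integer(photostim), nt)
  side_chr <- if (is.null(side)) {
    rep(c("L", "R"), length.out = nt)
  } else {
    c("L", "R")[rep_len(as.integer(side), nt) + 1L]
  }
  idx <- rep(seq_len(nt), len)
  k <- sequence(len)
  slot <- 30                       # seconds reserved per trial
  roi_enter <- (seq_len(nt) - 1) * slot
  poke_out <- roi_enter[idx] + k * 0.6
  tibble::tibble(
    subject_id = subject_id, session_id = session_id,
    genotype = "opsin", protocol = "stim_poking",
    trial_index = idx,
    trial_type = NA_integer_,
    side = side_chr[idx],
    correct = 1L,
    photostim = photostim[idx],
    roi_enter_s = roi_enter[idx],
    roi_exit_s = (roi_enter + len * 0.6 + 1)[idx],
    timeout = 0L,
    poke_index = as.integer(k),
    poke_in_s = poke_out - 0.4,
    poke_out_s = poke_out,
    rewarded = as.integer(unlist(strsplit(outcomes, ""), use.names = FALSE))
  )
}
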