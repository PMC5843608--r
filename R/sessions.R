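#' @importFrom dplyr %>% arrange group_by summarise mutate ungroup filter
#'   bind_rows left_join select n lag first last across
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column set of the denormalized session log: one row per poke,
# trial- and session-level fields repeated on each row.
session_log_columns <- c(
  "subject_id", "session_id", "genotype", "protocol",
  "trial_index", "trial_type", "side", "correct", "photostim",
  "roi_enter_s", "roi_exit_s", "timeout",
  "poke_index", "poke_in_s", "poke_out_s", "rewarded"
)

assert_sessions <- function(sessions) {
  if (!is.data.frame(sessions)) {
    stop("`sessions` must be a data frame of pokes (one row per poke)",
         call. = FALSE)
  }
  missing <- setdiff(session_log_columns, names(sessions))
  if (length(missing)) {
    stop("`sessions` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(sessions)
}

# Stable per-trial grouping key.
trial_key <- function(sessions) {
  paste(sessions$subject_id, sessions$session_id, sessions$trial_index,
        sep = "\r")
}

# Split poke-row indices by trial, preserving poke order within trial.
trial_row_index <- function(sessions) {
  ord <- order(sessions$subject_id, sessions$session_id,
               sessions$trial_index, sessions$poke_index)
  split(ord, trial_key(sessions)[ord])
}

#' Segment a trial's outcome sequence into reward-bracketed runs
#'
#' A run is a maximal stretch of consecutive omissions. Each reward closes
#' the current run as censored (terminal `"reward"`) and opens the next one;
#' the end of the trial closes the final run as a leave event (terminal
#' `"leave"`), or as `"leave_after_reward"` when the trial's final poke was
#' rewarded (downstream model fitting excludes that terminal, since leaving
#' decisions are only defined after omissions). Zero-length runs arise from
#' consecutive rewards.
#'
#' @param outcomes 0/1 vector of poke outcomes of one trial (at least one
#'   poke).
#'
#' @return A tibble with one row per run: `run_index` (0-based),
#'   `n_omissions`, `terminal`, and `last_reward_position` (poke index of
#'   the reward that opened the run, 0 for the first run).
#' @examples
#' segment_runs(c(1, 0, 0, 1, 0, 0, 0))
#' @export
segment_runs <- function(outcomes) {
  if (length(outcomes) == 0L) stop("trial has no pokes", call. = FALSE)
  if (!all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0 (omission) or 1 (reward)", call. = FALSE)
  }
  rewards <- which(outcomes == 1)
  # runs closed by each reward, then the terminal run
  open_pos <- c(0L, rewards)                   # reward that opened each run
  close_at <- c(rewards, length(outcomes) + 1L)
  n_omissions <- close_at - open_pos - 1L
  terminal <- c(
    rep("reward", length(rewards)),
    if (length(outcomes) %in% rewards) "leave_after_reward" else "leave"
  )
  tibble(
    run_index = seq_along(open_pos) - 1L,
    n_omissions = as.integer(n_omissions),
    terminal = terminal,
    last_reward_position = as.integer(open_pos)
  )
}

#' Prepare raw session logs for analysis
#'
#' Applies the standard preprocessing: trials are relabelled correct/error
#' by the side-alternation rule (a trial is correct when its side differs
#' from the previous trial's side; the first trial of a session is correct
#' by convention), sessions are truncated to their first `max_trials`
#' trials, and trials with fewer than `min_pokes` pokes are dropped.
#' Original trial indices are preserved.
#'
#' @param sessions Poke-level session log (see [write_sessions()] for the
#'   schema).
#' @param max_trials Number of leading trials retained per session.
#' @param min_pokes Minimum pokes a trial must contain to be kept.
#'
#' @return The filtered poke table, same schema as the input.
#' @export
prepare_sessions <- function(sessions, max_trials = 60, min_pokes = 3) {
  assert_sessions(sessions)
  sessions <- as_tibble(sessions) %>%
    arrange(.data$subject_id, .data$session_id, .data$trial_index,
            .data$poke_index)
  trials <- sessions %>%
    group_by(.data$subject_id, .data$session_id, .data$trial_index) %>%
    summarise(side = first(.data$side), n_pokes = n(), .groups = "drop_last") %>%
    mutate(
      correct_new = as.integer(.data$side != lag(.data$side, default = "")),
      correct_new = ifelse(seq_len(n()) == 1L, 1L, .data$correct_new),
      trial_rank = seq_len(n())
    ) %>%
    ungroup() %>%
    filter(.data$trial_rank <= max_trials, .data$n_pokes >= min_pokes) %>%
    select("subject_id", "session_id", "trial_index", "correct_new")
  sessions %>%
    dplyr::inner_join(trials,
                      by = c("subject_id", "session_id", "trial_index")) %>%
    mutate(correct = .data$correct_new) %>%
    select(-"correct_new")
}

#' @importFrom rlang .data
NULL
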