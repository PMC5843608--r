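#' Reward schedule of the probabilistic foraging task
#'
#' Bundles the generative parameters of the task: three latent patch types
#' whose per-poke reward probability decays exponentially at a shared rate
#' but with different initial scaling, a hard cap after which reward
#' probability is zero, and the prior over types.
#'
#' The per-poke reward probability for type `i` is
#' `A_i * exp(-(n - 1) / decay_constant)` for poke number `n` up to
#' `max_pokes`, and 0 beyond.
#'
#' @param scaling_factors Initial reward probabilities `A_1 <= A_2 <= A_3`
#'   for the low-, medium- and high-quality patch types.
#' @param decay_constant Decay time constant in units of pokes.
#' @param max_pokes Poke number after which reward probability is zero.
#' @param type_prior Prior probability of each type; must sum to 1.
#'
#' @return An object of class `reward_schedule`.
#' @examples
#' sched <- reward_schedule()
#' reward_probability(1:6, type_index = 1, sched)
#' @export
reward_schedule <- function(scaling_factors = c(0.5, 0.75, 1.0),
                            decay_constant = 5,
                            max_pokes = 20L,
                            type_prior = rep(1 / 3, 3)) {
  stopifnot(
    length(scaling_factors) == 3L,
    all(scaling_factors > 0), all(scaling_factors <= 1),
    !is.unsorted(scaling_factors),
    length(decay_constant) == 1L, decay_constant > 0,
    length(max_pokes) == 1L, max_pokes >= 1,
    length(type_prior) == 3L, all(type_prior >= 0),
    abs(sum(type_prior) - 1) < 1e-10
  )
  structure(
    list(
      scaling_factors = as.numeric(scaling_factors),
      decay_constant = as.numeric(decay_constant),
      max_pokes = as.integer(max_pokes),
      type_prior = as.numeric(type_prior)
    ),
    class = "reward_schedule"
  )
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat("<reward_schedule>\n")
  cat("  scaling factors A:", paste(x$scaling_factors, collapse = ", "), "\n")
  cat("  decay constant:", x$decay_constant, "pokes;  reward cap after poke",
      x$max_pokes, "\n")
  cat("  type prior:", paste(signif(x$type_prior, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-poke reward probability for a known patch type
#'
#' @param n Poke number(s) within the trial, 1-based.
#' @param type_index Patch type, 1 (low) to 3 (high).
#' @param schedule A [reward_schedule()].
#'
#' @return Numeric vector of probabilities, one per element of `n`.
#' @export
reward_probability <- function(n, type_index, schedule = reward_schedule()) {
  stopifnot(inherits(schedule, "reward_schedule"))
  if (length(type_index) != 1L || !type_index %in% 1:3) {
    stop("`type_index` must be a single value in 1..3", call. = FALSE)
  }
  n <- as.numeric(n)
  if (any(n < 1)) stop("poke number `n` must be >= 1", call. = FALSE)
  p <- schedule$scaling_factors[type_index] *
    exp(-(n - 1) / schedule$decay_constant)
  p[n > schedule$max_pokes] <- 0
  p
}

# Per-poke outcome likelihood matrix: rows = poke number 1..n, cols = 3 types.
# outcomes is a 0/1 vector.
outcome_likelihoods <- function(outcomes, schedule) {
  n <- length(outcomes)
  p <- vapply(1:3, function(i) reward_probability(seq_len(n), i, schedule),
              numeric(n))
  p <- matrix(p, nrow = n)
  ifelse(matrix(outcomes, n, 3) == 1, p, 1 - p)
}

check_outcomes <- function(outcomes, schedule) {
  if (length(outcomes) > schedule$max_pokes) {
    stop("outcome history longer than the schedule's poke cap (",
         schedule$max_pokes, ")", call. = FALSE)
  }
  if (length(outcomes) && !all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0 (omission) or 1 (reward)", call. = FALSE)
  }
}

#' Posterior over patch types given an outcome history
#'
#' Bayes' rule over the three latent patch types: the posterior is
#' proportional to `prior_i * prod_j P(o_j | t_i)`, with the per-poke
#' likelihood given by [reward_probability()].
#'
#' @param outcomes 0/1 vector of poke outcomes from trial start (may be
#'   empty, in which case the prior is returned).
#' @inheritParams reward_probability
#'
#' @return Probability vector of length 3 summing to 1.
#' @export
posterior_over_types <- function(outcomes, schedule = reward_schedule()) {
  stopifnot(inherits(schedule, "reward_schedule"))
  check_outcomes(outcomes, schedule)
  if (length(outcomes) == 0L) return(schedule$type_prior)
  lik <- apply(outcome_likelihoods(outcomes, schedule), 2, prod)
  w <- schedule$type_prior * lik
  if (sum(w) <= 0) {
    stop("outcome history has zero likelihood under every patch type",
         call. = FALSE)
  }
  w / sum(w)
}

#' Subjective probability that the next poke is rewarded
#'
#' The model-based estimate of reward probability for the hypothetical next
#' poke: the type-conditional reward probabilities at poke `n + 1`, averaged
#' under the posterior over types given the history so far. With a
#' degenerate prior on one type this reduces to [reward_probability()].
#'
#' @inheritParams posterior_over_types
#'
#' @return A single probability.
#' @export
next_reward_probability <- function(outcomes, schedule = reward_schedule()) {
  post <- posterior_over_types(outcomes, schedule)
  n_next <- length(outcomes) + 1
  if (n_next > schedule$max_pokes) return(0)
  p_next <- vapply(1:3, function(i) reward_probability(n_next, i, schedule),
                   numeric(1))
  sum(p_next * post)
}

# Subjective next-reward probability after each poke of a trial, vectorized:
# element k is next_reward_probability(outcomes[1:k]). Used by observation
# construction, leaving-probability summaries, and the rule-based agents.
belief_path <- function(outcomes, schedule) {
  n <- length(outcomes)
  if (n == 0L) return(numeric(0))
  check_outcomes(outcomes, schedule)
  lik <- outcome_likelihoods(outcomes, schedule)
  cum <- apply(lik, 2, cumprod)
  cum <- matrix(cum, nrow = n)
  w <- sweep(cum, 2, schedule$type_prior, `*`)
  tot <- rowSums(w)
  if (any(tot <= 0)) {
    stop("outcome history has zero likelihood under every patch type",
         call. = FALSE)
  }
  w <- w / tot
  p_next <- vapply(1:3, function(i) {
    reward_probability(pmin(seq_len(n) + 1, schedule$max_pokes + 1), i,
                       schedule)
  }, numeric(n))
  p_next <- matrix(p_next, nrow = n)
  # positions beyond the cap have probability zero for every type
  over <- (seq_len(n) + 1) > schedule$max_pokes
  p_next[over, ] <- 0
  rowSums(p_next * w)
}
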