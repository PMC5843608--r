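#' Omission duty cycle records
#'
#' The omission duty cycle (ODC) of a poke is its duration divided by the
#' sum of that duration and the preceding inter-poke interval — a vigor
#' readout. It is defined only for omission pokes that have a predecessor
#' within the same trial (the first poke has no preceding interval, and
#' rewarded pokes are excluded because reward consumption inflates their
#' duration).
#'
#' @param sessions Session log (correct trials are used).
#'
#' @return A tibble with one row per eligible poke: identifiers, the poke's
#'   run position `n_since_reward`, covariates, `rel_position` relative to
#'   the trial's last reward (-1 = immediately before, +1 = immediately
#'   after; `NA` in unrewarded trials), and `odc`. When the log carries the
#'   generator's `true_hazard` column it is propagated.
#' @export
compute_odc <- function(sessions) {
  assert_sessions(sessions)
  s <- sessions[sessions$correct == 1, ]
  if (!nrow(s)) stop("no correct trials", call. = FALSE)
  s <- s[order(s$subject_id, s$session_id, s$trial_index, s$poke_index), ]
  key <- trial_key(s)
  same_trial <- duplicated(key)             # poke has a predecessor
  prev_out <- c(NA_real_, s$poke_out_s[-nrow(s)])
  duration <- s$poke_out_s - s$poke_in_s
  ipi <- s$poke_in_s - prev_out
  if (any(duration <= 0) || any(ipi[same_trial] <= 0, na.rm = TRUE)) {
    stop("non-positive poke duration or inter-poke interval", call. = FALSE)
  }
  lr_incl <- stats::ave(s$poke_index * s$rewarded, key, FUN = cummax)
  last_rw <- stats::ave(s$poke_index * s$rewarded, key, FUN = max)
  keep <- same_trial & s$rewarded == 0
  tibble(
    subject_id = s$subject_id[keep],
    session_id = s$session_id[keep],
    trial_index = s$trial_index[keep],
    genotype = s$genotype[keep],
    poke_index = s$poke_index[keep],
    n_since_reward = as.integer(s$poke_index - lr_incl)[keep],
    last_reward_position = as.integer(lr_incl)[keep],
    side = as.integer(s$side == "R")[keep],
    photostim = as.integer(s$photostim)[keep],
    rel_position = ifelse(last_rw[keep] > 0,
                          s$poke_index[keep] - last_rw[keep], NA_integer_),
    odc = (duration / (duration + ipi))[keep],
    true_hazard = if ("true_hazard" %in% names(s)) {
      s$true_hazard[keep]
    } else {
      NA_real_
    }
  )
}

# Attach the model hazard implied by per-subject fits to ODC records.
attach_hazard <- function(records, fits) {
  if (inherits(fits, "ph_fit")) {
    fits <- stats::setNames(rep(list(fits), length(unique(records$subject_id))),
                            unique(records$subject_id))
  }
  missing <- setdiff(unique(records$subject_id), names(fits))
  if (length(missing)) {
    stop("no fit supplied for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$hazard <- NA_real_
  for (sid in unique(records$subject_id)) {
    ix <- records$subject_id == sid
    records$hazard[ix] <- hazard_of(
      fits[[sid]], records$n_since_reward[ix], records$photostim[ix],
      records$side[ix], records$last_reward_position[ix]
    )
  }
  records
}

#' ODC and hazard profiles aligned on the trial's last reward
#'
#' Within a trial the hazard of leaving rises and poke vigor falls, but a
#' reward resets the decision process: just after the last reward the
#' hazard is lower — and the ODC higher — than just before it, despite the
#' overall monotonic trends. This function computes the mean ODC and mean
#' model hazard by position relative to the last reward, and the scalar
#' before/after contrasts (position +1 minus position -1) per subject with
#' Wilcoxon signed-rank tests across subjects.
#'
#' @param sessions Session log.
#' @param fits Named list of per-subject `ph_fit` objects (see
#'   [fit_ph_by_subject()]), or a single fit applied to all subjects.
#' @param positions Relative positions profiled.
#'
#' @return A list of class `odc_alignment`: `profile` (mean ODC and hazard
#'   by relative position, averaged within then across subjects),
#'   `contrasts` (per-subject after-minus-before for both quantities), and
#'   the two signed-rank `tests`.
#' @export
align_last_reward <- function(sessions, fits, positions = -5:5) {
  rec <- attach_hazard(compute_odc(sessions), fits)
  rec <- rec[!is.na(rec$rel_position) & rec$rel_position %in% positions, ]
  per_sub <- rec %>%
    group_by(.data$subject_id, .data$rel_position) %>%
    summarise(odc = mean(.data$odc), hazard = mean(.data$hazard),
              .groups = "drop")
  profile <- per_sub %>%
    group_by(.data$rel_position) %>%
    summarise(odc = mean(.data$odc), hazard = mean(.data$hazard),
              n_subjects = n(), .groups = "drop")
  contrasts <- per_sub %>%
    group_by(.data$subject_id) %>%
    summarise(
      odc_contrast = .data$odc[.data$rel_position == 1] -
        .data$odc[.data$rel_position == -1],
      hazard_contrast = .data$hazard[.data$rel_position == 1] -
        .data$hazard[.data$rel_position == -1],
      .groups = "drop"
    )
  sr <- function(x) {
    if (length(x) < 2) return(NULL)
    wt <- stats::wilcox.test(x, exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  structure(
    list(profile = profile, contrasts = contrasts,
         tests = list(odc = sr(contrasts$odc_contrast),
                      hazard = sr(contrasts$hazard_contrast))),
    class = "odc_alignment"
  )
}

#' @export
print.odc_alignment <- function(x, ...) {
  cat("<odc_alignment> (position +1 vs -1 around the last reward)\n")
  cat(sprintf("  ODC contrast:    %+.4f (signed-rank p = %.3g)\n",
              mean(x$contrasts$odc_contrast),
              if (is.null(x$tests$odc)) NA else x$tests$odc$p))
  cat(sprintf("  hazard contrast: %+.4f (signed-rank p = %.3g)\n",
              mean(x$contrasts$hazard_contrast),
              if (is.null(x$tests$hazard)) NA else x$tests$hazard$p))
  invisible(x)
}

#' Links between poke vigor and the latent decision variable
#'
#' Three analyses connecting the ODC to the fitted hazard of leaving:
#' (i) the Pearson correlation between ODC and hazard (pooled, and the mean
#' of within-subject correlations); (ii) per-subject linear regression of
#' ODC on position relative to the last reward plus a photostimulation
#' term — stimulation raises vigor when only position is controlled;
#' (iii) per-subject regression of ODC on the model hazard plus a
#' photostimulation term — conditioning on the hazard should absorb the
#' stimulation effect, because the fitted hazard already carries it. Group
#' tests: signed-rank of the opsin coefficients against zero, rank-sum of
#' opsin vs control.
#'
#' @inheritParams align_last_reward
#' @param min_records Minimum ODC records required per subject.
#'
#' @return A list of class `odc_links`: `r_pooled`, `r_within` (mean
#'   within-subject r), `coefs` (per-subject stimulation coefficients from
#'   both regressions), and `tests`.
#' @export
odc_model_links <- function(sessions, fits, min_records = 10) {
  rec <- attach_hazard(compute_odc(sessions), fits)
  counts <- table(rec$subject_id)
  keep_subjects <- names(counts)[counts >= min_records]
  skipped <- setdiff(names(counts), keep_subjects)
  if (length(skipped)) {
    warning("subject(s) skipped (< ", min_records, " records): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  rec <- rec[rec$subject_id %in% keep_subjects, ]
  r_pooled <- stats::cor(rec$odc, rec$hazard)
  coefs <- list()
  r_sub <- numeric(0)
  for (sid in keep_subjects) {
    d <- rec[rec$subject_id == sid, ]
    r_sub[sid] <- stats::cor(d$odc, d$hazard)
    stim_pos <- if (stats::var(d$photostim) > 0 &&
                    sum(!is.na(d$rel_position)) >= min_records) {
      stats::coef(stats::lm(odc ~ rel_position + photostim, data = d))[
        "photostim"]
    } else {
      NA_real_
    }
    stim_haz <- if (stats::var(d$photostim) > 0) {
      stats::coef(stats::lm(odc ~ hazard + photostim, data = d))["photostim"]
    } else {
      NA_real_
    }
    coefs[[sid]] <- tibble(
      subject_id = sid, genotype = d$genotype[1],
      stim_coef_position = unname(stim_pos),
      stim_coef_hazard = unname(stim_haz)
    )
  }
  coefs <- bind_rows(coefs)
  group_tests <- function(values) {
    v <- values[!is.na(values)]
    g <- coefs$genotype[!is.na(values)]
    out <- list(signed_rank_opsin = NULL, rank_sum = NULL)
    if (sum(g == "opsin") >= 2) {
      wt <- stats::wilcox.test(v[g == "opsin"], exact = FALSE)
      out$signed_rank_opsin <- list(statistic = unname(wt$statistic),
                                    p = wt$p.value)
    }
    if (length(unique(g)) == 2) {
      wt <- stats::wilcox.test(v[g == "opsin"], v[g == "control"],
                               exact = FALSE)
      out$rank_sum <- list(statistic = unname(wt$statistic), p = wt$p.value)
    }
    out
  }
  structure(
    list(r_pooled = r_pooled, r_within = mean(r_sub), coefs = coefs,
         tests = list(position = group_tests(coefs$stim_coef_position),
                      hazard = group_tests(coefs$stim_coef_hazard))),
    class = "odc_links"
  )
}

#' @export
print.odc_links <- function(x, ...) {
  cat("<odc_links>\n")
  cat(sprintf("  ODC-hazard correlation: pooled r = %.4f, within-subject mean r = %.4f\n",
              x$r_pooled, x$r_within))
  op <- x$coefs$genotype == "opsin"
  cat(sprintf("  stim coefficient (ODC ~ position + stim), opsin mean: %+.4f\n",
              mean(x$coefs$stim_coef_position[op], na.rm = TRUE)))
  cat(sprintf("  stim coefficient (ODC ~ hazard + stim),  opsin mean: %+.4f\n",
              mean(x$coefs$stim_coef_hazard[op], na.rm = TRUE)))
  invisible(x)
}
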