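SESSION_LOG_SCHEMA <- "1.0"

#' Write a session log to CSV
#'
#' One row per poke, trial fields repeated (denormalized), times in seconds
#' from session start with 6 decimal places, sorted by subject, session,
#' trial, and poke. The first line is a schema-version comment; extra
#' columns beyond the canonical schema (e.g. the generator's truth columns)
#' are preserved.
#'
#' @param sessions Poke-level session log.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  assert_sessions(sessions)
  sessions <- as_tibble(sessions) %>%
    arrange(.data$subject_id, .data$session_id, .data$trial_index,
            .data$poke_index)
  extra <- setdiff(names(sessions), session_log_columns)
  sessions <- sessions[, c(session_log_columns, extra)]
  time_cols <- c("roi_enter_s", "roi_exit_s", "poke_in_s", "poke_out_s")
  sessions[time_cols] <- lapply(sessions[time_cols],
                                function(x) sprintf("%.6f", x))
  writeLines(paste0("# session-log-schema: ", SESSION_LOG_SCHEMA), path)
  readr::write_csv(sessions, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a session log written by [write_sessions()]
#'
#' Validates the schema version (newer major versions are rejected), the
#' required columns, and the event-structure invariants: poke out after
#' poke in, pokes inside their trial's ROI window, strictly increasing poke
#' times within a trial, and no duplicate (subject, session, trial, poke)
#' keys. Violations are reported with the offending data row numbers.
#'
#' @param path CSV path.
#' @return A poke-level tibble.
#' @export
read_sessions <- function(path) {
  first <- readLines(path, n = 1)
  version <- sub("^#\\s*session-log-schema:\\s*", "", first)
  if (identical(version, first)) {
    stop("not a session log: missing schema-version header", call. = FALSE)
  }
  major <- as.integer(strsplit(version, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major > as.integer(
    strsplit(SESSION_LOG_SCHEMA, ".", fixed = TRUE)[[1]][1])) {
    stop("session log schema version ", version,
         " is newer than supported (", SESSION_LOG_SCHEMA, ")",
         call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 2)[2], ",", fixed = TRUE)[[1]]
  known <- list(
    subject_id = readr::col_character(),
    session_id = readr::col_character(),
    genotype = readr::col_character(),
    protocol = readr::col_character(),
    side = readr::col_character(),
    trial_index = readr::col_integer(),
    trial_type = readr::col_integer(),
    correct = readr::col_integer(),
    photostim = readr::col_integer(),
    timeout = readr::col_integer(),
    poke_index = readr::col_integer(),
    rewarded = readr::col_integer(),
    roi_enter_s = readr::col_double(),
    roi_exit_s = readr::col_double(),
    poke_in_s = readr::col_double(),
    poke_out_s = readr::col_double(),
    potential_outcomes = readr::col_character()
  )
  spec <- do.call(readr::cols, c(known[intersect(names(known), header)],
                                 .default = readr::col_guess()))
  s <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                       progress = FALSE, col_types = spec)
  assert_sessions(s)
  validate_session_rows(s)
  as_tibble(s)
}

validate_session_rows <- function(s) {
  bad <- function(cond) which(cond)
  problems <- character(0)
  report <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, paste0(what, " at row(s) ",
                                      paste(utils::head(rows, 10),
                                            collapse = ", "),
                                      if (length(rows) > 10) " ..."))
    }
  }
  report(bad(s$poke_out_s <= s$poke_in_s), "poke_out_s <= poke_in_s")
  report(bad(s$poke_in_s < s$roi_enter_s | s$poke_out_s > s$roi_exit_s),
         "poke outside ROI window")
  key <- paste(s$subject_id, s$session_id, s$trial_index, s$poke_index)
  report(bad(duplicated(key)), "duplicate (subject, session, trial, poke) key")
  ord <- order(s$subject_id, s$session_id, s$trial_index, s$poke_index)
  so <- s[ord, ]
  tk <- trial_key(so)
  nonmono <- so$poke_in_s < c(-Inf, so$poke_out_s[-nrow(so)]) &
    duplicated(tk)
  report(ord[bad(nonmono)], "non-monotone poke times within trial")
  if (length(problems)) {
    stop("invalid session log:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(s)
}

#' Serialize a fitted leaving model to JSON
#'
#' Writes the baseline hazard vector (for `ph_fit`), the coefficient map,
#' fit metadata and a schema version, so fits can be archived next to the
#' session logs they came from.
#'
#' @param fit A `ph_fit` or `mvt_logistic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ph_fit") || inherits(fit, "mvt_logistic_fit"))
  body <- unclass(fit)
  if (!is.null(body$betas)) body$betas <- as.list(body$betas)
  body$model <- class(fit)
  body$schema_version <- "1.0"
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit written by [write_fit_json()]
#'
#' @param path JSON path.
#' @return The restored `ph_fit` or `mvt_logistic_fit`.
#' @export
read_fit_json <- function(path) {
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  major <- as.integer(strsplit(body$schema_version %||% "999",
                               ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major > 1) {
    stop("fit schema version ", body$schema_version,
         " is newer than supported", call. = FALSE)
  }
  cls <- body$model
  body$model <- NULL
  body$schema_version <- NULL
  if (identical(cls, "ph_fit")) {
    body$betas <- vapply(body$betas, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    body$baseline_hazard <- as.numeric(body$baseline_hazard)
    body$n_cap <- as.integer(body$n_cap)
  }
  structure(body, class = cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
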