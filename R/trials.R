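# Trial-level data model: readers/writers for the delimited trial-table
# format, the correctness rule, and the reaction-time trial filter.

trial_columns <- c("participant_id", "continuum_id", "condition",
                   "morph_pct", "response", "rt_ms", "block")

continuum_columns <- c("continuum_id", "identity_A", "identity_B",
                       "condition", "b_is_more_familiar")

#' Validate a trial table
#'
#' Checks the trial-table contract: required columns, morph levels on the
#' nine-level design grid, responses coded as the literal labels `A`/`B`,
#' known condition labels and positive reaction times. Violations are
#' reported with the offending row numbers.
#'
#' @param trials A data frame of trials.
#' @return The validated trials, as a tibble, invisibly unchanged.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  trials$morph_pct <- as.integer(trials$morph_pct)
  trials$block <- as.integer(trials$block)
  trials$rt_ms <- as.numeric(trials$rt_ms)

  bad_rows <- function(ok) which(!ok)
  problems <- character(0)
  r <- bad_rows(trials$morph_pct %in% morph_levels())
  if (length(r) > 0) {
    problems <- c(problems, paste0(
      "morph_pct outside the design levels {10,...,90} in row(s): ",
      paste(utils::head(r, 10), collapse = ", ")))
  }
  r <- bad_rows(trials$response %in% c("A", "B"))
  if (length(r) > 0) {
    problems <- c(problems, paste0(
      "response must be 'A' or 'B' in row(s): ",
      paste(utils::head(r, 10), collapse = ", ")))
  }
  r <- bad_rows(trials$condition %in% all_conditions())
  if (length(r) > 0) {
    problems <- c(problems, paste0(
      "unknown condition label in row(s): ",
      paste(utils::head(r, 10), collapse = ", ")))
  }
  r <- bad_rows(is.finite(trials$rt_ms) & trials$rt_ms > 0)
  if (length(r) > 0) {
    problems <- c(problems, paste0(
      "rt_ms must be a positive number in row(s): ",
      paste(utils::head(r, 10), collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(trials)
}

#' Read a trial table
#'
#' Reads a comma-separated trial table (one row per 2AFC presentation) with
#' header `participant_id,continuum_id,condition,morph_pct,response,rt_ms,
#' block`, validates every row, and infers the morph continua from the
#' distinct (continuum_id, condition) pairs. An optional sidecar table can
#' supply the endpoint identities of each continuum.
#'
#' @param path Path to the trial CSV file.
#' @param continua_path Optional path to a continuum sidecar CSV with header
#'   `continuum_id,identity_A,identity_B,condition,b_is_more_familiar`.
#' @return A list with elements `trials` (tibble of validated trials) and
#'   `continua` (tibble of morph continua).
#' @export
read_trials <- function(path, continua_path = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    stop("trial file contains no trials: ", path, call. = FALSE)
  }
  trials <- validate_trials(raw)

  if (!is.null(continua_path)) {
    continua <- utils::read.csv(continua_path, stringsAsFactors = FALSE)
    missing <- setdiff(continuum_columns, names(continua))
    if (length(missing) > 0) {
      stop("continuum table is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(continua$identity_A == continua$identity_B)) {
      stop("continuum endpoints identity_A and identity_B must differ",
           call. = FALSE)
    }
    continua <- tibble::as_tibble(continua)
  } else {
    continua <- infer_continua(trials)
  }
  list(trials = trials, continua = continua)
}

# Infer the continuum table from the distinct (continuum_id, condition)
# pairs present in the trials; endpoint identities are placeholders.
infer_continua <- function(trials) {
  con <- dplyr::distinct(trials[, c("continuum_id", "condition")])
  con <- con[order(con$continuum_id), ]
  tibble::tibble(
    continuum_id = con$continuum_id,
    identity_A = paste0(con$continuum_id, "_A"),
    identity_B = paste0(con$continuum_id, "_B"),
    condition = con$condition,
    b_is_more_familiar = b_is_more_familiar(con$condition)
  )
}

#' Write a trial table
#'
#' Writes trials in the canonical comma-separated format accepted by
#' [read_trials()].
#'
#' @param trials A validated trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Correctness of a 2AFC response
#'
#' A response is correct when it matches the identity contributing the
#' greater share of the morph: above the 50% morph the correct response is
#' `B`, below it `A`. At the 50% morph no correct response exists and `NA`
#' is returned.
#'
#' @param trials A trial tibble (vectorized over rows).
#' @return Logical vector: `TRUE`/`FALSE`/`NA` per trial.
#' @export
is_correct <- function(trials) {
  ifelse(trials$morph_pct == 50L, NA,
         ifelse(trials$morph_pct > 50L,
                trials$response == "B",
                trials$response == "A"))
}

#' Filter trials for reaction-time analysis
#'
#' Applies, in order: the reaction-time window (retain 150 ms <= rt <=
#' 5,000 ms, bounds inclusive), removal of 50% morph trials (no correct
#' response exists there), and removal of incorrect trials. Each removed
#' trial is attributed to the first rule that removed it, so the counts in
#' the report partition the input.
#'
#' @param trials A trial tibble.
#' @param rt_min,rt_max Reaction-time window in milliseconds.
#' @return A list with `trials` (retained tibble) and `report` (a
#'   `filter_report` with removal counts).
#' @export
filter_for_rt <- function(trials, rt_min = 150, rt_max = 5000) {
  n_input <- nrow(trials)
  fast <- trials$rt_ms < rt_min
  slow <- !fast & trials$rt_ms > rt_max
  in_window <- !fast & !slow
  midpoint <- in_window & trials$morph_pct == 50L
  correct <- is_correct(trials)
  incorrect <- in_window & !midpoint & !correct
  incorrect[is.na(incorrect)] <- FALSE
  keep <- in_window & !midpoint & !incorrect

  report <- structure(list(
    n_input = n_input,
    n_rt_fast = sum(fast),
    n_rt_slow = sum(slow),
    n_midpoint = sum(midpoint),
    n_incorrect = sum(incorrect),
    n_retained = sum(keep)
  ), class = "filter_report")

  retained <- trials[keep, , drop = FALSE]
  if (nrow(retained) == 0) {
    warning("no trials retained by the reaction-time filter", call. = FALSE)
  }
  list(trials = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Reaction-time trial filter\n")
  cat(sprintf("  input:      %d trials\n", x$n_input))
  cat(sprintf("  removed:    %d too fast, %d too slow, %d midpoint, %d incorrect\n",
              x$n_rt_fast, x$n_rt_slow, x$n_midpoint, x$n_incorrect))
  cat(sprintf("  retained:   %d trials\n", x$n_retained))
  invisible(x)
}
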