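# Aggregation: percent-"Identity B" response curves, label-flip
# symmetrization for arbitrary-label control continua, and participant-level
# percentile bootstrap confidence intervals.

new_response_curve <- function(df, symmetrized = FALSE, grouping = "per_participant") {
  structure(tibble::as_tibble(df),
            symmetrized = symmetrized,
            grouping = grouping,
            class = c("response_curve", class(tibble::tibble())))
}

#' Is a curve symmetrized?
#' @param curve A `response_curve`.
#' @return Logical flag.
#' @export
is_symmetrized <- function(curve) isTRUE(attr(curve, "symmetrized"))

#' Percent "Identity B" response curve
#'
#' Computes, per morph level, the mean percentage of trials answered with
#' the Identity-B label. With `grouping = "per_participant"` (the default)
#' each participant's percentage is computed first and participants are
#' averaged with equal weight; `"pooled"` uses the grand trial proportion.
#'
#' @param trials A trial tibble.
#' @param condition Condition label to restrict to; may be omitted when the
#'   trials contain a single condition.
#' @param grouping `"per_participant"` or `"pooled"`.
#' @return A `response_curve` tibble with columns `condition`, `morph_pct`,
#'   `mean_pct`, `ci_low`, `ci_high`, `n_trials`. Levels with no trials are
#'   flagged with `NA`, never silently 0.
#' @export
percent_b <- function(trials, condition = NULL,
                      grouping = c("per_participant", "pooled")) {
  grouping <- match.arg(grouping)
  if (!is.null(condition)) {
    trials <- trials[trials$condition == condition, , drop = FALSE]
  } else {
    condition <- unique(trials$condition)
    if (length(condition) != 1) {
      stop("trials span several conditions; pass `condition` explicitly",
           call. = FALSE)
    }
  }
  if (nrow(trials) == 0) {
    stop("no trials for condition '", condition, "'", call. = FALSE)
  }
  levels <- morph_levels()
  lev_f <- factor(trials$morph_pct, levels = levels)
  n <- as.vector(table(lev_f))
  if (grouping == "pooled") {
    b <- tapply(trials$response == "B", lev_f, sum)
    pct <- 100 * as.vector(b) / n
  } else {
    pp <- participant_pct(trials)
    pct <- colMeans(pp$pct, na.rm = TRUE)
    pct[colSums(!is.na(pp$pct)) == 0] <- NA_real_
  }
  pct[n == 0] <- NA_real_
  if (anyNA(pct)) {
    warning("morph level(s) with no trials: ",
            paste(levels[is.na(pct)], collapse = ", "), call. = FALSE)
  }
  new_response_curve(tibble::tibble(
    condition = condition, morph_pct = levels, mean_pct = as.numeric(pct),
    ci_low = NA_real_, ci_high = NA_real_, n_trials = n
  ), symmetrized = FALSE, grouping = grouping)
}

# participant x level percentage matrix (plus counts) for one condition
participant_pct <- function(trials) {
  levels <- morph_levels()
  pid <- factor(trials$participant_id)
  lev <- factor(trials$morph_pct, levels = levels)
  s <- tapply(trials$response == "B", list(pid, lev), sum)
  n <- tapply(rep(1L, nrow(trials)), list(pid, lev), sum)
  s[is.na(s)] <- 0; n[is.na(n)] <- 0
  pct <- 100 * s / n
  pct[n == 0] <- NA_real_
  list(pct = pct, n = n, participants = levels(pid))
}

#' Symmetrize a response curve
#'
#' For control continua the Identity-B designation is arbitrary; the curve
#' is made point-symmetric about the 50% morph by averaging each level with
#' the complement of its mirror level:
#' `f'(x) = (f(x) + 100 - f(100 - x)) / 2`, with `f'(50) = 50` exactly.
#' Applying it to an already-symmetrized curve is a no-op.
#'
#' @param curve A `response_curve` covering all nine morph levels.
#' @return The symmetrized `response_curve` (confidence bounds are dropped;
#'   recompute them with [bootstrap_curve()]).
#' @export
symmetrize <- function(curve) {
  if (is_symmetrized(curve)) return(curve)
  levels <- morph_levels()
  if (!all(levels %in% curve$morph_pct)) {
    stop("curve must contain all nine morph levels", call. = FALSE)
  }
  curve <- curve[match(levels, curve$morph_pct), ]
  f <- curve$mean_pct
  fs <- symmetrize_values(f)
  n2 <- curve$n_trials + rev(curve$n_trials)
  new_response_curve(tibble::tibble(
    condition = curve$condition, morph_pct = levels, mean_pct = fs,
    ci_low = NA_real_, ci_high = NA_real_, n_trials = n2
  ), symmetrized = TRUE, grouping = attr(curve, "grouping"))
}

# f ordered by morph_levels(); returns the symmetrized values
symmetrize_values <- function(f) {
  fs <- (f + 100 - rev(f)) / 2
  fs[morph_levels() == 50L] <- 50
  fs
}

#' Flip the Identity-A/B labels of selected continua
#'
#' Re-expresses trials of the given continua under the opposite endpoint
#' designation: morph percentage `m` becomes `100 - m` and responses `A`
#' and `B` are swapped. Used by the bootstrap to re-randomize the arbitrary
#' labels of control continua.
#'
#' @param trials A trial tibble.
#' @param continuum_ids Continuum ids to flip.
#' @return The trial tibble with flipped labels.
#' @export
flip_labels <- function(trials, continuum_ids) {
  i <- trials$continuum_id %in% continuum_ids
  trials$morph_pct[i] <- 100L - trials$morph_pct[i]
  trials$response[i] <- ifelse(trials$response[i] == "B", "A", "B")
  trials
}

#' Percentile bootstrap interval for an arbitrary statistic
#'
#' Resamples participants with replacement `n_boot` times and returns
#' percentile bounds of the replicate statistics. Resampled participants
#' are relabeled so that a participant drawn twice contributes as two
#' independent units. If `flip_continua` is given (the control continua of
#' an arbitrary-label condition), every replicate additionally
#' re-randomizes the A/B label of each listed continuum with probability
#' 1/2 before the statistic is evaluated.
#'
#' @param trials A trial tibble with >= 2 participants.
#' @param statistic Function mapping a trial tibble to a numeric vector.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are seed-deterministic.
#' @param level Coverage level, default 0.95.
#' @param flip_continua Optional character vector of continuum ids whose
#'   labels are re-randomized per replicate.
#' @return Tibble with one row per statistic component: `estimate` (on the
#'   original sample), `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(trials, statistic, n_boot = 10000, seed = 1,
                         level = 0.95, flip_continua = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  pids <- unique(trials$participant_id)
  if (length(pids) < 2) {
    stop("bootstrap requires at least two participants", call. = FALSE)
  }
  est <- statistic(trials)
  by_pid <- split(seq_len(nrow(trials)), trials$participant_id)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample(pids, length(pids), replace = TRUE)
      idx <- unlist(by_pid[draw], use.names = FALSE)
      res <- trials[idx, , drop = FALSE]
      res$participant_id <- rep(paste0(draw, ".", seq_along(draw)),
                                lengths(by_pid[draw]))
      if (length(flip_continua) > 0) {
        flips <- flip_continua[stats::runif(length(flip_continua)) < 0.5]
        res <- flip_labels(res, flips)
      }
      as.numeric(statistic(res))
    }, numeric(length(est)))
  })
  reps <- matrix(reps, nrow = length(est))
  alpha <- (1 - level) / 2
  tibble::tibble(
    statistic = if (!is.null(names(est))) names(est) else
      as.character(seq_along(est)),
    estimate = as.numeric(est),
    ci_low = apply(reps, 1, stats::quantile, probs = alpha, names = FALSE),
    ci_high = apply(reps, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  )
}

# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Bootstrap replicates of participant-equal-weight response curves for one
# or more conditions, with the SAME participant resample per replicate
# (paired across conditions). Returns array [n_boot, 9, n_conditions].
# Control conditions get per-replicate label re-randomization of each of
# their continua, and their replicate curves are symmetrized.
boot_curve_replicates <- function(trials, conditions, n_boot, seed,
                                  symmetrize_controls = TRUE) {
  levels <- morph_levels()
  pids <- sort(unique(trials$participant_id))
  P <- length(pids)
  pid_sum <- function(m, row_pid) {
    out <- matrix(0, P, 9)
    agg <- rowsum(m, row_pid)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  prep <- lapply(conditions, function(cond) {
    tr <- trials[trials$condition == cond, , drop = FALSE]
    if (nrow(tr) == 0) stop("no trials for condition '", cond, "'",
                            call. = FALSE)
    pid <- match(tr$participant_id, pids)
    cid <- factor(tr$continuum_id)
    row <- as.integer(interaction(pid, cid, drop = TRUE))
    lev <- match(tr$morph_pct, levels)
    R <- max(row)
    s <- matrix(0, R, 9); n <- matrix(0, R, 9)
    sb <- tapply(tr$response == "B", list(row, lev), sum)
    nb <- tapply(rep(1L, nrow(tr)), list(row, lev), sum)
    ri <- as.integer(rownames(sb)); ci <- as.integer(colnames(sb))
    s[ri, ci] <- ifelse(is.na(sb), 0, sb)
    n[ri, ci] <- ifelse(is.na(nb), 0, nb)
    row_pid <- as.integer(tapply(pid, row, function(x) x[1]))
    row_cont <- as.integer(tapply(as.integer(cid), row, function(x) x[1]))
    control <- cond %in% control_conditions() && symmetrize_controls
    # without label flips the participant percentages are fixed
    pp <- if (!control) {
      ps <- pid_sum(s, row_pid); pn <- pid_sum(n, row_pid)
      p <- 100 * ps / pn
      p[pn == 0] <- NA_real_
      p
    } else NULL
    list(s = s, n = n, row_pid = row_pid, row_cont = row_cont,
         n_cont = nlevels(cid), control = control, pp = pp)
  })
  names(prep) <- conditions

  out <- array(NA_real_, c(n_boot, 9, length(conditions)),
               dimnames = list(NULL, levels, conditions))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      draw <- sample.int(P, P, replace = TRUE)
      for (j in seq_along(conditions)) {
        pr <- prep[[j]]
        if (!pr$control) {
          curve <- colMeans(pr$pp[draw, , drop = FALSE], na.rm = TRUE)
        } else {
          s <- pr$s; n <- pr$n
          flip <- stats::runif(pr$n_cont) < 0.5
          fr <- flip[pr$row_cont]
          if (any(fr)) {
            s[fr, ] <- n[fr, 9:1, drop = FALSE] - s[fr, 9:1, drop = FALSE]
            n[fr, ] <- n[fr, 9:1, drop = FALSE]
          }
          ps <- pid_sum(s, pr$row_pid)[draw, , drop = FALSE]
          pn <- pid_sum(n, pr$row_pid)[draw, , drop = FALSE]
          p <- 100 * ps / pn
          p[pn == 0] <- NA_real_
          curve <- symmetrize_values(colMeans(p, na.rm = TRUE))
        }
        out[b, , j] <- curve
      }
    }
  })
  out
}

#' Response curve with bootstrap confidence intervals
#'
#' Point estimate via [percent_b()] (symmetrized for arbitrary-label
#' control conditions), with percentile confidence bounds from the
#' participant-resampling bootstrap of [bootstrap_ci()]; for control
#' conditions each replicate re-randomizes the continuum labels before
#' symmetrizing.
#'
#' @param trials A trial tibble.
#' @param condition Condition label.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Coverage level.
#' @param symmetrized Whether to symmetrize; defaults to `TRUE` exactly for
#'   control conditions.
#' @return A `response_curve` with `ci_low`/`ci_high` filled in.
#' @export
bootstrap_curve <- function(trials, condition, n_boot = 10000, seed = 1,
                            level = 0.95,
                            symmetrized = condition %in% control_conditions()) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  curve <- percent_b(trials, condition)
  if (symmetrized) curve <- symmetrize(curve)
  reps <- boot_curve_replicates(trials, condition, n_boot, seed,
                                symmetrize_controls = symmetrized)[, , 1]
  reps <- matrix(reps, nrow = n_boot)
  alpha <- (1 - level) / 2
  curve$ci_low <- apply(reps, 2, stats::quantile, probs = alpha,
                        na.rm = TRUE, names = FALSE)
  curve$ci_high <- apply(reps, 2, stats::quantile, probs = 1 - alpha,
                         na.rm = TRUE, names = FALSE)
  curve
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve: %s%s\n", x$condition[1],
              if (is_symmetrized(x)) " (symmetrized)" else ""))
  NextMethod()
}

#' Read a packaged reference response curve
#'
#' Loads one of the packaged reference response-curve summaries (tidy
#' `condition,morph_pct,mean_pct,ci_low,ci_high,n` tables transcribed from
#' a published morphed-face familiarity study) as a `response_curve`.
#'
#' @param name Fixture name, e.g. `"exp1_curve_unfamiliar_familiar"`. See
#'   `list_curve_fixtures()` for available names.
#' @return A `response_curve`.
#' @export
curve_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "morphcp")
  if (path == "") stop("no packaged curve fixture named '", name, "'",
                       call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sym <- df$condition[1] %in% control_conditions()
  new_response_curve(tibble::tibble(
    condition = df$condition, morph_pct = as.integer(df$morph_pct),
    mean_pct = df$mean_pct, ci_low = df$ci_low, ci_high = df$ci_high,
    n_trials = if ("n" %in% names(df)) df$n else NA_integer_
  ), symmetrized = sym)
}

#' @rdname curve_fixture
#' @export
list_curve_fixtures <- function() {
  files <- list.files(system.file("extdata", package = "morphcp"),
                      pattern = "^exp[12]_curve.*\\.csv$")
  sub("\\.csv$", "", files)
}
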