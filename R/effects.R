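# Per-morph-level condition contrasts (unstandardized effect sizes) and
# the asymmetry-bias statistic quantifying the conservative criterion for
# the more familiar label.

#' Per-morph-level effect sizes between two conditions
#'
#' The effect at each morph level is the signed difference between the mean
#' percent Identity-B responses of a condition and a reference condition.
#' Both sign conventions occur in reporting practice, so the convention is
#' an explicit argument: `"reference_minus_condition"` makes a reduced
#' familiar-response rate a positive effect; `"condition_minus_reference"`
#' makes it negative.
#'
#' When `trials` are supplied, percentile confidence bounds are computed by
#' a paired participant bootstrap: the same resampled participants feed
#' both curves in every replicate, and control-condition replicates
#' re-randomize their continuum labels before symmetrization.
#'
#' @param condition_curve,reference_curve `response_curve`s sharing all
#'   nine morph levels (the reference symmetrized when its labels are
#'   arbitrary).
#' @param sign_convention `"reference_minus_condition"` (default) or
#'   `"condition_minus_reference"`.
#' @param trials Optional trial tibble for bootstrap confidence bounds.
#' @param n_boot,seed,level Bootstrap settings.
#' @return An `effect_table` tibble: `condition`, `reference`, `morph_pct`,
#'   `effect`, `ci_low`, `ci_high`.
#' @export
effect_size <- function(condition_curve, reference_curve,
                        sign_convention = c("reference_minus_condition",
                                            "condition_minus_reference"),
                        trials = NULL, n_boot = 10000, seed = 1,
                        level = 0.95) {
  sign_convention <- match.arg(sign_convention)
  levels <- morph_levels()
  if (!setequal(condition_curve$morph_pct, levels) ||
      !setequal(reference_curve$morph_pct, levels)) {
    stop("both curves must cover exactly the nine design morph levels",
         call. = FALSE)
  }
  cc <- condition_curve[match(levels, condition_curve$morph_pct), ]
  rc <- reference_curve[match(levels, reference_curve$morph_pct), ]
  sgn <- if (sign_convention == "reference_minus_condition") 1 else -1
  effect <- sgn * (rc$mean_pct - cc$mean_pct)

  ci_low <- ci_high <- rep(NA_real_, length(levels))
  if (!is.null(trials)) {
    conds <- c(cc$condition[1], rc$condition[1])
    reps <- boot_curve_replicates(
      trials, conds, n_boot, seed,
      symmetrize_controls = is_symmetrized(reference_curve) ||
        is_symmetrized(condition_curve))
    diff <- sgn * (reps[, , 2] - reps[, , 1])
    diff <- matrix(diff, nrow = n_boot)
    alpha <- (1 - level) / 2
    ci_low <- apply(diff, 2, stats::quantile, probs = alpha,
                    na.rm = TRUE, names = FALSE)
    ci_high <- apply(diff, 2, stats::quantile, probs = 1 - alpha,
                     na.rm = TRUE, names = FALSE)
  }
  structure(tibble::tibble(
    condition = cc$condition[1], reference = rc$condition[1],
    morph_pct = levels, effect = effect,
    ci_low = ci_low, ci_high = ci_high
  ), sign_convention = sign_convention,
     class = c("effect_table", class(tibble::tibble())))
}

#' Asymmetry bias of a response curve
#'
#' Quantifies the preference for the more familiar (Identity-B) label by
#' comparing each morph level `x <= 50` with its mirror level:
#' `bias(x) = f(x) - (100 - f(100 - x))`, and at the midpoint
#' `bias(50) = f(50) - 50`. Negative values indicate a conservative
#' criterion for the more familiar identity; a symmetrized curve has zero
#' bias everywhere.
#'
#' @param curve A `response_curve` covering all nine morph levels, for a
#'   condition with a meaningful more-familiar Identity B.
#' @param trials Optional trial tibble for bootstrap confidence bounds
#'   (participant resampling, paired within replicate).
#' @param n_boot,seed,level Bootstrap settings.
#' @return A `bias_table` tibble: `condition`, `x`, `bias`, `ci_low`,
#'   `ci_high`, for `x` in 10, 20, 30, 40, 50.
#' @export
asymmetry_bias <- function(curve, trials = NULL, n_boot = 10000, seed = 1,
                           level = 0.95) {
  levels <- morph_levels()
  if (!setequal(curve$morph_pct, levels)) {
    stop("curve must cover exactly the nine design morph levels",
         call. = FALSE)
  }
  curve <- curve[match(levels, curve$morph_pct), ]
  x <- levels[levels <= 50L]
  bias <- bias_values(curve$mean_pct)

  ci_low <- ci_high <- rep(NA_real_, length(x))
  if (!is.null(trials)) {
    reps <- boot_curve_replicates(trials, curve$condition[1], n_boot, seed)
    breps <- t(apply(matrix(reps, nrow = n_boot), 1, bias_values))
    alpha <- (1 - level) / 2
    ci_low <- apply(breps, 2, stats::quantile, probs = alpha,
                    na.rm = TRUE, names = FALSE)
    ci_high <- apply(breps, 2, stats::quantile, probs = 1 - alpha,
                     na.rm = TRUE, names = FALSE)
  }
  structure(tibble::tibble(
    condition = curve$condition[1], x = x, bias = bias,
    ci_low = ci_low, ci_high = ci_high
  ), class = c("bias_table", class(tibble::tibble())))
}

# f ordered by morph_levels(); bias for x in {10,...,50}
bias_values <- function(f) {
  levels <- morph_levels()
  x <- levels[levels <= 50L]
  vapply(x, function(xi) {
    fy <- if (xi == 50L) 50 else f[levels == 100L - xi]
    f[levels == xi] - (100 - fy)
  }, numeric(1))
}
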