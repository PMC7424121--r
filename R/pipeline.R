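# End-to-end pipeline: read -> filter -> aggregate -> symmetrize ->
# effects/bias -> choice GLMM + RT LMM -> PSE, with tidy table outputs and
# a reproducible run log.

#' Analysis configuration
#'
#' @param trials_path Path to the trial CSV table.
#' @param out_dir Output directory (created if missing).
#' @param experiment `"exp1"` or `"exp2"`; selects the condition structure
#'   and the default effect-size comparisons and sign conventions.
#' @param continua_path Optional continuum sidecar table.
#' @param n_boot Bootstrap replicates for all confidence intervals.
#' @param seed Integer seed driving every stochastic step.
#' @param level Confidence level.
#' @param scaling Morph scaling passed to [model_spec()].
#' @param verbose Print stage-level progress.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(trials_path, out_dir,
                            experiment = c("exp1", "exp2"),
                            continua_path = NULL,
                            n_boot = 1000, seed = 1, level = 0.95,
                            scaling = "zscore_over_trials",
                            verbose = TRUE) {
  experiment <- match.arg(experiment)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  structure(list(trials_path = trials_path, out_dir = out_dir,
                 experiment = experiment, continua_path = continua_path,
                 n_boot = n_boot, seed = seed, level = level,
                 scaling = scaling, verbose = verbose),
            class = "analysis_config")
}

# default comparisons: (condition, reference, sign convention) per design
default_comparisons <- function(experiment) {
  if (experiment == "exp1") {
    list(list(condition = "unfamiliar_familiar",
              reference = "unfamiliar_unfamiliar",
              sign_convention = "reference_minus_condition"))
  } else {
    list(
      list(condition = "stranger_friend", reference = "stranger_stranger",
           sign_convention = "condition_minus_reference"),
      list(condition = "stranger_self", reference = "stranger_stranger",
           sign_convention = "condition_minus_reference"),
      list(condition = "friend_self", reference = "friend_friend",
           sign_convention = "condition_minus_reference"))
  }
}

#' Run the full analysis pipeline
#'
#' Executes read, filter, aggregation (with symmetrization of control
#' conditions), effect sizes, asymmetry bias, choice GLMM, reaction-time
#' LMM and PSE estimation, writing tidy delimited tables and JSON model
#' reports to `config$out_dir`. Re-running with an identical configuration
#' reproduces the outputs byte for byte. A failing stage raises an error
#' naming the stage.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  note("morphcp %s | experiment=%s seed=%d n_boot=%d level=%.2f",
       as.character(utils::packageVersion("morphcp")),
       config$experiment, config$seed, config$n_boot, config$level)

  dat <- stage("read", read_trials(config$trials_path,
                                   config$continua_path))
  trials <- dat$trials
  note("read: %d trials, %d continua, %d participants", nrow(trials),
       nrow(dat$continua), length(unique(trials$participant_id)))

  conds <- intersect(design_conditions(config$experiment),
                     unique(trials$condition))
  if (length(conds) == 0) {
    stop("pipeline stage 'aggregate' failed: no trials from the ",
         config$experiment, " condition set", call. = FALSE)
  }

  curves <- stage("aggregate", {
    lapply(stats::setNames(conds, conds), function(cond) {
      bootstrap_curve(trials, cond, n_boot = config$n_boot,
                      seed = config$seed, level = config$level)
    })
  })
  note("aggregate: %d condition curves (controls symmetrized)",
       length(curves))

  comparisons <- Filter(function(cmp) {
    cmp$condition %in% conds && cmp$reference %in% conds
  }, default_comparisons(config$experiment))
  effects <- stage("effects", {
    lapply(comparisons, function(cmp) {
      effect_size(curves[[cmp$condition]], curves[[cmp$reference]],
                  sign_convention = cmp$sign_convention, trials = trials,
                  n_boot = config$n_boot, seed = config$seed,
                  level = config$level)
    })
  })
  biases <- stage("bias", {
    fam <- setdiff(conds, control_conditions())
    lapply(stats::setNames(fam, fam), function(cond) {
      asymmetry_bias(curves[[cond]], trials = trials,
                     n_boot = config$n_boot, seed = config$seed,
                     level = config$level)
    })
  })
  note("effects: %d comparisons; bias: %d conditions", length(effects),
       length(biases))

  spec_choice <- model_spec("choice", scaling = config$scaling)
  choice_fit <- stage("choice_model", fit_binomial_glmm(trials,
                                                        spec_choice))
  choice_wald <- stage("choice_model", wald_type3(choice_fit))
  reference <- if (config$experiment == "exp1") "unfamiliar_unfamiliar"
               else "stranger_stranger"
  pse <- stage("pse", {
    dplyr::bind_rows(lapply(conds, function(cond) {
      estimate_pse(choice_fit, cond,
                   reference = if (cond != reference &&
                                   reference %in% conds) reference)
    }))
  })
  note("choice model: converged=%s loglik=%.2f", choice_fit$converged,
       choice_fit$loglik)

  filtered <- stage("rt_filter", filter_for_rt(trials))
  note("rt filter: retained %d of %d trials (fast=%d slow=%d midpoint=%d incorrect=%d)",
       filtered$report$n_retained, filtered$report$n_input,
       filtered$report$n_rt_fast, filtered$report$n_rt_slow,
       filtered$report$n_midpoint, filtered$report$n_incorrect)
  spec_rt <- model_spec("log_rt", scaling = config$scaling)
  rt_fit <- stage("rt_model", fit_linear_mixed(filtered$trials, spec_rt))
  rt_wald <- stage("rt_model", wald_type3(rt_fit))
  note("rt model: converged=%s loglik=%.2f", rt_fit$converged,
       rt_fit$loglik)

  stage("write", {
    utils::write.csv(dplyr::bind_rows(curves),
                     file.path(config$out_dir, "curves.csv"),
                     row.names = FALSE, quote = FALSE)
    if (length(effects) > 0) {
      utils::write.csv(dplyr::bind_rows(effects),
                       file.path(config$out_dir, "effects.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (length(biases) > 0) {
      utils::write.csv(dplyr::bind_rows(biases),
                       file.path(config$out_dir, "bias.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(choice = model_report(choice_fit, choice_wald, pse),
           rt = model_report(rt_fit, rt_wald, NULL),
           filter = unclass(filtered$report)),
      file.path(config$out_dir, "models.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  })

  invisible(list(trials = trials, continua = dat$continua,
                 curves = curves, effects = effects, biases = biases,
                 choice_fit = choice_fit, choice_wald = choice_wald,
                 pse = pse, rt_fit = rt_fit, rt_wald = rt_wald,
                 filter_report = filtered$report))
}

model_report <- function(fit, wald, pse) {
  rep <- list(
    family = fit$family,
    coefficients = as.list(fit$beta),
    std_errors = as.list(stats::setNames(sqrt(diag(fit$vcov_beta)),
                                         names(fit$beta))),
    random_sd = as.list(fit$sigma),
    residual_sd = fit$sigma_resid,
    loglik = fit$loglik,
    converged = fit$converged,
    n_obs = fit$n_obs,
    wald = as.data.frame(wald)
  )
  if (!is.null(pse)) rep$pse <- as.data.frame(pse)
  rep
}

#' Write packaged reference tables and matched trial fixtures
#'
#' Copies the packaged reference response-curve, effect-size and
#' reaction-time tables into `dir` and generates matched synthetic trial
#' sets: trial tables with the exact design shape of each experiment whose
#' aggregated (and, for control conditions, symmetrized) response curves
#' reproduce the reference percentages to one decimal place. Responses are
#' assigned by choosing the integer Identity-B count closest to each
#' reference percentage; reaction times follow the deterministic
#' ambiguity profile (no noise), so the fixture is for arithmetic checks,
#' not RT inference.
#'
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- system.file("extdata", package = "morphcp")
  src <- list.files(ext, pattern = "\\.csv$", full.names = TRUE)
  file.copy(src, dir, overwrite = TRUE)
  written <- file.path(dir, basename(src))

  p1 <- file.path(dir, "exp1_matched_trials.csv")
  write_trials(matched_trials("exp1"), p1)
  p2 <- file.path(dir, "exp2_matched_trials.csv")
  write_trials(matched_trials("exp2"), p2)
  invisible(c(written, p1, p2))
}

# reference mean percentages used to build the matched trial sets; control
# conditions are stored as the raw (point-symmetric) curve whose
# symmetrization reproduces the reference values
fixture_targets <- function(design) {
  if (design == "exp1") {
    uf <- curve_fixture("exp1_curve_unfamiliar_familiar")$mean_pct
    uu <- curve_fixture("exp1_curve_unfamiliar_unfamiliar")$mean_pct
    uu <- make_point_symmetric(uu)
    list(unfamiliar_familiar = uf, unfamiliar_unfamiliar = uu)
  } else {
    out <- lapply(stats::setNames(nm = design_conditions("exp2")),
                  function(cond) {
      f <- curve_fixture(paste0("exp2_curve_", cond))$mean_pct
      if (cond %in% control_conditions()) f <- make_point_symmetric(f)
      f
    })
    out
  }
}

# raw curve g with g(x) = f(x) for x <= 50 and g(100-x) = 100 - f(x): its
# symmetrization equals f at every level at or below 50 (and differs from
# a printed upper tail only where the printed table is internally
# inconsistent by rounding)
make_point_symmetric <- function(f) {
  lev <- morph_levels()
  g <- f
  g[lev > 50] <- 100 - rev(f[lev < 50])
  g
}

# design-shaped trial set whose pooled percent-B matches the targets to
# the nearest achievable count
matched_trials <- function(design) {
  targets <- fixture_targets(design)
  cfg <- simulation_config(design = design, seed = 1L)
  layout <- design_continua(cfg)
  pids <- sprintf("p%02d", seq_len(cfg$n_participants))
  reps <- if (design == "exp1") 12L else 10L
  levels <- morph_levels()

  rows <- list()
  for (li in seq_along(layout$stub)) {
    cond <- layout$condition[li]
    for (p in pids) {
      cid <- if (design == "exp1") layout$stub[li]
             else paste(p, layout$stub[li], sep = "_")
      for (m in levels) {
        block <- if (design == "exp1") {
          ((seq_len(reps) - 1L) %/% 4L) + 1L +
            if (cond == "unfamiliar_unfamiliar") 3L else 0L
        } else seq_len(reps)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant_id = p, continuum_id = cid, condition = cond,
          morph_pct = m,
          rt_ms = 700 * exp(0.25 * (1 - abs(m - 50) / 40)),
          block = block)
      }
    }
  }
  trials <- dplyr::bind_rows(rows)
  trials <- trials[order(trials$condition, trials$morph_pct,
                         trials$participant_id, trials$continuum_id,
                         trials$block), ]
  # per (condition, level): first `round(target/100 * n)` trials answer B
  trials$response <- "A"
  for (cond in names(targets)) {
    for (i in seq_along(levels)) {
      idx <- which(trials$condition == cond &
                     trials$morph_pct == levels[i])
      k <- round(targets[[cond]][i] / 100 * length(idx))
      trials$response[idx[seq_len(k)]] <- "B"
    }
  }
  trials[, c("participant_id", "continuum_id", "condition", "morph_pct",
             "response", "rt_ms", "block")]
}
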