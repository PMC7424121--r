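# Synthetic trial generator emulating the two experimental designs:
# lapse-adjusted logistic choice with condition-specific boundary shifts,
# crossed participant/continuum random intercepts, and lognormal reaction
# times peaking at the ambiguous midpoint of the continuum.

#' Default boundary locations per condition
#'
#' Point of subjective equality (PSE), in morph-percent units, for each
#' condition of a design. Control continua sit at 50; conditions whose
#' Identity-B endpoint is the more familiar face are shifted to 55,
#' reflecting the conservative criterion for the familiar label.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @return Named numeric vector of PSEs.
#' @export
default_pse <- function(design = c("exp1", "exp2")) {
  design <- match.arg(design)
  conds <- design_conditions(design)
  pse <- ifelse(conds %in% control_conditions(), 50, 55)
  stats::setNames(pse, conds)
}

#' Simulation configuration
#'
#' Full generative specification for [simulate_trials()]. Defaults encode
#' the study conditions the generator emulates: 15 participants; Exp 1 with
#' three familiar--unfamiliar and three unfamiliar--unfamiliar continua at
#' 12 presentations per morph image (six blocks of 108 trials); Exp 2 with
#' ten continua per participant across five conditions at 10 presentations
#' per stimulus (ten blocks of 90 intermixed trials).
#'
#' The choice model is a lapse-adjusted logistic:
#' `P(B) = lapse/2 + (1 - lapse) * plogis(slope * (m - pse_k) + u_i + v_c)`
#' with participant intercepts `u_i ~ N(0, sd_participant^2)` and continuum
#' intercepts `v_c ~ N(0, sd_continuum^2)`. Setting `lapse = 0` gives the
#' pure logistic mixed model that the inference module fits.
#'
#' Reaction times are lognormal with location
#' `rt_base_log + rt_condition_offsets[k] + rt_ambiguity_gain * (1 - |m - 50| / 40)`
#' and scale `rt_sd_log`, truncated to (0, 10 s].
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param n_participants Number of participants.
#' @param pse_by_condition Named numeric vector, condition -> boundary
#'   location in morph-percent units.
#' @param slope Logistic steepness per morph-percent unit.
#' @param lapse Lapse rate in `[0, 1]`: probability of a stimulus-independent
#'   guess trial (split evenly between the two responses).
#' @param sd_participant,sd_continuum Random-intercept standard deviations
#'   on the logit scale.
#' @param rt_base_log Mean log reaction time (log-milliseconds) at the
#'   unambiguous ends of the continuum.
#' @param rt_ambiguity_gain Added mean log-RT at the 50% morph, interpolated
#'   linearly in `1 - |m - 50| / 40`.
#' @param rt_condition_offsets Named numeric vector of additive log-RT
#'   shifts per condition; missing conditions default to 0.
#' @param rt_sd_log Lognormal scale parameter (> 0).
#' @param seed Integer seed; identical configs give identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = c("exp1", "exp2"),
                              n_participants = 15L,
                              pse_by_condition = default_pse(design),
                              slope = 0.15,
                              lapse = 0.02,
                              sd_participant = 0.5,
                              sd_continuum = 0.3,
                              rt_base_log = log(700),
                              rt_ambiguity_gain = 0.25,
                              rt_condition_offsets = NULL,
                              rt_sd_log = 0.35,
                              seed = 1L) {
  design <- match.arg(design)
  conds <- design_conditions(design)
  stopifnot(n_participants >= 1, slope >= 0,
            lapse >= 0, lapse <= 1,
            sd_participant >= 0, sd_continuum >= 0,
            rt_ambiguity_gain >= 0, rt_sd_log > 0)
  unknown <- setdiff(names(pse_by_condition), conds)
  if (length(unknown) > 0) {
    stop("pse_by_condition names unknown condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(conds %in% names(pse_by_condition))) {
    stop("pse_by_condition must cover every condition of the design: ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  if (is.null(rt_condition_offsets)) {
    slow_cond <- switch(design, exp1 = "unfamiliar_familiar",
                        exp2 = "stranger_stranger")
    rt_condition_offsets <- stats::setNames(
      ifelse(conds == slow_cond, 0.08, 0), conds)
  }
  unknown <- setdiff(names(rt_condition_offsets), conds)
  if (length(unknown) > 0) {
    stop("rt_condition_offsets names unknown condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  offsets <- stats::setNames(rep(0, length(conds)), conds)
  offsets[names(rt_condition_offsets)] <- rt_condition_offsets

  structure(list(
    design = design,
    n_participants = as.integer(n_participants),
    pse_by_condition = pse_by_condition[conds],
    slope = slope,
    lapse = lapse,
    sd_participant = sd_participant,
    sd_continuum = sd_continuum,
    rt_base_log = rt_base_log,
    rt_ambiguity_gain = rt_ambiguity_gain,
    rt_condition_offsets = offsets,
    rt_sd_log = rt_sd_log,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path Path to a YAML or JSON file whose fields mirror the
#'   arguments of [simulation_config()].
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (nm in c("pse_by_condition", "rt_condition_offsets")) {
    if (!is.null(fields[[nm]])) fields[[nm]] <- unlist(fields[[nm]])
  }
  do.call(simulation_config, fields)
}

# Design layout: one row per continuum with condition and per-participant
# nesting flag. Exp 1 continua are shared across participants; Exp 2
# continua are unique per participant.
design_continua <- function(config) {
  if (config$design == "exp1") {
    tibble::tibble(
      stub = c(paste0("uf", 1:3), paste0("uu", 1:3)),
      condition = rep(design_conditions("exp1"), each = 3)
    )
  } else {
    tibble::tibble(
      stub = c(paste0("sf", 1:4), paste0("ss", 1:2), paste0("fs", 1:2),
               "st", "ff"),
      condition = c(rep("stranger_friend", 4), rep("stranger_self", 2),
                    rep("friend_self", 2), "stranger_stranger",
                    "friend_friend")
    )
  }
}

# Shuffle trial indices within a block so that consecutive trials never
# come from the same continuum. Both designs present each continuum equally
# often within a block, so a round-robin of shuffled continuum rounds (with
# a boundary swap when one round ends with the continuum the next starts
# with) satisfies the constraint exactly; degenerate blocks (a single
# continuum) fall back to a plain shuffle.
shuffle_block <- function(continuum) {
  n <- length(continuum)
  ids <- unique(continuum)
  k <- length(ids)
  counts <- table(continuum)
  if (k < 2 || length(unique(counts)) != 1) return(sample.int(n))
  r <- as.integer(counts[1])
  rounds <- vapply(seq_len(r), function(j) sample(ids), character(k))
  for (j in seq_len(r - 1)) {
    if (rounds[1, j + 1] == rounds[k, j]) {
      rounds[1:2, j + 1] <- rounds[2:1, j + 1]
    }
  }
  # map the continuum sequence back to shuffled trial indices
  seq_ids <- as.vector(rounds)
  ord <- integer(n)
  for (id in ids) {
    ord[seq_ids == id] <- sample(which(continuum == id))
  }
  ord
}

#' Simulate trial-level data
#'
#' Generates a full synthetic dataset under the configured design, together
#' with the continuum table and a ground-truth record of every latent draw.
#'
#' @param config A [simulation_config()].
#' @return A list with `trials` (tibble), `continua` (tibble) and `truth`
#'   (list with participant intercepts `u`, continuum intercepts `v`,
#'   per-trial success probabilities, and the config).
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  pids <- sprintf("p%02d", seq_len(config$n_participants))
  u <- stats::setNames(stats::rnorm(length(pids), 0, config$sd_participant),
                       pids)
  layout <- design_continua(config)

  if (config$design == "exp1") {
    continua <- tibble::tibble(
      continuum_id = layout$stub,
      condition = layout$condition
    )
    reps <- 12L
  } else {
    continua <- tibble::tibble(
      continuum_id = as.vector(t(outer(pids, layout$stub, paste, sep = "_"))),
      condition = rep(layout$condition, times = length(pids)),
      participant_id = rep(pids, each = nrow(layout))
    )
    reps <- 10L
  }
  v <- stats::setNames(
    stats::rnorm(nrow(continua), 0, config$sd_continuum),
    continua$continuum_id)

  levels <- morph_levels()
  if (config$design == "exp1") {
    # 3 blocks per condition; each block holds 4 reps x 9 levels x 3 continua
    per_participant <- do.call(rbind, lapply(seq_len(6L), function(b) {
      cond <- design_conditions("exp1")[(b - 1) %/% 3 + 1]
      ids <- continua$continuum_id[continua$condition == cond]
      g <- expand.grid(continuum_id = ids, morph_pct = levels,
                       rep = 1:4, stringsAsFactors = FALSE)
      g$block <- b
      g$condition <- cond
      g
    }))
    trials <- do.call(rbind, lapply(pids, function(p) {
      d <- per_participant
      d$participant_id <- p
      d
    }))
  } else {
    trials <- do.call(rbind, lapply(pids, function(p) {
      ids <- continua$continuum_id[continua$participant_id == p]
      cond <- continua$condition[continua$participant_id == p]
      stim <- expand.grid(idx = seq_along(ids), morph_pct = levels,
                          stringsAsFactors = FALSE)   # 90 unique stimuli
      d <- do.call(rbind, lapply(seq_len(reps), function(b) {
        s <- stim
        s$block <- b
        s
      }))
      d$continuum_id <- ids[d$idx]
      d$condition <- cond[d$idx]
      d$participant_id <- p
      d[, c("continuum_id", "morph_pct", "block", "condition",
            "participant_id")]
    }))
  }

  # within-block shuffle, no identical continuum on consecutive trials
  key <- paste(trials$participant_id, trials$block)
  ord <- unlist(lapply(split(seq_len(nrow(trials)), key), function(idx) {
    idx[shuffle_block(trials$continuum_id[idx])]
  }), use.names = FALSE)
  trials <- trials[ord, ]

  pse <- config$pse_by_condition[trials$condition]
  eta <- config$slope * (trials$morph_pct - pse) +
    u[trials$participant_id] + v[trials$continuum_id]
  p_b <- config$lapse / 2 + (1 - config$lapse) * stats::plogis(eta)
  resp_b <- stats::runif(nrow(trials)) < p_b

  meanlog <- config$rt_base_log +
    config$rt_condition_offsets[trials$condition] +
    config$rt_ambiguity_gain * (1 - abs(trials$morph_pct - 50) / 40)
  rt <- stats::rlnorm(nrow(trials), meanlog, config$rt_sd_log)
  while (any(rt > 10000)) {   # truncate to (0, 10 s] by redrawing
    i <- which(rt > 10000)
    rt[i] <- stats::rlnorm(length(i), meanlog[i], config$rt_sd_log)
  }

  out <- tibble::tibble(
    participant_id = trials$participant_id,
    continuum_id = trials$continuum_id,
    condition = trials$condition,
    morph_pct = as.integer(trials$morph_pct),
    response = ifelse(resp_b, "B", "A"),
    rt_ms = rt,
    block = as.integer(trials$block)
  )
  continua_out <- tibble::tibble(
    continuum_id = continua$continuum_id,
    identity_A = paste0(continua$continuum_id, "_A"),
    identity_B = paste0(continua$continuum_id, "_B"),
    condition = continua$condition,
    b_is_more_familiar = b_is_more_familiar(continua$condition)
  )
  list(
    trials = out,
    continua = continua_out,
    truth = list(u = u, v = v, p_b = p_b, config = config)
  )
}
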