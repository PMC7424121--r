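# Synthetic-data generator: design structure, determinism, and agreement
# of the simulated choices and reaction times with the generative model.

test_that("identical configs give identical output and seeds are local", {
  cfg <- simulation_config("exp1", n_participants = 3, seed = 42)
  set.seed(999)
  a <- simulate_trials(cfg)
  x <- runif(1)
  set.seed(999)
  b <- simulate_trials(cfg)
  y <- runif(1)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$u, b$truth$u)
  expect_identical(x, y)   # the generator does not disturb the caller RNG
})

test_that("both designs produce their exact trial-count structure", {
  s1 <- simulate_trials(simulation_config("exp1", n_participants = 2,
                                          seed = 1))
  expect_equal(nrow(s1$trials), 2 * 6 * 9 * 12)
  expect_equal(nrow(s1$continua), 6)
  p <- s1$trials[s1$trials$participant_id == "p01", ]
  expect_equal(as.vector(table(p$block)), rep(108L, 6))

  s2 <- simulate_trials(simulation_config("exp2", n_participants = 2,
                                          seed = 1))
  expect_equal(nrow(s2$trials), 2 * 10 * 9 * 10)
  expect_equal(nrow(s2$continua), 20)
  counts <- table(s2$continua$condition) / 2   # continua per participant
  expect_equal(counts[["stranger_friend"]], 4)
  expect_equal(counts[["stranger_self"]], 2)
  expect_equal(counts[["friend_self"]], 2)
  expect_equal(counts[["stranger_stranger"]], 1)
  expect_equal(counts[["friend_friend"]], 1)
  p <- s2$trials[s2$trials$participant_id == "p01", ]
  expect_equal(as.vector(table(p$block)), rep(90L, 10))
})

test_that("no two consecutive trials within a block share a continuum", {
  for (design in c("exp1", "exp2")) {
    sim <- simulate_trials(simulation_config(design, n_participants = 2,
                                             seed = 7))
    by_block <- split(sim$trials$continuum_id,
                      paste(sim$trials$participant_id, sim$trials$block))
    for (cont in by_block) {
      expect_false(any(cont[-1] == cont[-length(cont)]))
    }
  }
})

test_that("pure guessing (lapse = 1) yields ~50% at every level", {
  sim <- simulate_trials(simulation_config("exp1", lapse = 1, seed = 8))
  curve <- percent_b(sim$trials, "unfamiliar_familiar",
                     grouping = "pooled")
  # 1080 Bernoulli(0.5) trials per level: 3 binomial SEs ~ 4.6 pp
  expect_true(all(abs(curve$mean_pct - 50) < 4.6))
})

test_that("a steep, noiseless psychometric function becomes a step", {
  cfg <- simulation_config("exp1", slope = 10, lapse = 0,
                           sd_participant = 0, sd_continuum = 0,
                           pse_by_condition = c(unfamiliar_familiar = 50,
                                                unfamiliar_unfamiliar = 50),
                           seed = 9)
  sim <- simulate_trials(cfg)
  curve <- percent_b(sim$trials, "unfamiliar_familiar",
                     grouping = "pooled")
  expect_true(all(curve$mean_pct[curve$morph_pct < 50] < 0.5))
  expect_true(all(curve$mean_pct[curve$morph_pct > 50] > 99.5))
})

test_that("the midpoint gap between shifted and control conditions matches the closed form", {
  cfg <- simulation_config("exp1", slope = 0.15, lapse = 0.02,
                           sd_participant = 0.5, sd_continuum = 0,
                           pse_by_condition = c(unfamiliar_familiar = 55,
                                                unfamiliar_unfamiliar = 50),
                           seed = 42)
  sim <- simulate_trials(cfg)
  pp <- function(cond) {
    tr <- sim$trials[sim$trials$condition == cond &
                       sim$trials$morph_pct == 50L, ]
    tapply(tr$response == "B", tr$participant_id, mean) * 100
  }
  shifted <- pp("unfamiliar_familiar")
  control <- pp("unfamiliar_unfamiliar")
  gap <- mean(control) - mean(shifted)
  expected_gap <-
    expected_percent_b(50, 50, 0.15, 0.02, 0.5) -
    expected_percent_b(50, 55, 0.15, 0.02, 0.5)
  # participant means are paired (same intercepts), so use the paired SE
  se <- sd(control - shifted) / sqrt(length(shifted))
  expect_lt(abs(gap - expected_gap), 3 * se)
  expect_lt(mean(shifted), mean(control))
})

test_that("marginal response frequencies converge to the analytic curve at 10x size", {
  cfg <- simulation_config("exp1", n_participants = 150, lapse = 0.02,
                           sd_participant = 0.5, sd_continuum = 0,
                           seed = 10)
  sim <- simulate_trials(cfg)
  for (cond in design_conditions("exp1")) {
    tr <- sim$trials[sim$trials$condition == cond, ]
    pmat <- 100 * tapply(tr$response == "B",
                         list(tr$participant_id, tr$morph_pct), mean)
    emp <- colMeans(pmat)
    se <- apply(pmat, 2, sd) / sqrt(nrow(pmat))
    for (i in seq_along(morph_levels())) {
      ana <- expected_percent_b(morph_levels()[i],
                                cfg$pse_by_condition[[cond]],
                                cfg$slope, cfg$lapse, cfg$sd_participant)
      expect_lt(abs(emp[i] - ana), 3 * se[i] + 0.3)
    }
  }
})

test_that("mean log-RT at the midpoint exceeds the ends by the ambiguity gain", {
  sim <- simulate_trials(simulation_config("exp1", seed = 12))
  for (cond in design_conditions("exp1")) {
    tr <- sim$trials[sim$trials$condition == cond, ]
    at <- function(m) log(tr$rt_ms[tr$morph_pct == m])
    mid <- at(50); end <- at(10)
    gain_hat <- mean(mid) - mean(end)
    se <- sqrt(var(mid) / length(mid) + var(end) / length(end))
    expect_lt(abs(gain_hat - 0.25), 3 * se)
  }
})

test_that("config validation rejects unknown or incomplete condition maps", {
  expect_error(simulation_config("exp1",
                                 pse_by_condition = c(bogus = 50)),
               "unknown condition")
  expect_error(simulation_config("exp1",
                                 pse_by_condition = c(unfamiliar_familiar = 55)),
               "every condition")
  expect_error(simulation_config("exp1", lapse = 1.2))
})

test_that("config round-trips through a JSON file", {
  cfg <- simulation_config("exp2", slope = 0.2, seed = 3)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lapply(unclass(cfg), function(x)
    if (is.null(names(x))) x else as.list(x)), js,
    auto_unbox = TRUE, digits = NA)
  back <- read_simulation_config(js)
  expect_equal(back$slope, 0.2)
  expect_equal(back$pse_by_condition, cfg$pse_by_condition)
  a <- simulate_trials(back)$trials
  b <- simulate_trials(cfg)$trials
  expect_identical(a$response, b$response)
  expect_equal(a$rt_ms, b$rt_ms, tolerance = 1e-9)
})
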