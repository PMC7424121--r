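# Mixed-model inference: Laplace GLMM, Gaussian LMM, Type-3 Wald tests and
# PSE estimation, validated against independent oracles.

sim_exp1 <- function(seed, ...) {
  simulate_trials(simulation_config("exp1", lapse = 0, seed = seed, ...))
}

test_that("with zero true random variance the GLMM collapses to plain logistic regression", {
  sim <- sim_exp1(101, n_participants = 30, sd_participant = 0,
                  sd_continuum = 0)
  fit <- fit_binomial_glmm(sim$trials)
  expect_true(fit$converged)
  expect_true(all(fit$sigma^2 < 0.01))

  # independent IRLS oracle: stats::glm on the same design
  d <- sim$trials
  d$y <- as.integer(d$response == "B")
  d$ms <- (d$morph_pct - 50) / sd(d$morph_pct)
  d$cond <- factor(d$condition)
  contrasts(d$cond) <- contr.sum(2)
  g <- glm(y ~ ms * cond, family = binomial, data = d)
  expect_true(all(abs(fit$beta - unname(coef(g))) < 1e-3))
})

test_that("the Laplace log-likelihood agrees with adaptive quadrature on a tiny instance", {
  set.seed(4)
  m5 <- rep(rep(c(20L, 40L, 50L, 60L, 80L), 4), 3)
  tr <- make_trials(
    participant_id = rep(sprintf("p%d", 1:3), each = 20),
    continuum_id = "c1", condition = "unfamiliar_familiar",
    morph_pct = m5,
    response = ifelse(runif(60) < plogis((m5 - 50) / 12 +
                                           rep(rnorm(3, 0, 1), each = 20)),
                      "B", "A"),
    rt_ms = 800)
  spec <- model_spec("choice", random = "participant")
  fit <- fit_binomial_glmm(tr, spec)
  quad <- quad_marginal_loglik(tr, fit$beta[1:2], fit$sigma[["participant"]],
                               center = fit$center, scale = fit$scale)
  expect_lt(abs(fit$loglik - quad), 0.1)
  # the Laplace approximation should not overshoot the exact likelihood
  expect_lt(fit$loglik, quad + 1e-3)
})

test_that("GLMM estimates agree with an independently implemented Laplace fitter", {
  skip_if_not_installed("lme4")
  sim <- sim_exp1(103)
  fit <- fit_binomial_glmm(sim$trials)
  d <- sim$trials
  d$y <- as.integer(d$response == "B")
  d$ms <- (d$morph_pct - 50) / sd(d$morph_pct)
  d$cond <- factor(d$condition)
  contrasts(d$cond) <- contr.sum(2)
  m <- lme4::glmer(y ~ ms * cond + (1 | participant_id) +
                     (1 | continuum_id),
                   data = d, family = binomial)
  expect_true(all(abs(fit$beta - unname(lme4::fixef(m))) < 0.02))
  sds <- sqrt(unlist(lme4::VarCorr(m)))
  expect_lt(abs(fit$sigma[["participant"]] - sds[["participant_id"]]), 0.02)
  expect_lt(abs(fit$sigma[["continuum"]] - sds[["continuum_id"]]), 0.02)
})

test_that("the LMM maximizes the same marginal likelihood as a reference ML fitter", {
  skip_if_not_installed("lme4")
  sim <- sim_exp1(104)
  flt <- filter_for_rt(sim$trials)
  fit <- fit_linear_mixed(flt$trials)
  d <- flt$trials
  d$ly <- log(d$rt_ms)
  d$ms <- (d$morph_pct - 50) / sd(d$morph_pct)
  d$cond <- factor(d$condition)
  contrasts(d$cond) <- contr.sum(2)
  m <- lme4::lmer(ly ~ ms * cond + (1 | participant_id) +
                    (1 | continuum_id), data = d, REML = FALSE)
  expect_lt(abs(fit$loglik - as.numeric(logLik(m))), 1e-4)
  expect_true(all(abs(fit$beta - unname(lme4::fixef(m))) < 1e-5))
  expect_lt(abs(fit$sigma_resid - stats::sigma(m)), 1e-5)
})

test_that("with zero random variance the LMM matches ordinary least squares", {
  sim <- sim_exp1(105, sd_participant = 0, sd_continuum = 0)
  flt <- filter_for_rt(sim$trials)
  fit <- fit_linear_mixed(flt$trials)
  d <- flt$trials
  d$ly <- log(d$rt_ms)
  d$ms <- (d$morph_pct - 50) / sd(d$morph_pct)
  d$cond <- factor(d$condition)
  contrasts(d$cond) <- contr.sum(2)
  ls <- lm(ly ~ ms * cond, data = d)
  expect_true(all(abs(fit$beta - unname(coef(ls))) < 1e-4))
})

test_that("a single-participant dataset falls back to fixed effects with a warning", {
  tr <- make_balanced_trials(n_participants = 1, reps = 12, seed = 6)
  tr$rt_ms <- exp(rnorm(nrow(tr), log(700), 0.3))
  flt <- filter_for_rt(tr)
  expect_warning(fit <- fit_linear_mixed(
    flt$trials, model_spec("log_rt", random = "participant")),
    "single level")
  expect_true(fit$converged)
  expect_equal(length(fit$sigma), 0)
})

test_that("adding a constant to all log RTs shifts only the intercept", {
  sim <- sim_exp1(106, n_participants = 6)
  flt <- filter_for_rt(sim$trials)
  f1 <- fit_linear_mixed(flt$trials)
  shifted <- flt$trials
  shifted$rt_ms <- shifted$rt_ms * exp(1)
  f2 <- fit_linear_mixed(shifted)
  expect_lt(abs((f2$beta[1] - f1$beta[1]) - 1), 1e-6)
  expect_true(all(abs(f2$beta[-1] - f1$beta[-1]) < 1e-6))
})

test_that("Type-3 Wald statistics are invariant to relabeling conditions", {
  sim <- simulate_trials(simulation_config("exp2", n_participants = 6,
                                           lapse = 0, seed = 107))
  fit1 <- fit_binomial_glmm(sim$trials)
  w1 <- wald_type3(fit1)
  relabeled <- sim$trials
  # bijective relabeling permutes the factor ordering
  map <- c(stranger_friend = "zz_sf", stranger_self = "aa_ss",
           friend_self = "mm_fs", stranger_stranger = "stranger_stranger",
           friend_friend = "friend_friend")
  relabeled$condition <- unname(map[relabeled$condition])
  # bypass the condition vocabulary check by fitting directly
  fit2 <- fit_binomial_glmm(relabeled)
  w2 <- wald_type3(fit2)
  expect_equal(w1$chisq, w2$chisq, tolerance = 1e-4)
  expect_equal(w1$df, w2$df)
})

test_that("Wald identities: zero block and single-coefficient term", {
  sim <- sim_exp1(108, n_participants = 6)
  fit <- fit_binomial_glmm(sim$trials)
  w <- wald_type3(fit)
  i <- which(fit$assign == 1)
  expect_equal(w$chisq[w$term == "morph_pct"],
               (fit$beta[i] / sqrt(fit$vcov_beta[i, i]))^2,
               ignore_attr = TRUE)

  fit0 <- fit
  fit0$beta[fit0$assign == 3] <- 0
  w0 <- wald_type3(fit0)
  expect_equal(w0$chisq[w0$term == "morph_pct:condition"], 0)
  expect_equal(w0$p_value[w0$term == "morph_pct:condition"], 1)
})

test_that("PSE inverts the fitted psychometric function in closed form", {
  base <- list(
    family = "binomial",
    beta = c("(Intercept)" = 0, morph = 2, condition1 = 0,
             "morph:condition1" = 0),
    vcov_beta = diag(1e-4, 4),
    assign = c(0L, 1L, 2L, 3L),
    center = 50, scale = 40,
    condition_levels = c("unfamiliar_familiar", "unfamiliar_unfamiliar"),
    contrasts = matrix(c(1, -1), 2, 1,
                       dimnames = list(c("unfamiliar_familiar",
                                         "unfamiliar_unfamiliar"), NULL)))
  fit <- structure(base, class = "mixed_fit")
  expect_equal(estimate_pse(fit, "unfamiliar_familiar")$pse, 50)

  # unscaled intercept -1 with slope 0.1 per morph unit around 50:
  # on the /40 scale that is beta = (-1, 4) -> boundary at 60
  fit$beta[1:2] <- c(-1, 0.1 * 40)
  expect_equal(estimate_pse(fit, "unfamiliar_familiar")$pse, 60)

  fit$beta[2] <- 0
  expect_error(estimate_pse(fit, "unfamiliar_familiar"), "slope is zero")
})

test_that("fits are deterministic given the data", {
  sim <- sim_exp1(109, n_participants = 5)
  f1 <- fit_binomial_glmm(sim$trials)
  f2 <- fit_binomial_glmm(sim$trials)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik, f2$loglik)
})
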