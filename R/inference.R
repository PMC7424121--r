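# Mixed-model inference, implemented from first principles:
#   * binomial GLMM (logit link) fitted by maximizing the Laplace
#     approximation to the marginal likelihood; the inner step is penalized
#     iteratively reweighted least squares (PIRLS) for the joint mode of
#     the fixed and random coefficients, the outer step a quasi-Newton
#     search over log random-effect standard deviations;
#   * Gaussian linear mixed model for log reaction times, maximizing the
#     exact marginal likelihood profiled over the residual variance;
#   * term-wise Type-3 Wald chi-square tests under zero-sum contrasts;
#   * point-of-subjective-equality (categorical boundary) estimation with
#     delta-method standard errors.

#' Mixed-model specification
#'
#' Fixed effects are the scaled morph percentage (continuous), the
#' condition factor under zero-sum contrast coding, and their interaction;
#' random effects are crossed intercepts for participant and/or continuum.
#'
#' @param response `"choice"` (Identity-B indicator, binomial GLMM) or
#'   `"log_rt"` (log-transformed reaction time, Gaussian LMM).
#' @param random Character vector among `"participant"`, `"continuum"`.
#' @param scaling Morph scaling: `"zscore_over_trials"` centers at 50 and
#'   divides by the standard deviation of the morph percentage over trials
#'   (~25.8 for the balanced nine-level design); `"center50_div40"` divides
#'   by 40 so the unambiguous ends map to +/-1.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = c("choice", "log_rt"),
                       random = c("participant", "continuum"),
                       scaling = c("zscore_over_trials", "center50_div40")) {
  response <- match.arg(response)
  scaling <- match.arg(scaling)
  random <- match.arg(random, c("participant", "continuum"),
                      several.ok = TRUE)
  structure(list(response = response, random = random, scaling = scaling),
            class = "model_spec")
}

# fixed-effect design matrix with zero-sum condition contrasts
build_fixed <- function(morph_pct, condition, spec) {
  center <- 50
  scale <- switch(spec$scaling,
                  zscore_over_trials = stats::sd(morph_pct),
                  center50_div40 = 40)
  if (!is.finite(scale) || scale == 0) scale <- 40
  s <- (morph_pct - center) / scale
  cond <- factor(condition, levels = sort(unique(condition)))
  K <- nlevels(cond)
  if (K >= 2) {
    Cm <- stats::contr.sum(K)
    rownames(Cm) <- levels(cond)
    colnames(Cm) <- paste0("condition", seq_len(K - 1))
    Xc <- Cm[as.integer(cond), , drop = FALSE]
    X <- cbind("(Intercept)" = 1, morph = s, Xc,
               Xc * s)
    colnames(X)[(2 + K):(2 * K)] <- paste0("morph:condition",
                                           seq_len(K - 1))
    assign <- c(0L, 1L, rep(2L, K - 1), rep(3L, K - 1))
  } else {
    Cm <- matrix(numeric(0), 1, 0, dimnames = list(levels(cond), NULL))
    X <- cbind("(Intercept)" = 1, morph = s)
    assign <- c(0L, 1L)
  }
  list(X = X, assign = assign, center = center, scale = scale,
       condition_levels = levels(cond), contrasts = Cm)
}

# random-intercept indicator matrix; one block per grouping factor
build_random <- function(trials, random) {
  blocks <- list()
  for (term in random) {
    f <- factor(switch(term,
                       participant = trials$participant_id,
                       continuum = trials$continuum_id))
    Zk <- matrix(0, nrow(trials), nlevels(f))
    Zk[cbind(seq_len(nrow(trials)), as.integer(f))] <- 1
    colnames(Zk) <- paste0(term, ".", levels(f))
    blocks[[term]] <- Zk
  }
  Z <- do.call(cbind, blocks)
  term_of <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  list(Z = Z, term_of = term_of,
       n_groups = vapply(blocks, ncol, integer(1)))
}

new_mixed_fit <- function(...) structure(list(...), class = "mixed_fit")

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("%s mixed model (%s)\n",
              if (x$family == "binomial") "Binomial logit" else "Gaussian",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  observations: %d; log-likelihood: %.3f\n",
              x$n_obs, x$loglik))
  se <- sqrt(diag(x$vcov_beta))
  coefs <- data.frame(estimate = x$beta, std_error = se)
  print(round(coefs, 4))
  if (length(x$sigma) > 0) {
    cat("  random-intercept sd:",
        paste(sprintf("%s %.3f", names(x$sigma), x$sigma), collapse = ", "),
        "\n")
  }
  if (!is.na(x$sigma_resid)) {
    cat(sprintf("  residual sd: %.3f\n", x$sigma_resid))
  }
  invisible(x)
}

# binomial log-likelihood of aggregated counts at probabilities mu
binom_loglik <- function(succ, tot, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(lchoose(tot, succ) + succ * log(mu) + (tot - succ) * log(1 - mu))
}

# PIRLS for the joint mode of (beta, u*) where u* is the spherical random
# effect (u = sd * u*, so Zs = Z %*% diag(sd) and the penalty is the
# identity). The spherical parameterization stays well conditioned as any
# sd approaches 0. Returns the mode, the Laplace log-likelihood and the
# penalized information matrix.
pirls <- function(X, Zs, succ, tot, beta0, u0,
                  tol = 1e-10, max_iter = 100) {
  p <- ncol(X); q <- ncol(Zs)
  C <- cbind(X, Zs)
  coef <- c(beta0, u0)
  y <- succ / tot
  obj_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(C %*% coef)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    wt <- tot * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    A <- crossprod(C * sqrt(wt))
    diag(A)[(p + 1):(p + q)] <- diag(A)[(p + 1):(p + q)] + 1
    rhs <- drop(crossprod(C, wt * z))
    coef_new <- drop(solve(A, rhs))
    # step-halving on the penalized log-likelihood
    step <- 1
    repeat {
      cand <- coef + step * (coef_new - coef)
      mu_c <- stats::plogis(drop(C %*% cand))
      obj <- binom_loglik(succ, tot, mu_c) -
        0.5 * sum(cand[(p + 1):(p + q)]^2)
      if (is.finite(obj) && (obj >= obj_old - 1e-12 || step < 1e-4)) break
      step <- step / 2
    }
    coef <- cand
    if (abs(obj - obj_old) < tol * (abs(obj) + 1)) {
      converged <- TRUE
      obj_old <- obj
      break
    }
    obj_old <- obj
  }
  eta <- drop(C %*% coef)
  mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  wt <- tot * mu * (1 - mu)
  A <- crossprod(C * sqrt(wt))
  diag(A)[(p + 1):(p + q)] <- diag(A)[(p + 1):(p + q)] + 1
  H <- A[(p + 1):(p + q), (p + 1):(p + q), drop = FALSE]
  u <- coef[(p + 1):(p + q)]
  ll_cond <- binom_loglik(succ, tot, mu)
  laplace <- ll_cond - 0.5 * sum(u^2) -
    sum(log(diag(chol(H))))            # -1/2 log det(Zs'WZs + I)
  list(beta = coef[seq_len(p)], u = u, laplace = laplace, A = A,
       converged = converged, penalized_obj = obj_old)
}

#' Fit the binomial choice GLMM
#'
#' Maximizes the Laplace-approximated marginal likelihood of a logistic
#' mixed model for the Identity-B choice: fixed effects for scaled morph
#' percentage, condition (zero-sum contrasts) and their interaction;
#' crossed random intercepts per `spec$random`. Identical trials are
#' aggregated to binomial counts before fitting, which leaves the
#' likelihood unchanged. The outer optimization runs over log standard
#' deviations with convergence declared at a relative log-likelihood
#' change below 1e-8.
#'
#' @param trials A trial tibble.
#' @param spec A [model_spec()] with `response = "choice"`.
#' @return A `mixed_fit`: `beta`, `vcov_beta`, `sigma` (random-intercept
#'   sds), `loglik` (Laplace), `converged`, `separation`, `n_obs`,
#'   `n_groups`, plus the design metadata needed by [wald_type3()] and
#'   [estimate_pse()].
#' @export
fit_binomial_glmm <- function(trials, spec = model_spec("choice")) {
  stopifnot(spec$response == "choice")
  # drop random terms without at least two levels (not identifiable)
  random <- spec$random
  dropped <- character(0)
  for (term in random) {
    n_lev <- length(unique(switch(term,
                                  participant = trials$participant_id,
                                  continuum = trials$continuum_id)))
    if (n_lev < 2) dropped <- c(dropped, term)
  }
  if (length(dropped) > 0) {
    warning("random term(s) with a single level dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    random <- setdiff(random, dropped)
  }

  scale_sd <- stats::sd(trials$morph_pct)
  key <- paste(trials$participant_id, trials$continuum_id,
               trials$condition, trials$morph_pct, sep = "\r")
  succ <- tapply(trials$response == "B", key, sum)
  tot <- tapply(rep(1L, nrow(trials)), key, sum)
  first <- !duplicated(key)
  cells <- trials[first, c("participant_id", "continuum_id", "condition",
                           "morph_pct")]
  ord <- match(key[first], names(succ))
  succ <- as.numeric(succ[ord]); tot <- as.numeric(tot[ord])

  spec_use <- spec
  if (spec$scaling == "zscore_over_trials") {
    # scale from the trial-level (pre-aggregation) morph distribution
    fx <- build_fixed(cells$morph_pct, cells$condition, spec)
    fx$scale <- scale_sd
    fx$X[, "morph"] <- (cells$morph_pct - fx$center) / fx$scale
    k <- grep("^morph:condition", colnames(fx$X))
    if (length(k) > 0) {
      cc <- fx$contrasts[match(cells$condition, rownames(fx$contrasts)), ,
                         drop = FALSE]
      fx$X[, k] <- cc * fx$X[, "morph"]
    }
  } else {
    fx <- build_fixed(cells$morph_pct, cells$condition, spec)
  }
  X <- fx$X
  p <- ncol(X)

  beta_start <- stats::glm.fit(X, cbind(succ, tot - succ),
                               family = stats::binomial())$coefficients
  beta_start[!is.finite(beta_start)] <- 0

  if (length(random) == 0) {
    g <- stats::glm.fit(X, cbind(succ, tot - succ),
                        family = stats::binomial())
    mu <- g$fitted.values
    A <- crossprod(X * sqrt(tot * mu * (1 - mu)))
    fit <- new_mixed_fit(
      family = "binomial", beta = stats::setNames(g$coefficients,
                                                  colnames(X)),
      vcov_beta = solve(A), sigma = numeric(0), sigma_resid = NA_real_,
      loglik = binom_loglik(succ, tot, mu), converged = g$converged,
      separation = any(abs(g$coefficients) > 25),
      n_obs = nrow(trials), n_groups = integer(0),
      assign = fx$assign, center = fx$center, scale = fx$scale,
      condition_levels = fx$condition_levels, contrasts = fx$contrasts,
      spec = spec)
    return(fit)
  }

  rd <- build_random(cells, random)
  Z <- rd$Z
  q <- ncol(Z)
  term_idx <- match(rd$term_of, random)

  warm <- new.env(parent = emptyenv())
  warm$beta <- beta_start
  warm$u <- rep(0, q)
  laplace_at <- function(sds) {
    Zs <- Z * rep(sds[term_idx], each = nrow(Z))
    ft <- pirls(X, Zs, succ, tot, warm$beta, warm$u)
    warm$beta <- ft$beta
    warm$u <- ft$u
    ft
  }
  obj <- function(sds) -laplace_at(sds)$laplace
  opt <- stats::nlminb(rep(0.5, length(random)), obj,
                       lower = 0, upper = 1e2,
                       control = list(rel.tol = 1e-8))
  # polish: restart once from the solution
  opt <- stats::nlminb(opt$par, obj, lower = 0, upper = 1e2,
                       control = list(rel.tol = 1e-8))
  final <- laplace_at(opt$par)
  vcov_beta <- solve(final$A)[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  new_mixed_fit(
    family = "binomial",
    beta = stats::setNames(final$beta, colnames(X)),
    vcov_beta = vcov_beta,
    sigma = stats::setNames(opt$par, random),
    sigma_resid = NA_real_,
    u = stats::setNames(final$u * opt$par[term_idx], colnames(Z)),
    loglik = final$laplace,
    converged = opt$convergence == 0 && final$converged,
    separation = any(abs(final$beta) > 25),
    n_obs = nrow(trials), n_groups = rd$n_groups,
    assign = fx$assign, center = fx$center, scale = fx$scale,
    condition_levels = fx$condition_levels, contrasts = fx$contrasts,
    spec = spec)
}

#' Fit the Gaussian linear mixed model for log reaction times
#'
#' Maximizes the exact marginal likelihood (profiled over the residual
#' variance) of a random-intercept model for `log(rt_ms)`, with the same
#' fixed-effect structure as the choice model. Trials should first pass
#' through [filter_for_rt()]. A grouping factor with a single level is
#' dropped with a warning (fixed-effects-only fall-back when none remain).
#'
#' @param trials A filtered trial tibble.
#' @param spec A [model_spec()] with `response = "log_rt"`.
#' @return A `mixed_fit` with `sigma_resid` filled in.
#' @export
fit_linear_mixed <- function(trials, spec = model_spec("log_rt")) {
  stopifnot(spec$response == "log_rt")
  if (nrow(trials) == 0) stop("no trials to fit", call. = FALSE)
  y <- log(trials$rt_ms)
  fx <- build_fixed(trials$morph_pct, trials$condition, spec)
  X <- fx$X
  p <- ncol(X)
  n <- length(y)

  random <- spec$random
  dropped <- character(0)
  for (term in random) {
    n_lev <- length(unique(switch(term,
                                  participant = trials$participant_id,
                                  continuum = trials$continuum_id)))
    if (n_lev < 2) dropped <- c(dropped, term)
  }
  if (length(dropped) > 0) {
    warning("random term(s) with a single level dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    random <- setdiff(random, dropped)
  }

  if (length(random) == 0) {
    ls <- stats::lm.fit(X, y)
    rss <- sum(ls$residuals^2)
    sigma2 <- rss / n
    XtXi <- solve(crossprod(X))
    ll <- -0.5 * n * (log(2 * pi * sigma2) + 1)
    return(new_mixed_fit(
      family = "gaussian",
      beta = stats::setNames(ls$coefficients, colnames(X)),
      vcov_beta = sigma2 * XtXi, sigma = numeric(0),
      sigma_resid = sqrt(sigma2), loglik = ll, converged = TRUE,
      separation = FALSE, n_obs = n, n_groups = integer(0),
      assign = fx$assign, center = fx$center, scale = fx$scale,
      condition_levels = fx$condition_levels, contrasts = fx$contrasts,
      spec = spec))
  }

  rd <- build_random(trials, random)
  Z <- rd$Z
  q <- ncol(Z)
  term_idx <- match(rd$term_of, random)

  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- drop(crossprod(X, y)); Zty <- drop(crossprod(Z, y))
  yty <- sum(y^2)
  rhs <- c(Xty, Zty)

  # spherical parameterization: u = Lambda u*, Zs = Z Lambda, penalty I;
  # lam are relative standard deviations sd_k / sigma_resid
  solve_mme <- function(lam_par) {
    L <- lam_par[term_idx]
    A12 <- XtZ * rep(L, each = p)
    A22 <- ZtZ * outer(L, L)
    diag(A22) <- diag(A22) + 1
    A <- rbind(cbind(XtX, A12), cbind(t(A12), A22))
    rhs_s <- c(Xty, L * Zty)
    coef <- drop(solve(A, rhs_s))
    pwrss <- yty - sum(coef * rhs_s)
    logdet <- 2 * sum(log(diag(chol(A22))))
    dev <- logdet + n * log(2 * pi * pwrss / n) + n
    list(coef = coef, pwrss = pwrss, dev = dev, A = A, L = L)
  }
  opt <- stats::nlminb(rep(1, length(random)),
                       function(lp) solve_mme(lp)$dev,
                       lower = 0, upper = 1e3,
                       control = list(rel.tol = 1e-10))
  opt <- stats::nlminb(opt$par, function(lp) solve_mme(lp)$dev,
                       lower = 0, upper = 1e3,
                       control = list(rel.tol = 1e-10))
  final <- solve_mme(opt$par)
  sigma2 <- final$pwrss / n
  lam <- opt$par
  vcov_beta <- sigma2 * solve(final$A)[seq_len(p), seq_len(p),
                                       drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  new_mixed_fit(
    family = "gaussian",
    beta = stats::setNames(final$coef[seq_len(p)], colnames(X)),
    vcov_beta = vcov_beta,
    sigma = stats::setNames(lam * sqrt(sigma2), random),
    sigma_resid = sqrt(sigma2),
    u = stats::setNames(final$L * final$coef[(p + 1):(p + q)],
                        colnames(Z)),
    loglik = -0.5 * final$dev,
    converged = opt$convergence == 0,
    separation = FALSE,
    n_obs = n, n_groups = rd$n_groups,
    assign = fx$assign, center = fx$center, scale = fx$scale,
    condition_levels = fx$condition_levels, contrasts = fx$contrasts,
    spec = spec)
}

#' Type-3 Wald chi-square tests
#'
#' Tests each fixed-effect term (morph percentage, condition, interaction)
#' with a Wald chi-square on its coefficient block: `b' V^-1 b` with `V`
#' the corresponding block of the coefficient covariance, degrees of
#' freedom equal to the block size. Under zero-sum contrasts this carries
#' Type-3 (each term adjusted for all others) semantics.
#'
#' @param fit A converged `mixed_fit`.
#' @return A `wald_table` tibble: `term`, `chisq`, `df`, `p_value`.
#' @export
wald_type3 <- function(fit) {
  term_names <- c("morph_pct", "condition", "morph_pct:condition")
  rows <- lapply(1:3, function(a) {
    idx <- which(fit$assign == a)
    if (length(idx) == 0) return(NULL)
    b <- fit$beta[idx]
    V <- fit$vcov_beta[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular covariance block for term '", term_names[a], "'",
           call. = FALSE))
    chisq <- max(0, drop(t(b) %*% Vi %*% b))
    tibble::tibble(term = term_names[a], chisq = chisq,
                   df = length(idx),
                   p_value = stats::pchisq(chisq, length(idx),
                                           lower.tail = FALSE))
  })
  structure(dplyr::bind_rows(rows),
            class = c("wald_table", class(tibble::tibble())))
}

#' Point of subjective equality per condition
#'
#' Solves the fitted fixed-effect predictor for the morph percentage at
#' which P(Identity B) = 0.5 with random effects at zero, maps it back
#' through the morph scaling, and attaches a delta-method standard error.
#' With a reference condition, the boundary shift and its standard error
#' are reported as well.
#'
#' @param fit A fitted choice `mixed_fit`.
#' @param condition Condition label to evaluate.
#' @param reference Optional reference condition for the shift.
#' @return A `pse_estimate` tibble: `condition`, `pse`, `se`, and (when a
#'   reference is given) `reference`, `shift`, `shift_se`.
#' @export
estimate_pse <- function(fit, condition, reference = NULL) {
  stopifnot(fit$family == "binomial")
  grad_and_pse <- function(cond) {
    if (!cond %in% fit$condition_levels) {
      stop("condition '", cond, "' was not in the fitted data",
           call. = FALSE)
    }
    cvec <- fit$contrasts[cond, ]
    w_num <- numeric(length(fit$beta))   # numerator: intercept + condition
    w_den <- numeric(length(fit$beta))   # denominator: morph slope terms
    w_num[fit$assign == 0] <- 1
    w_num[fit$assign == 2] <- cvec
    w_den[fit$assign == 1] <- 1
    w_den[fit$assign == 3] <- cvec
    a <- sum(w_num * fit$beta)
    d <- sum(w_den * fit$beta)
    if (abs(d) < 1e-10) {
      stop("fitted morph slope is zero for condition '", cond,
           "'; the point of subjective equality is undefined",
           call. = FALSE)
    }
    pse <- fit$center - fit$scale * a / d
    grad <- -fit$scale * (w_num / d - a * w_den / d^2)
    list(pse = pse, grad = grad)
  }
  g1 <- grad_and_pse(condition)
  se <- sqrt(drop(t(g1$grad) %*% fit$vcov_beta %*% g1$grad))
  out <- tibble::tibble(condition = condition, pse = g1$pse, se = se)
  if (!is.null(reference)) {
    g0 <- grad_and_pse(reference)
    dg <- g1$grad - g0$grad
    out$reference <- reference
    out$shift <- g1$pse - g0$pse
    out$shift_se <- sqrt(drop(t(dg) %*% fit$vcov_beta %*% dg))
  }
  structure(out, class = c("pse_estimate", class(tibble::tibble())))
}
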