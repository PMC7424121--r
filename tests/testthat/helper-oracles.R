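# Independent oracles used to validate the implementation.

# Exact marginal log-likelihood of a one-condition random-intercept
# logistic model, by adaptive numerical integration over each
# participant's intercept. Trials are aggregated to binomial counts per
# (participant, morph) cell, matching the likelihood the fitter uses
# (including the binomial coefficients). `beta` = (intercept, slope on the
# scaled morph covariate); `scale`/`center` define that scaling.
quad_marginal_loglik <- function(trials, beta, sd_participant,
                                 center = 50, scale = sd(trials$morph_pct)) {
  s <- (trials$morph_pct - center) / scale
  key <- paste(trials$participant_id, trials$morph_pct)
  succ <- tapply(trials$response == "B", key, sum)
  tot <- tapply(rep(1, nrow(trials)), key, sum)
  cell <- !duplicated(key)
  pid <- trials$participant_id[cell]
  sc <- s[cell]
  ord <- match(key[cell], names(succ))
  succ <- as.numeric(succ[ord]); tot <- as.numeric(tot[ord])

  total <- sum(lchoose(tot, succ))
  for (p in unique(pid)) {
    i <- pid == p
    f <- function(u) {
      sapply(u, function(ui) {
        mu <- plogis(beta[1] + beta[2] * sc[i] + ui)
        mu <- pmin(pmax(mu, 1e-300), 1 - 1e-16)
        exp(sum(succ[i] * log(mu) + (tot[i] - succ[i]) * log(1 - mu))) *
          dnorm(ui, 0, sd_participant)
      })
    }
    total <- total + log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  total
}

# closed-form expected percent-B at morph m under the lapse-adjusted
# logistic with participant intercept sd `sd_p` (continuum sd zero),
# by numerical integration over the participant intercept
expected_percent_b <- function(m, pse, slope, lapse, sd_p) {
  if (sd_p == 0) {
    return(100 * (lapse / 2 + (1 - lapse) * plogis(slope * (m - pse))))
  }
  f <- function(u) plogis(slope * (m - pse) + u) * dnorm(u, 0, sd_p)
  100 * (lapse / 2 +
           (1 - lapse) * integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
}
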