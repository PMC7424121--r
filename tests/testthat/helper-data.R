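# Small trial-table builders used across the tests.

make_trials <- function(participant_id = "p01", continuum_id = "c1",
                        condition = "unfamiliar_familiar",
                        morph_pct = 50L, response = "A", rt_ms = 800,
                        block = 1L) {
  tibble::tibble(participant_id = participant_id,
                 continuum_id = continuum_id, condition = condition,
                 morph_pct = as.integer(morph_pct), response = response,
                 rt_ms = rt_ms, block = as.integer(block))
}

# balanced one-condition dataset: every participant sees `reps` trials at
# each morph level; responses drawn Bernoulli(p_fun(morph)) under `seed`
make_balanced_trials <- function(n_participants = 4, reps = 6,
                                 condition = "unfamiliar_familiar",
                                 p_fun = function(m) 0.5, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("p%02d", 1:n_participants),
                   morph_pct = morph_levels(), rep = seq_len(reps),
                   stringsAsFactors = FALSE)
  make_trials(participant_id = g$participant_id, continuum_id = "c1",
              condition = condition, morph_pct = g$morph_pct,
              response = ifelse(runif(nrow(g)) < p_fun(g$morph_pct),
                                "B", "A"),
              rt_ms = 500 + 100 * runif(nrow(g)), block = 1L)
}

# a response_curve built directly from values ordered by morph_levels()
make_curve <- function(values, condition = "unfamiliar_familiar",
                       symmetrized = FALSE) {
  structure(tibble::tibble(
    condition = condition, morph_pct = morph_levels(),
    mean_pct = values, ci_low = NA_real_, ci_high = NA_real_,
    n_trials = 100L
  ), symmetrized = symmetrized,
     class = c("response_curve", class(tibble::tibble())))
}
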