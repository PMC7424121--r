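# Shared design constants: morph levels and condition vocabularies of the
# two experimental designs.

#' Design morph levels
#'
#' The nine morph percentages used throughout: 10--90% Identity B in steps
#' of 10.
#'
#' @return Integer vector of the nine design morph levels.
#' @export
morph_levels <- function() seq(10L, 90L, by = 10L)

#' Condition vocabularies
#'
#' Condition labels for the two experimental designs. Experiment 1 blocks
#' morph continua between an unfamiliar and a personally familiar identity
#' against unfamiliar--unfamiliar controls. Experiment 2 intermixes five
#' conditions crossing stranger, friend and self.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @return Character vector of condition labels.
#' @export
design_conditions <- function(design = c("exp1", "exp2")) {
  design <- match.arg(design)
  switch(design,
    exp1 = c("unfamiliar_familiar", "unfamiliar_unfamiliar"),
    exp2 = c("stranger_friend", "stranger_self", "friend_self",
             "stranger_stranger", "friend_friend")
  )
}

#' Conditions with an arbitrary Identity-B designation
#'
#' In control continua both endpoints have the same familiarity status, so
#' which endpoint counts as "Identity B" is an arbitrary labelling choice;
#' response curves for these conditions are symmetrized before reporting.
#'
#' @return Character vector of control condition labels.
#' @export
control_conditions <- function() {
  c("unfamiliar_unfamiliar", "stranger_stranger", "friend_friend")
}

all_conditions <- function() {
  c(design_conditions("exp1"), design_conditions("exp2"))
}

# TRUE when the Identity-B endpoint of `condition` is the more familiar one
b_is_more_familiar <- function(condition) {
  !condition %in% control_conditions()
}
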