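#' Exclude primed words from misjudged sentences
#'
#' Removes, for each participant separately, the primed association trials
#' whose source high-ambiguity sentence that participant judged incorrectly
#' in the coherence task (two ambiguous words per sentence). Unprimed trials
#' are never removed: an unprimed word's sentence was not heard by that
#' participant.
#'
#' @param assoc_trials word-association table
#'   (see [generate_association_trials()]).
#' @param coherence_trials coherence trial table for the same participants.
#' @return list with `trials` (filtered table) and `n_excluded`.
#' @export
exclude_misjudged <- function(assoc_trials, coherence_trials) {
  need <- c("participant", "source_sentence_id", "primed")
  stopifnot(all(need %in% names(assoc_trials)))
  bad <- coherence_trials[coherence_trials$sentence_type == "high_ambiguity" &
                            !coherence_trials$correct, , drop = FALSE]
  primed <- assoc_trials[assoc_trials$primed, , drop = FALSE]
  known <- paste(coherence_trials$participant, coherence_trials$sentence_id)
  mapped <- paste(primed$participant, primed$source_sentence_id)
  if (!all(mapped %in% known)) {
    stop("primed word(s) map to no coherence sentence for that participant",
         call. = FALSE)
  }
  bad_keys <- paste(bad$participant, bad$sentence_id)
  drop <- assoc_trials$primed &
    paste(assoc_trials$participant, assoc_trials$source_sentence_id) %in% bad_keys
  list(trials = assoc_trials[!drop, , drop = FALSE], n_excluded = sum(drop))
}

#' Fit the word-meaning priming model
#'
#' Logistic mixed model of response consistency with the subordinate meaning
#' on deviation-coded Priming (primed = +1/2, unprimed = -1/2), continuous
#' Meaning Dominance (mean-centred so the priming main effect is evaluated
#' at average dominance), and their interaction, with random intercepts for
#' participants and words. Residuals are returned on the response
#' (probability) scale.
#'
#' @param assoc_trials association table after [exclude_misjudged()].
#' @param engine `"lmer"` (default) or `"glm"` fallback.
#' @param center_dominance mean-centre dominance before fitting (default
#'   TRUE).
#' @return a `condition_fit` whose coefficients include `.cond` (priming),
#'   `dominance_c` and their interaction.
#' @export
fit_priming_model <- function(assoc_trials, engine = c("lmer", "glm"),
                              center_dominance = TRUE) {
  engine <- match.arg(engine)
  need <- c("participant", "word_id", "primed", "dominance", "consistent")
  stopifnot(all(need %in% names(assoc_trials)))
  if (length(unique(assoc_trials$consistent)) < 2L) {
    stop("consistency outcome is constant; model is not identifiable",
         call. = FALSE)
  }
  assoc_trials$.resp <- as.integer(assoc_trials$consistent)
  assoc_trials$.prime_lab <- ifelse(assoc_trials$primed, "primed", "unprimed")
  assoc_trials$dominance_c <- if (center_dominance) {
    assoc_trials$dominance - mean(assoc_trials$dominance)
  } else {
    assoc_trials$dominance
  }
  extra <- if (stats::var(assoc_trials$dominance_c) > 0) {
    c("dominance_c", ".cond:dominance_c")
  } else {
    NULL  # constant dominance: reduce to the priming-only fit
  }
  fit_two_condition(assoc_trials, ".resp", ".prime_lab", "primed", "unprimed",
                    "word_id", "binomial", engine, extra_fixed = extra)
}

#' Per-participant residual priming effect
#'
#' Mean response-scale residual over a participant's primed trials minus the
#' mean over their unprimed trials: positive values mean the participant
#' showed more word-meaning priming than the group model predicts.
#'
#' @param fit a `condition_fit` from [fit_priming_model()].
#' @param participant participant id.
#' @return signed effect on the probability scale.
#' @export
priming_effect <- function(fit, participant) {
  residual_effect(fit, participant, cond_a = "primed", cond_b = "unprimed")
}

#' Residual priming effects for every participant
#'
#' @param fit a `condition_fit` from [fit_priming_model()].
#' @return data.frame with `participant` and `effect`.
#' @export
priming_effects_table <- function(fit) {
  residual_effects_table(fit, cond_a = "primed", cond_b = "unprimed")
}
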