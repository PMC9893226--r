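# Synthetic coherence-judgement and word-association trial generators.
#
# Sentence material is structural only: 40 high-ambiguity sentences
# (h01..h40, each contributing two ambiguous words), 40 matched low-ambiguity
# sentences (l01..l40) and 40 anomalous sentences (a01..a40). Participants
# alternate between two counterbalanced lists: list A hears coherent
# sentences 1-20, list B sentences 21-40; every participant hears all 40
# anomalous sentences (80 trials in total).

coherent_list <- function(participant_index) {
  if (participant_index %% 2L == 1L) 1:20 else 21:40
}

# deterministic per-item random intercepts on log10 RT, shared across cohorts
coherence_item_effects <- function(config) {
  with_seed(substream_seed(config$seed, "items"), {
    list(
      high = stats::rnorm(40, 0, config$rt_item_sd),
      low = stats::rnorm(40, 0, config$rt_item_sd),
      anom = stats::rnorm(40, 0, config$rt_item_sd),
      dominance = {
        nu <- config$dominance_mean * (1 - config$dominance_mean) /
          config$dominance_sd^2 - 1
        nu <- max(nu, 0.05)
        stats::rbeta(80, config$dominance_mean * nu,
                     (1 - config$dominance_mean) * nu)
      }
    )
  })
}

#' Generate coherence-judgement trials
#'
#' Produces 80 trials per participant: 20 high-ambiguity and 20 low-ambiguity
#' coherent sentences (from the participant's counterbalanced list) and all
#' 40 anomalous sentences. Judgement accuracy is Bernoulli with per-type
#' error rates from the config; log10 response time (seconds from sentence
#' offset) is normal with participant and item intercepts plus the
#' participant's latent ambiguity cost on high-ambiguity trials.
#'
#' With `paper_counts_fixture = TRUE` (requires exactly 18 participants) the
#' generated table is made exclusion-clean and the printed exclusion pattern
#' is injected deterministically (first eligible trials in participant order):
#' 2 anomalous + 1 low-ambiguity response more than 300 ms before sentence
#' offset, 23 incorrect coherent judgements (14 high-, 9 low-ambiguity), and
#' 3 correct coherent responses more than 4,000 ms after offset,
#' non-overlapping with the other exclusions.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config the matching [cohort_config()].
#' @param paper_counts_fixture logical; inject the printed exclusion counts.
#' @return data.frame with columns `participant`, `sentence_id`,
#'   `sentence_type` (`high_ambiguity`, `low_ambiguity`, `anomalous`),
#'   `list`, `judged_coherent`, `correct`, `rt_from_offset` (ms).
#' @export
generate_coherence_trials <- function(cohort, config,
                                      paper_counts_fixture = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (paper_counts_fixture && nrow(cohort) != 18L) {
    stop("paper_counts_fixture requires exactly 18 participants", call. = FALSE)
  }
  items <- coherence_item_effects(config)
  trials <- with_seed(substream_seed(config$seed, "coherence"), {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- cohort[i, ]
      b_p <- stats::rnorm(1, 0, config$rt_participant_sd)
      lst <- coherent_list(i)
      sid <- c(sprintf("h%02d", lst), sprintf("l%02d", lst),
               sprintf("a%02d", 1:40))
      stype <- rep(c("high_ambiguity", "low_ambiguity", "anomalous"),
                   c(20L, 20L, 40L))
      b_i <- c(items$high[lst], items$low[lst], items$anom)
      cost <- ifelse(stype == "high_ambiguity", p$latent_rt_cost, 0)
      x <- config$rt_log10_mean + b_p + b_i + cost +
        stats::rnorm(80, 0, config$rt_sd)
      p_err <- c(high_ambiguity = config$p_error_high,
                 low_ambiguity = config$p_error_low,
                 anomalous = config$p_error_anomalous)[stype]
      correct <- stats::runif(80) >= p_err
      data.frame(
        participant = p$id, sentence_id = sid, sentence_type = stype,
        list = if (i %% 2L == 1L) "A" else "B",
        judged_coherent = ifelse(stype == "anomalous", !correct, correct),
        correct = correct,
        rt_from_offset = 10^x * 1000,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  rownames(trials) <- NULL
  if (paper_counts_fixture) trials <- inject_paper_counts(trials)
  trials
}

# Deterministically rewrite an 18-participant trial table so the exclusion
# filters reproduce the printed counts exactly. Base trials are first made
# exclusion-clean (all correct, RTs inside the admissible window), then the
# printed violations are injected on the first eligible trial of each
# participant in id order.
inject_paper_counts <- function(trials) {
  trials$correct <- TRUE
  trials$judged_coherent <- trials$sentence_type != "anomalous"
  trials$rt_from_offset <- pmin(pmax(trials$rt_from_offset, 150), 3800)
  ids <- unique(trials$participant)
  touched <- rep(FALSE, nrow(trials))
  first_eligible <- function(participant, type) {
    idx <- which(trials$participant == participant &
                   trials$sentence_type == type & !touched)
    if (!length(idx)) stop("fixture injection found no eligible trial")
    idx[1L]
  }
  # 2 anomalous + 1 low-ambiguity fast responses (> 300 ms before offset)
  for (pid in ids[1:2]) {
    i <- first_eligible(pid, "anomalous")
    trials$rt_from_offset[i] <- -400
    touched[i] <- TRUE
  }
  i <- first_eligible(ids[1L], "low_ambiguity")
  trials$rt_from_offset[i] <- -350
  touched[i] <- TRUE
  # 23 incorrect coherent judgements: 14 high-, 9 low-ambiguity
  for (pid in ids[1:14]) {
    i <- first_eligible(pid, "high_ambiguity")
    trials$correct[i] <- FALSE
    trials$judged_coherent[i] <- FALSE
    touched[i] <- TRUE
  }
  for (pid in ids[1:9]) {
    i <- first_eligible(pid, "low_ambiguity")
    trials$correct[i] <- FALSE
    trials$judged_coherent[i] <- FALSE
    touched[i] <- TRUE
  }
  # 3 slow correct coherent responses (> 4,000 ms after offset)
  for (pid in ids[1:3]) {
    i <- first_eligible(pid, "low_ambiguity")
    trials$rt_from_offset[i] <- 4500
    touched[i] <- TRUE
  }
  trials
}

#' Generate word-association trials
#'
#' Each participant responds to all 80 ambiguous words (two per
#' high-ambiguity sentence); the 40 words from the participant's
#' coherence-task list are primed, the other 40 unprimed (counterbalanced
#' across participants). Consistency with the subordinate meaning is
#' Bernoulli with log-odds
#' `qlogis(baseline) + dominance_slope * (dominance - mean) +
#'  primed * latent_priming + interaction * primed * (dominance - mean)`,
#' so unprimed responses average the configured baseline rate (default 0.29).
#' Dominance norms are Beta-distributed item properties (mean 0.31, SD 0.25).
#'
#' With `paper_counts_fixture = TRUE` (requires 18 participants) the `excluded`
#' flag marks the two primed words from each of the 14 high-ambiguity
#' sentences misjudged in the matching coherence fixture (28 rows).
#'
#' @inheritParams generate_coherence_trials
#' @return data.frame with columns `participant`, `word_id`,
#'   `source_sentence_id`, `primed`, `dominance`, `consistent`, `excluded`.
#' @export
generate_association_trials <- function(cohort, config,
                                        paper_counts_fixture = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (paper_counts_fixture && nrow(cohort) != 18L) {
    stop("paper_counts_fixture requires exactly 18 participants", call. = FALSE)
  }
  items <- coherence_item_effects(config)
  dom <- items$dominance
  base <- stats::qlogis(config$baseline_subordinate_rate)
  trials <- with_seed(substream_seed(config$seed, "association"), {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- cohort[i, ]
      lst <- coherent_list(i)
      sentence_idx <- rep(1:40, each = 2L)
      primed <- sentence_idx %in% lst
      dc <- dom - config$dominance_mean
      eta <- base + config$dominance_slope * dc +
        primed * p$latent_priming +
        config$priming_dominance_interaction * primed * dc
      data.frame(
        participant = p$id,
        word_id = sprintf("w%03d", 1:80),
        source_sentence_id = sprintf("h%02d", sentence_idx),
        primed = primed,
        dominance = dom,
        consistent = as.integer(stats::runif(80) < stats::plogis(eta)),
        excluded = FALSE,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  rownames(trials) <- NULL
  if (paper_counts_fixture) {
    # mirror the coherence fixture: participants 1..14 misjudge their first
    # high-ambiguity sentence, whose two primed words are then excluded
    ids <- unique(cohort$id)
    for (i in 1:14) {
      first_sentence <- sprintf("h%02d", coherent_list(i)[1L])
      hit <- trials$participant == ids[i] &
        trials$source_sentence_id == first_sentence & trials$primed
      trials$excluded[hit] <- TRUE
    }
  }
  trials
}
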