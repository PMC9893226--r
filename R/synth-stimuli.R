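#' Build synthetic word-report stimulus sets
#'
#' Creates 40 sentence records (word counts only, no linguistic content)
#' grouped into 8 sets of 5 sentences, each set totalling exactly 45 words
#' with individual sentences 6-13 words long. Sets are designed to be
#' interchangeable so that assignment of sets to degradation levels and test
#' phases can be counterbalanced across participants.
#'
#' @param seed RNG seed for drawing word-count compositions.
#' @return data.frame with columns `set_id` (1-8), `sentence_id` (1-40),
#'   `n_words`.
#' @examples
#' sets <- build_stimulus_sets(seed = 1)
#' tapply(sets$n_words, sets$set_id, sum)  # all 45
#' @export
build_stimulus_sets <- function(seed = 1) {
  # enumerate every composition of 45 into 5 ordered parts within 6..13,
  # then draw 8 of them; rejection-free and exactly reproducible
  parts <- 6:13
  grid <- expand.grid(a = parts, b = parts, c = parts, d = parts)
  grid$e <- 45L - (grid$a + grid$b + grid$c + grid$d)
  grid <- grid[grid$e >= 6L & grid$e <= 13L, , drop = FALSE]
  comps <- as.matrix(grid)
  picks <- with_seed(seed, sample.int(nrow(comps), 8L, replace = FALSE))
  data.frame(
    set_id = rep(1:8, each = 5L),
    sentence_id = 1:40,
    n_words = as.integer(t(comps[picks, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Counterbalanced assignment of stimulus sets to conditions
#'
#' Each participant hears all 8 sets, one per cell of the 2 (phase: pre,
#' post) x 4 (degradation: clear, 16, 8, 4 channels) design. Assignment
#' follows a Latin-square rotation so that across any 8 consecutive
#' participants every set appears in every cell exactly once.
#'
#' @param n_participants number of participants.
#' @return data.frame with `participant_index`, `phase`, `channels`, `set_id`.
#' @export
assign_stimulus_sets <- function(n_participants) {
  stopifnot(n_participants >= 0)
  if (n_participants == 0) {
    return(data.frame(participant_index = integer(), phase = character(),
                      channels = integer(), set_id = integer()))
  }
  cells <- expand.grid(channels = c(32L, 16L, 8L, 4L),
                       phase = c("pre", "post"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(n_participants), function(i) {
    rot <- (i - 1L) %% 8L
    data.frame(
      participant_index = i,
      phase = cells$phase,
      channels = cells$channels,
      set_id = ((seq_len(8L) - 1L + rot) %% 8L) + 1L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Generate word-report trials for a synthetic cohort
#'
#' For every participant, phase (pre/post training) and degradation level
#' (clear, 16-, 8-, 4-channel vocoded) the assigned stimulus set contributes
#' 5 sentences. The number of words reported correctly per sentence is drawn
#' binomially with success probability given by the logistic psychometric
#' function evaluated at `x = log2(channels)` (clear speech treated as 32
#' channels) using the participant's latent threshold for that phase, the
#' configured slope, zero guess rate and the configured lapse rate.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param stimulus_sets data.frame from [build_stimulus_sets()].
#' @param config the [cohort_config()] used to build the cohort.
#' @return data.frame with one row per sentence: `participant`, `phase`,
#'   `channels`, `x` (log2 channels), `set_id`, `sentence_id`, `n_words`,
#'   `n_correct`.
#' @export
generate_word_report_trials <- function(cohort, stimulus_sets, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  ok_levels <- c(32L, 16L, 8L, 4L)
  assign <- assign_stimulus_sets(nrow(cohort))
  if (!all(assign$channels %in% ok_levels)) {
    stop("unknown degradation level", call. = FALSE)
  }
  with_seed(substream_seed(config$seed, "word_report"), {
    rows <- lapply(seq_len(nrow(assign)), function(j) {
      a <- assign[j, ]
      p_row <- cohort[a$participant_index, ]
      alpha <- if (a$phase == "pre") p_row$latent_alpha_pre else p_row$latent_alpha_post
      sents <- stimulus_sets[stimulus_sets$set_id == a$set_id, ]
      pr <- psychometric(log2(a$channels), alpha, config$psychometric_beta,
                         gamma = 0, lambda = config$lapse_rate)
      data.frame(
        participant = p_row$id,
        phase = a$phase,
        channels = a$channels,
        x = log2(a$channels),
        set_id = a$set_id,
        sentence_id = sents$sentence_id,
        n_words = sents$n_words,
        n_correct = stats::rbinom(nrow(sents), sents$n_words, pr),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
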