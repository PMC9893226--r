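# End-to-end orchestration: challenge 1 (degraded speech), challenge 2
# (semantic ambiguity) and the cross-challenge dissociation report.

# One-tailed correlations of a per-participant measure against the three
# lesion-volume columns, in the hypothesised damage-impairs direction.
correlate_lesions <- function(cohort, measures, direction) {
  merged <- merge(cohort, measures, by.x = "id", by.y = "participant")
  if (nrow(merged) < 4L) {
    stop("fewer than 4 participants with complete data; missing: ",
         paste(setdiff(cohort$id, measures$participant), collapse = ", "),
         call. = FALSE)
  }
  nets <- c(lang = "lesion_vol_lang", md = "lesion_vol_md",
            total = "lesion_vol_total")
  rows <- lapply(names(nets), function(nm) {
    res <- pearson_one_tailed(merged[[nets[[nm]]]], merged$measure, direction)
    data.frame(network = nm, r = res$r, n = res$n,
               p_one_tailed = res$p_one_tailed, direction = direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the degraded-speech challenge
#'
#' Fits the logistic psychometric function per participant and phase,
#' derives the perception measure (mean threshold number of channels across
#' the pre- and post-training tests; lower = better) and the adaptation
#' measure (pre minus post threshold location in log2 channels; positive =
#' improvement), and correlates both with lesion volume in each network.
#' Damage is hypothesised to raise thresholds (one-tailed positive) and to
#' reduce adaptation (one-tailed negative).
#'
#' @param cohort participant table with `id` and lesion-volume columns.
#' @param word_report_trials trial table
#'   (see [generate_word_report_trials()]).
#' @return list of class `challenge1_report`: `fits` (per participant and
#'   phase), `measures` (per participant: `threshold_mean_channels`,
#'   `adaptation_log2`), `correlations` (threshold and adaptation blocks).
#' @export
run_challenge1 <- function(cohort, word_report_trials) {
  fits <- fit_word_report(word_report_trials)
  ids <- unique(fits$participant)
  measures <- do.call(rbind, lapply(ids, function(pid) {
    pre <- fits[fits$participant == pid & fits$phase == "pre", ]
    post <- fits[fits$participant == pid & fits$phase == "post", ]
    if (!nrow(pre) || !nrow(post)) {
      stop("participant ", pid, " is missing a test phase", call. = FALSE)
    }
    data.frame(
      participant = pid,
      threshold_mean_channels = mean(c(pre$threshold_channels,
                                       post$threshold_channels)),
      adaptation_log2 = pre$alpha - post$alpha,
      stringsAsFactors = FALSE)
  }))
  thr <- measures[c("participant", "threshold_mean_channels")]
  names(thr)[2] <- "measure"
  adp <- measures[c("participant", "adaptation_log2")]
  names(adp)[2] <- "measure"
  structure(list(
    fits = fits,
    measures = measures,
    correlations = list(
      threshold = correlate_lesions(cohort, thr, "positive"),
      adaptation = correlate_lesions(cohort, adp, "negative")
    )
  ), class = "challenge1_report")
}

#' Run the semantic-ambiguity challenge
#'
#' Computes per-participant d-prime for each ambiguity condition, fits the
#' accuracy and log10 response-time condition models on the filtered trial
#' sets, fits the priming model after excluding primed words from misjudged
#' sentences, extracts per-participant residual ambiguity and priming
#' effects, and correlates them with lesion volumes. Damage is hypothesised
#' to enlarge the ambiguity RT cost (one-tailed positive) and to shrink
#' word-meaning priming (one-tailed negative).
#'
#' @param cohort participant table with `id` and lesion-volume columns.
#' @param coherence_trials coherence trial table.
#' @param assoc_trials word-association trial table.
#' @param engine random-effects engine for the mixed models (`"lmer"` or
#'   `"glm"`).
#' @return list of class `challenge2_report`: `dprimes`, `exclusions`
#'   (accuracy/rt/priming reports), `accuracy_fit`, `rt_fit`, `priming_fit`,
#'   `measures` (per participant: `ambiguity_rt_effect`, `priming_effect`),
#'   `correlations`.
#' @export
run_challenge2 <- function(cohort, coherence_trials, assoc_trials,
                           engine = c("lmer", "glm")) {
  engine <- match.arg(engine)
  acc <- apply_exclusions(coherence_trials, "accuracy")
  rt <- apply_exclusions(coherence_trials, "rt")
  accuracy_fit <- fit_condition_model(acc$trials, "binomial", engine)
  rt_fit <- fit_condition_model(rt$trials, "gaussian", engine)
  assoc <- exclude_misjudged(assoc_trials, coherence_trials)
  priming_fit <- fit_priming_model(assoc$trials, engine)
  amb <- residual_effects_table(rt_fit)
  prm <- priming_effects_table(priming_fit)
  measures <- merge(amb, prm, by = "participant",
                    suffixes = c("_ambiguity", "_priming"))
  names(measures) <- c("participant", "ambiguity_rt_effect", "priming_effect")
  amb_m <- amb; names(amb_m)[2] <- "measure"
  prm_m <- prm; names(prm_m)[2] <- "measure"
  structure(list(
    dprimes = dprime_by_participant(coherence_trials),
    exclusions = list(accuracy = acc$report, rt = rt$report,
                      priming_n_excluded = assoc$n_excluded,
                      priming_n_retained = nrow(assoc$trials)),
    accuracy_fit = accuracy_fit, rt_fit = rt_fit, priming_fit = priming_fit,
    measures = measures,
    correlations = list(
      ambiguity_rt = correlate_lesions(cohort, amb_m, "positive"),
      priming = correlate_lesions(cohort, prm_m, "negative")
    )
  ), class = "challenge2_report")
}

#' Cross-challenge dissociation report
#'
#' Restricts both challenge reports to the participants present in both,
#' recomputes the four lesion-behaviour correlations on that shared subset,
#' and compares dependent correlations with Meng's z: within measure across
#' networks (does MD damage predict the measure better than language
#' damage?) and within network across measures (is a network more predictive
#' of one challenge than the other?). The correlation between the two
#' lesion-volume predictors (`r12`) is computed from the data at hand.
#'
#' @param cohort participant table.
#' @param challenge1 a `challenge1_report`.
#' @param challenge2 a `challenge2_report`.
#' @return list of class `dissociation_report`: `n`, `correlations` (rows:
#'   measure x network), `comparisons` (rows of Meng z tests).
#' @export
run_dissociation <- function(cohort, challenge1, challenge2) {
  m1 <- challenge1$measures
  m2 <- challenge2$measures
  shared <- intersect(m1$participant, m2$participant)
  if (length(shared) < 4L) {
    stop("fewer than 4 participants shared between challenges", call. = FALSE)
  }
  sub <- merge(merge(cohort, m1, by.x = "id", by.y = "participant"),
               m2, by.x = "id", by.y = "participant")
  sub <- sub[sub$id %in% shared, ]
  n <- nrow(sub)
  measures <- list(
    perception = list(col = "threshold_mean_channels", dir = "positive"),
    perceptual_adaptation = list(col = "adaptation_log2", dir = "negative"),
    comprehension = list(col = "ambiguity_rt_effect", dir = "positive"),
    semantic_adaptation = list(col = "priming_effect", dir = "negative")
  )
  nets <- c(md = "lesion_vol_md", lang = "lesion_vol_lang",
            total = "lesion_vol_total")
  cor_rows <- list()
  rmat <- matrix(NA_real_, length(measures), length(nets),
                 dimnames = list(names(measures), names(nets)))
  for (mn in names(measures)) {
    for (nn in names(nets)) {
      res <- pearson_one_tailed(sub[[nets[[nn]]]], sub[[measures[[mn]]$col]],
                                measures[[mn]]$dir)
      rmat[mn, nn] <- res$r
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        measure = mn, network = nn, r = res$r, n = n,
        p_one_tailed = res$p_one_tailed, stringsAsFactors = FALSE)
    }
  }
  r12_networks <- stats::cor(sub$lesion_vol_md, sub$lesion_vol_lang)
  cmp_rows <- list()
  add_cmp <- function(label, r1, r2, r12) {
    mz <- meng_z(r1, r2, r12, n)
    cmp_rows[[length(cmp_rows) + 1L]] <<- data.frame(
      comparison = label, r1 = r1, r2 = r2, r12 = r12, z = mz$z,
      p_two_tailed = mz$p_two_tailed, stringsAsFactors = FALSE)
  }
  # across networks, within measure (shared behavioural variable)
  for (mn in names(measures)) {
    add_cmp(paste0(mn, ": md_vs_lang"), rmat[mn, "md"], rmat[mn, "lang"],
            r12_networks)
  }
  # across measures, within network (shared lesion variable)
  pairs <- utils::combn(names(measures), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r_ab <- stats::cor(sub[[measures[[a]]$col]], sub[[measures[[b]]$col]])
    for (nn in c("md", "lang")) {
      add_cmp(paste0(nn, ": ", a, "_vs_", b), rmat[a, nn], rmat[b, nn], r_ab)
    }
  }
  structure(list(
    n = n,
    participants = sort(shared),
    r12_networks = r12_networks,
    correlations = do.call(rbind, cor_rows),
    comparisons = do.call(rbind, cmp_rows),
    note = "no multiple-testing correction applied"
  ), class = "dissociation_report")
}

#' Run the full synthetic-mode pipeline
#'
#' Generates a cohort and all trial tables from a [cohort_config()], runs
#' both challenges and the dissociation report.
#'
#' @param config a [cohort_config()].
#' @param engine mixed-model engine (`"lmer"` or `"glm"`).
#' @param paper_counts_fixture inject the printed exclusion counts (requires
#'   `n_participants = 18`).
#' @return list of class `pipeline_report` with `config`, `seed`, `cohort`,
#'   `challenge1`, `challenge2`, `dissociation`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(cohort_config(n_participants = 19, seed = 1))
#' rep$challenge1$correlations$threshold
#' }
#' @export
run_pipeline <- function(config = cohort_config(),
                         engine = c("lmer", "glm"),
                         paper_counts_fixture = FALSE) {
  engine <- match.arg(engine)
  cohort <- generate_cohort(config)
  sets <- build_stimulus_sets(config$seed)
  wr <- generate_word_report_trials(cohort, sets, config)
  coh <- generate_coherence_trials(cohort, config, paper_counts_fixture)
  assoc <- generate_association_trials(cohort, config, paper_counts_fixture)
  ch1 <- run_challenge1(cohort, wr)
  ch2 <- run_challenge2(cohort, coh, assoc, engine)
  structure(list(
    config = config, seed = config$seed, cohort = cohort,
    challenge1 = ch1, challenge2 = ch2,
    dissociation = run_dissociation(cohort, ch1, ch2)
  ), class = "pipeline_report")
}
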