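#' Configuration for a synthetic lesion cohort
#'
#' Bundles every tunable parameter of the synthetic-data generators: cohort
#' size, the log-normal lesion-volume distributions in the two networks, the
#' lesion-behaviour couplings, and the latent behavioural parameters that the
#' trial generators consume. Defaults describe the world the analysis assumes:
#' a 19-participant cohort, positively skewed lesion volumes (median about
#' 8 cm^3), a baseline word-report threshold near 6 vocoder channels with a
#' pre-to-post training gain, a baseline subordinate-meaning consistency of
#' 0.29 with a priming effect of 0.352 log-odds and a dominance slope of
#' 1.112, and a semantic-ambiguity response-time cost of 0.043 log10 units.
#'
#' @param n_participants cohort size (default 19).
#' @param lesion_meanlog,lesion_sdlog log-normal parameters for per-network
#'   lesion volume in cm^3 (shared by both networks).
#' @param lesion_cor correlation between the two network lesion volumes on the
#'   log scale (not reported for real cohorts; exposed as a knob, default 0.2).
#' @param baseline_alpha population psychometric threshold, log2 channels.
#' @param training_gain pre-to-post drop in alpha, log2 channels.
#' @param coupling_md_threshold slope from MD lesion volume (cm^3) to alpha
#'   (log2 channels per cm^3); positive = damage impairs perception.
#' @param noise_sd_threshold SD of the participant-level alpha residual.
#' @param coupling_lang_priming slope from language lesion volume to the
#'   per-participant priming effect (log-odds per cm^3, subtracted so
#'   positive = damage shrinks priming).
#' @param noise_sd_priming SD of the participant-level priming residual
#'   (log-odds).
#' @param psychometric_beta slope of the generating psychometric function
#'   (per log2 channel).
#' @param lapse_rate generating lapse rate (upper-asymptote shortfall).
#' @param baseline_subordinate_rate unprimed probability of a word-association
#'   response consistent with the subordinate meaning (target 0.29).
#' @param priming_log_odds population priming effect, log-odds.
#' @param dominance_slope log-odds per unit meaning dominance.
#' @param priming_dominance_interaction interaction of priming with centred
#'   dominance, log-odds.
#' @param dominance_mean,dominance_sd moments of the Beta-distributed
#'   dominance norms (defaults 0.31 and 0.25, the printed norms).
#' @param ambiguity_rt_cost high-minus-low ambiguity response-time cost in
#'   log10 seconds (default 0.043).
#' @param ambiguity_rt_cost_sd between-participant SD of that cost.
#' @param rt_log10_mean grand mean of log10 response time in seconds
#'   (0 = one second from sentence offset).
#' @param rt_sd residual SD of log10 RT.
#' @param rt_participant_sd,rt_item_sd SDs of participant and item random
#'   intercepts on log10 RT.
#' @param p_error_high,p_error_low,p_error_anomalous generating error
#'   probabilities for coherence judgements by sentence type.
#' @param seed root RNG seed; all generators derive named substreams from it.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_participants = 5, seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_participants = 19,
                          lesion_meanlog = log(8),
                          lesion_sdlog = 0.8,
                          lesion_cor = 0.2,
                          baseline_alpha = 2.6,
                          training_gain = 0.3,
                          coupling_md_threshold = 0.02,
                          noise_sd_threshold = 0.42,
                          coupling_lang_priming = 0.02,
                          noise_sd_priming = 0.23,
                          psychometric_beta = 2,
                          lapse_rate = 0.02,
                          baseline_subordinate_rate = 0.29,
                          priming_log_odds = 0.352,
                          dominance_slope = 1.112,
                          priming_dominance_interaction = -0.300,
                          dominance_mean = 0.31,
                          dominance_sd = 0.25,
                          ambiguity_rt_cost = 0.043,
                          ambiguity_rt_cost_sd = 0.02,
                          rt_log10_mean = 0,
                          rt_sd = 0.15,
                          rt_participant_sd = 0.10,
                          rt_item_sd = 0.05,
                          p_error_high = 0.040,
                          p_error_low = 0.025,
                          p_error_anomalous = 0.010,
                          seed = 1) {
  cfg <- list(
    n_participants = n_participants,
    lesion_meanlog = lesion_meanlog, lesion_sdlog = lesion_sdlog,
    lesion_cor = lesion_cor,
    baseline_alpha = baseline_alpha, training_gain = training_gain,
    coupling_md_threshold = coupling_md_threshold,
    noise_sd_threshold = noise_sd_threshold,
    coupling_lang_priming = coupling_lang_priming,
    noise_sd_priming = noise_sd_priming,
    psychometric_beta = psychometric_beta, lapse_rate = lapse_rate,
    baseline_subordinate_rate = baseline_subordinate_rate,
    priming_log_odds = priming_log_odds,
    dominance_slope = dominance_slope,
    priming_dominance_interaction = priming_dominance_interaction,
    dominance_mean = dominance_mean, dominance_sd = dominance_sd,
    ambiguity_rt_cost = ambiguity_rt_cost,
    ambiguity_rt_cost_sd = ambiguity_rt_cost_sd,
    rt_log10_mean = rt_log10_mean, rt_sd = rt_sd,
    rt_participant_sd = rt_participant_sd, rt_item_sd = rt_item_sd,
    p_error_high = p_error_high, p_error_low = p_error_low,
    p_error_anomalous = p_error_anomalous,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (nm in names(cfg)) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || !is.finite(cfg[[nm]])) {
      stop("cohort_config field '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (cfg$n_participants < 0 || cfg$n_participants != round(cfg$n_participants)) {
    stop("n_participants must be a nonnegative integer", call. = FALSE)
  }
  probs <- c("baseline_subordinate_rate", "lapse_rate",
             "p_error_high", "p_error_low", "p_error_anomalous")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) {
      stop("cohort_config field '", nm, "' must lie in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$baseline_subordinate_rate <= 0) {
    stop("baseline_subordinate_rate must lie in (0, 1)", call. = FALSE)
  }
  sds <- c("lesion_sdlog", "noise_sd_threshold", "noise_sd_priming",
           "rt_sd", "rt_participant_sd", "rt_item_sd", "dominance_sd",
           "ambiguity_rt_cost_sd")
  for (nm in sds) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be nonnegative", call. = FALSE)
  }
  if (abs(cfg$lesion_cor) > 1) stop("lesion_cor must lie in [-1, 1]", call. = FALSE)
  if (cfg$psychometric_beta <= 0) stop("psychometric_beta must be > 0", call. = FALSE)
  if (cfg$dominance_mean <= 0 || cfg$dominance_mean >= 1) {
    stop("dominance_mean must lie in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_participants, "participants, seed", x$seed, "\n")
  cat("  lesion volumes: logN(", round(x$lesion_meanlog, 3), ",",
      x$lesion_sdlog, "), between-network cor", x$lesion_cor, "\n")
  cat("  couplings: MD->threshold", x$coupling_md_threshold,
      "| language->priming", x$coupling_lang_priming, "\n")
  invisible(x)
}
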