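#' Generate a synthetic lesion cohort
#'
#' Draws per-participant lesion volumes in the language and multiple demand
#' (MD) networks from a correlated log-normal distribution, then derives the
#' latent behavioural parameters that the trial generators consume:
#'
#' * `latent_alpha_pre  = baseline_alpha + coupling_md_threshold * lesion_vol_md + e`,
#'   `e ~ N(0, noise_sd_threshold)` — the pre-training psychometric threshold
#'   in log2 channels (larger MD damage, higher threshold, worse perception);
#' * `latent_alpha_post = latent_alpha_pre - training_gain` — thresholds drop
#'   by the configured training gain;
#' * `latent_priming = priming_log_odds - coupling_lang_priming * lesion_vol_lang + u`,
#'   `u ~ N(0, noise_sd_priming)` — the per-participant word-meaning priming
#'   effect in log-odds (larger language damage, smaller priming).
#'
#' Group labels (`LANG`, `MD`, `OTHER`) mimic recruitment labels: `OTHER` when
#' both network volumes are small, otherwise the network with the larger
#' volume. They are descriptive only; all analyses treat volume as graded.
#'
#' @param config a [cohort_config()].
#' @return a data.frame with one row per participant: `id`, `group`,
#'   `lesion_vol_lang`, `lesion_vol_md`, `lesion_vol_total` (cm^3),
#'   `latent_alpha_pre`, `latent_alpha_post` (log2 channels),
#'   `latent_priming` (log-odds), `latent_rt_cost` (log10 s).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 6, seed = 7))
#' cor(cohort$lesion_vol_md, cohort$latent_alpha_pre)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(config$n_participants)
  if (n == 0L) {
    return(data.frame(
      id = character(), group = character(),
      lesion_vol_lang = numeric(), lesion_vol_md = numeric(),
      lesion_vol_total = numeric(),
      latent_alpha_pre = numeric(), latent_alpha_post = numeric(),
      latent_priming = numeric(), latent_rt_cost = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  with_seed(substream_seed(config$seed, "cohort"), {
    # correlated bivariate normal on the log scale
    z1 <- stats::rnorm(n)
    z2 <- config$lesion_cor * z1 +
      sqrt(1 - config$lesion_cor^2) * stats::rnorm(n)
    vol_lang <- exp(config$lesion_meanlog + config$lesion_sdlog * z1)
    vol_md <- exp(config$lesion_meanlog + config$lesion_sdlog * z2)
    # a lesion can spill outside both networks; total gets extra volume
    vol_extra <- exp(config$lesion_meanlog - 1 +
                       config$lesion_sdlog * stats::rnorm(n))
    alpha_pre <- config$baseline_alpha +
      config$coupling_md_threshold * vol_md +
      stats::rnorm(n, 0, config$noise_sd_threshold)
    priming <- config$priming_log_odds -
      config$coupling_lang_priming * vol_lang +
      stats::rnorm(n, 0, config$noise_sd_priming)
    rt_cost <- stats::rnorm(n, config$ambiguity_rt_cost,
                            config$ambiguity_rt_cost_sd)
    grp <- ifelse(pmax(vol_lang, vol_md) < 3, "OTHER",
                  ifelse(vol_lang >= vol_md, "LANG", "MD"))
    data.frame(
      id = sprintf("p%02d", seq_len(n)),
      group = grp,
      lesion_vol_lang = vol_lang,
      lesion_vol_md = vol_md,
      lesion_vol_total = vol_lang + vol_md + vol_extra,
      latent_alpha_pre = alpha_pre,
      latent_alpha_post = alpha_pre - config$training_gain,
      latent_priming = priming,
      latent_rt_cost = rt_cost,
      stringsAsFactors = FALSE
    )
  })
}
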