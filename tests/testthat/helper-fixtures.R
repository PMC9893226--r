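# Shared fixtures: small deterministic cohorts and trial tables built in code.

small_config <- function(n = 6, seed = 42, ...) {
  cohort_config(n_participants = n, seed = seed, ...)
}

fixture_18 <- function(seed = 42, ...) {
  cfg <- cohort_config(n_participants = 18, seed = seed, ...)
  cohort <- generate_cohort(cfg)
  list(
    config = cfg,
    cohort = cohort,
    coherence = generate_coherence_trials(cohort, cfg,
                                          paper_counts_fixture = TRUE),
    association = generate_association_trials(cohort, cfg,
                                              paper_counts_fixture = TRUE)
  )
}

# population SD of a log-normal lesion-volume distribution
lognormal_sd <- function(meanlog, sdlog) {
  sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
}

# closed-form population correlation implied by a linear coupling
# y = slope * v + e with v ~ logN(meanlog, sdlog), e ~ N(0, noise_sd)
coupling_population_r <- function(slope, meanlog, sdlog, noise_sd) {
  s <- slope * lognormal_sd(meanlog, sdlog)
  s / sqrt(s^2 + noise_sd^2)
}

# brute-force LCS by enumeration of all subsequences of the target
brute_force_lcs <- function(target, response) {
  n <- length(target)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- target[idx]
    # is sub a subsequence of response?
    j <- 1L
    ok <- TRUE
    for (tok in sub) {
      while (j <= length(response) && response[j] != tok) j <- j + 1L
      if (j > length(response)) { ok <- FALSE; break }
      j <- j + 1L
    }
    if (ok) best <- max(best, length(sub))
  }
  best
}
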