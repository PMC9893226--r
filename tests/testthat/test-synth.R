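test_that("cohort generation validates config and handles edge cases", {
  expect_error(cohort_config(n_participants = -1), "nonnegative")
  expect_error(cohort_config(baseline_alpha = NaN), "finite")
  expect_error(cohort_config(baseline_subordinate_rate = 1.2), "\\[0, 1\\)")

  empty <- generate_cohort(cohort_config(n_participants = 0))
  expect_equal(nrow(empty), 0L)

  flat <- generate_cohort(small_config(n = 8, coupling_md_threshold = 0,
                                       noise_sd_threshold = 0))
  expect_true(all(flat$latent_alpha_pre == flat$latent_alpha_pre[1]))
  expect_equal(flat$latent_alpha_pre[1], 2.6)
  expect_true(all(flat$lesion_vol_lang >= 0 & flat$lesion_vol_md >= 0 &
                    flat$lesion_vol_total >= 0))
})

test_that("generators are byte-identical under identical config and seed", {
  cfg <- small_config(n = 5, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cohort <- generate_cohort(cfg)
  sets <- build_stimulus_sets(cfg$seed)
  expect_identical(generate_word_report_trials(cohort, sets, cfg),
                   generate_word_report_trials(cohort, sets, cfg))
  expect_identical(generate_coherence_trials(cohort, cfg),
                   generate_coherence_trials(cohort, cfg))
  expect_identical(generate_association_trials(cohort, cfg),
                   generate_association_trials(cohort, cfg))
  expect_identical(generate_toy_audio(0.2, 16000, seed = 3),
                   generate_toy_audio(0.2, 16000, seed = 3))
})

test_that("cohort coupling matches the closed-form correlation oracle", {
  cfg <- cohort_config(n_participants = 200, seed = 11)
  cohort <- generate_cohort(cfg)
  r_oracle <- coupling_population_r(cfg$coupling_md_threshold,
                                    cfg$lesion_meanlog, cfg$lesion_sdlog,
                                    cfg$noise_sd_threshold)
  r_sample <- cor(cohort$lesion_vol_md, cohort$latent_alpha_pre)
  expect_lt(abs(r_sample - r_oracle), 0.1)
  # language coupling is subtractive: negative correlation with priming
  expect_lt(cor(cohort$lesion_vol_lang, cohort$latent_priming), 0)
})

test_that("stimulus sets total 45 words each and counterbalance evenly", {
  sets <- build_stimulus_sets(seed = 1)
  expect_equal(nrow(sets), 40L)
  expect_equal(as.vector(tapply(sets$n_words, sets$set_id, sum)), rep(45, 8))
  expect_true(all(sets$n_words >= 6 & sets$n_words <= 13))
  expect_equal(length(unique(sets$set_id)), 8L)

  assign <- assign_stimulus_sets(16)
  tab <- table(assign$set_id, paste(assign$phase, assign$channels))
  expect_true(all(tab == 2))  # each set twice in each cell over 16 people
})

test_that("word-report trials follow the design arithmetic", {
  cfg <- cohort_config(n_participants = 19, seed = 5)
  cohort <- generate_cohort(cfg)
  wr <- generate_word_report_trials(cohort, build_stimulus_sets(5), cfg)
  expect_equal(nrow(wr), 19 * 2 * 4 * 5)
  expect_true(all(wr$n_correct >= 0 & wr$n_correct <= wr$n_words))
  expect_setequal(unique(wr$channels), c(32, 16, 8, 4))

  # asymptote: lambda = 0 and very low alpha puts clear speech near 1
  p <- psychometric(log2(32), alpha = -5, beta = 2, lambda = 0)
  expect_gt(p, 0.999)

  expect_error(generate_word_report_trials(cohort[0, ],
                                           build_stimulus_sets(5), cfg),
               "empty")
})

test_that("coherence trials: counts, null effect, and fixture injections", {
  fx <- fixture_18()
  expect_equal(nrow(fx$coherence), 1440L)

  flagged_fast <- sum(fx$coherence$rt_from_offset < -300)
  flagged_slow <- sum(fx$coherence$rt_from_offset > 4000)
  flagged_incorrect <- sum(!fx$coherence$correct)
  expect_equal(flagged_fast, 3L)
  expect_equal(flagged_slow, 3L)
  expect_equal(flagged_incorrect, 23L)
  by_type <- table(fx$coherence$sentence_type[!fx$coherence$correct])
  expect_equal(unname(by_type[["high_ambiguity"]]), 14L)
  expect_equal(unname(by_type[["low_ambiguity"]]), 9L)

  expect_error(generate_coherence_trials(generate_cohort(small_config(n = 5)),
                                         small_config(n = 5),
                                         paper_counts_fixture = TRUE),
               "18 participants")

  # null ambiguity cost: group mean log-RT difference ~ 0
  cfg0 <- cohort_config(n_participants = 40, seed = 8,
                        ambiguity_rt_cost = 0, ambiguity_rt_cost_sd = 0)
  ct0 <- generate_coherence_trials(generate_cohort(cfg0), cfg0)
  lrt <- log10(ct0$rt_from_offset / 1000)
  d <- mean(lrt[ct0$sentence_type == "high_ambiguity"]) -
    mean(lrt[ct0$sentence_type == "low_ambiguity"])
  mc <- sqrt(2) * sd(lrt) / sqrt(40 * 20)
  expect_lt(abs(d), 4 * mc)
})

test_that("association trials: counterbalancing, null effect, recovery", {
  fx <- fixture_18()
  expect_equal(sum(fx$association$excluded), 28L)
  counts <- table(fx$association$participant, fx$association$primed)
  expect_true(all(counts == 40))
  # counterbalancing: each word primed for half of an even cohort
  primed_per_word <- tapply(fx$association$primed, fx$association$word_id, sum)
  expect_true(all(primed_per_word == 9))

  cfg0 <- cohort_config(n_participants = 60, seed = 13,
                        priming_log_odds = 0, coupling_lang_priming = 0,
                        noise_sd_priming = 0)
  at0 <- generate_association_trials(generate_cohort(cfg0), cfg0)
  diff <- mean(at0$consistent[at0$primed]) - mean(at0$consistent[!at0$primed])
  expect_lt(abs(diff), 4 * sqrt(2 * 0.25 / (60 * 40)))

  # positive dominance slope is recovered by logistic regression
  cfg <- cohort_config(n_participants = 60, seed = 14)
  at <- generate_association_trials(generate_cohort(cfg), cfg)
  co <- coef(glm(consistent ~ primed + dominance, binomial(), at))
  expect_gt(co[["dominance"]], 0)
})

test_that("toy audio validates inputs and has high-frequency energy", {
  expect_error(generate_toy_audio(0, 16000), "> 0")
  expect_error(generate_toy_audio(1, 8000), "16000")
  x <- generate_toy_audio(0.5, 16000, seed = 4)
  expect_equal(length(x), 8000L)
  # FFT oracle: integrated spectral power above 2 kHz is substantial
  pw <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * 16000 / length(x)
  hi <- sum(pw[freqs > 2000 & freqs < 8000])
  expect_gt(hi / sum(pw), 0.05)
})

test_that("toy volumes share a grid and spheres match the volume formula", {
  vols <- generate_toy_volumes(c(30L, 30L, 30L), c(1, 1, 1), seed = 2,
                               n_participants = 4)
  expect_s3_class(vols$prob_map_lang, "volume_grid")
  expect_true(all(vapply(vols$lesion_masks, function(m)
    identical(dim(m$data), c(30L, 30L, 30L)), logical(1))))

  # sphere voxel-count enumeration oracle: within 5% of 4/3 pi r^3
  ax <- seq_len(41) - 21
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  for (r in c(6, 9)) {
    count <- sum(d2 <= r^2)
    expect_lt(abs(count - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
  }

  # identity: lesion equal to the thresholded map overlaps completely
  net <- threshold_map(vols$prob_map_md, 0.05)
  ov <- lesion_overlap(net, net)
  expect_equal(ov$overlap_volume, ov$network_volume)
  # all-zero lesion gives zero overlap
  zero <- volume_grid(array(0, dim(net$data)), net$voxel_dims, net$affine,
                      kind = "binary")
  expect_equal(lesion_overlap(zero, net)$overlap_volume, 0)
})
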