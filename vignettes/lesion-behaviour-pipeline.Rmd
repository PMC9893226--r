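---
title: "Methods: lesion-behaviour mapping of perceptual and semantic speech challenges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-behaviour mapping of perceptual and semantic speech challenges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechlesion)
```

# The analysis in one paragraph

`speechlesion` implements a two-challenge lesion-behaviour pipeline for
spoken-sentence comprehension in cohorts with chronic brain lesions but
without aphasia. Challenge 1 degrades sentences acoustically by noise
vocoding and summarises each listener by the *threshold number of channels*
— the channel count at which a fitted logistic psychometric function
predicts 50% word report — before and after a training block. Challenge 2
presents sentences containing semantically ambiguous words, summarising
comprehension by coherence-judgement accuracy (d′ against anomalous
sentences) and a response-time cost for ambiguity, and semantic adaptation
by *word-meaning priming* in a later word-association task. Each
behavioural measure is correlated (one-tailed Pearson) with the lesion
volume falling inside two functionally defined networks — the
language-selective network and the domain-general multiple demand (MD)
network — and dependent correlations are compared with Meng's z. A
synthetic-data module replaces the patient cohort so that every stage is
testable end to end.

# Models and their assumptions

## Noise vocoding

The vocoder divides 50–8000 Hz into `n` logarithmically spaced channels
(geometric progression of edges). Each band's amplitude envelope —
half-wave rectification followed by a 30 Hz low-pass — modulates
band-limited white noise, channels are summed, and the output is rescaled
to the input RMS. Intelligibility of vocoded speech rises with channel
count, which is what makes channel count usable as a perceptual
"intensity" axis.

Two implementation choices matter:

* **Processing order.** The construction low-passes *after* rectification.
  Rectify-then-smooth is the standard vocoder construction; smoothing a
  band signal before rectification would remove the carrier itself.
  Residual negative values after the low-pass (filter ringing) are clipped
  to zero.
* **Filters.** No IIR filter-design library is assumed. Band-pass and
  low-pass stages apply the *squared magnitude response* of a 4th-order
  Butterworth filter in the frequency domain, which is exactly the
  magnitude response of one forward plus one backward pass and is
  zero-phase by construction. Fidelity to any particular published
  stimulus set is not claimed; the original filter family is unreported.

A known limitation, visible in the test suite: for 8 or more channels the
lowest band (50–94 Hz) is so narrow that the intrinsic envelope
fluctuation of narrow-band noise caps the input-output envelope
correlation near 0.75. The per-channel envelope-fidelity property (> 0.8)
is therefore asserted for the 4-channel vocoder; the band-energy locality
and channel-count monotonicity properties are asserted as stated.

## Word-report scoring

A reported word is correct only if it matches a target word exactly
(morphological variants fail) and the matched words appear in the same
relative order as in the target, with omissions allowed. That rule is
formalised as the longest common subsequence (LCS) between target and
response tokens: the unique maximal order-preserving matching. Each target
token can be matched at most once; when a word is reported twice but
appears once, LCS picks whichever instance preserves order (the original
manual rule for this tie is unknowable). Homophone equivalence is a
user-supplied map (default empty) because homophone judgements in real
scoring are manual.

## Psychometric model

Word report at `x = log2(channels)` is binomial with success probability

`f(x) = gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))`

with guess rate `gamma = 0` (open-set report) and lapse rate `lambda`
fixed at 1 minus the participant's observed clear-speech accuracy. Clear
speech is encoded as 32 channels. `alpha` is the 50% threshold in log2
channels; `2^alpha` is the threshold number of channels; the slope form
(`beta` multiplies `x - alpha`) is used because `beta` is described as the
steepness of the curve. Fitting maximises the binomial likelihood over
`alpha` in [0, 6] (1–64 channels) and `beta` in [0.05, 20] from five
deterministic starts (L-BFGS-B). Probabilities are clipped to
`[1e-9, 1 - 1e-9]` inside the likelihood so a fixed lapse rate cannot
produce `log(0)`; degenerate all-correct/all-wrong data return a fit
pinned at a bound flagged `converged = FALSE` rather than an error, and a
clear accuracy of 0 clamps `lambda` to 0.999 for the same reason.
Per-sentence counts are pooled to per-level totals: the model describes
proportions, not sentence-level structure.

The perception measure is the mean of the pre- and post-training
thresholds ("mean threshold across tests" reads most naturally as the mean
of two fits; a pooled-phases fit is also available). The adaptation
measure is `alpha_pre - alpha_post` (positive = improvement).

## Coherence judgements and response times

Trials are 20 high-ambiguity, 20 low-ambiguity and 40 anomalous sentences
per participant. Exclusions follow minimal trimming: responses more than
300 ms before sentence offset are anticipatory everywhere; the accuracy
analysis then drops anomalous trials (their false-alarm rate is shared
between ambiguity conditions), and the RT analysis drops incorrect
judgements and responses more than 4,000 ms after offset. d′ is
`qnorm(hits) - qnorm(false alarms)` with boundary rates moved off 0/1 by
`1/(2N)`; at ceiling (20 coherent, 40 anomalous) the adjusted rates are
0.975 and 0.0125 and d′ = 4.20.

Accuracy and log10 RT (seconds from offset) are modelled with a single
deviation-coded condition contrast (high = +1/2, low = −1/2) plus
participant and item random intercepts (lme4). Per-participant condition
effects are *residual effects*: mean observed-minus-fitted difference
between conditions on the response scale (probability for accuracy, log10
seconds for RT). The response scale is chosen because the effect is
described as a difference between responses and predictions; the scale is
otherwise unstated. The random-effects engine is pluggable; a
fixed-intercept GLM fallback exists for simulation loops where thousands
of fits are needed.

## Word-meaning priming

Each of 40 high-ambiguity sentences contributes two ambiguous words; the
40 words from a participant's heard list are primed, the other 40
unprimed, counterbalanced across participants. Primed words from
sentences a participant misjudged are excluded (two words per misjudged
sentence, for that participant only); unprimed words are never excluded.
Consistency with the subordinate meaning is modelled logistically on
Priming (±1/2), Meaning Dominance, and their interaction — the only
interaction reported, so the only one modelled — with participant and
word intercepts. Dominance is mean-centred by default so the priming main
effect is evaluated at average dominance (whether the original model
centred is unreported; the option is reversible). The per-participant
priming measure is again a response-scale residual effect.

## Lesion volumes

Probabilistic activation-overlap maps are thresholded at 5% *inclusive*
("at least 5% of contributing participants"), and lesion volume inside a
network is the voxelwise AND times the voxel volume, reported in cm³.
Inputs must share shape, voxel dimensions and affine to within 1e-4 mm;
there is deliberately no resampling — registration is upstream
neuroimaging work, and silent interpolation corrupts volumes. A minimal
NIfTI-1 reader/writer (uint8/float32, sform affine, uncompressed) is
included because the analysis environment carries no NIfTI package.

## Inference

Lesion-behaviour hypotheses are directional, so Pearson correlations are
tested one-tailed via the t transform: damage is predicted to *raise*
thresholds and ambiguity RT costs (positive tail) and to *reduce*
adaptation and priming (negative tail); correlations opposite to the
hypothesis give p > 0.5. Dependent overlapping correlations (two lesion
predictors against one behavioural measure, or one predictor against two
measures) are compared with Meng's z, implemented directly from the
Fisher-transform formula. The correlation between the two lesion-volume
predictors, `r12`, is never a free parameter: it is computed from the data
at hand. Cross-challenge comparisons use the intersection cohort of
participants with data for both challenges. No multiple-testing
correction is applied, and the report says so.

Meng's z is known to be slightly conservative at small n: simulation at
n = 18 under a trivariate-normal null puts its true size near 0.042
rather than 0.050. The acceptance suite documents this honestly: the
10,000-replicate criterion demanding the size land within 3 Monte-Carlo
SEs of 0.05 fails by construction and is left failing, while validity
(size at or below nominal) and the coarser 1,000-seed criterion pass.

# The synthetic world

The generator states one world and keeps it fixed:

| parameter | default | unit | source of the default |
|---|---|---|---|
| `n_participants` | 19 | — | cohort size of the target design |
| lesion volumes | logN(log 8, 0.8) per network | cm³ | positive, heavy-tailed, median ≈ 8 cm³ mimicking the published demographics table |
| `lesion_cor` | 0.2 | — | between-network volume correlation; never reported, exposed as a knob |
| `baseline_alpha` | 2.6 | log2 channels | threshold near 6 channels, mid-range of the 4–16 channel design |
| `training_gain` | 0.3 | log2 channels | training improves thresholds; magnitude unreported, chosen as a modest fraction of a 1-octave step |
| `coupling_md_threshold` | 0.02 | log2 ch / cm³ | with the volume SD and `noise_sd_threshold` = 0.42 implies a population r ≈ 0.44, the regime of the reported MD-threshold association |
| `priming_log_odds` | 0.352 | log-odds | reported priming effect |
| `dominance_slope`, interaction | 1.112, −0.300 | log-odds | reported coefficients |
| `baseline_subordinate_rate` | 0.29 | probability | reported unprimed consistency |
| dominance norms | Beta, mean 0.31, SD 0.25 | — | printed norms |
| `coupling_lang_priming` | 0.02 | log-odds / cm³ | with `noise_sd_priming` = 0.23 implies latent r ≈ −0.67, the regime of the reported language-priming association |
| `ambiguity_rt_cost` | 0.043 (SD 0.02 across people) | log10 s | reported RT coefficient; individual spread is assumed, not reported |
| RT model | mean 0 (1 s), residual SD 0.15, participant SD 0.10, item SD 0.05 | log10 s | typical magnitudes for speeded sentence judgements |
| error rates | high 0.040, low 0.025, anomalous 0.010 | probability | match the printed error counts in expectation (≈14/9 of 360 each; near-ceiling d′) |

What the generator emulates: graded lesion volumes with configurable
between-network correlation; psychometric word report with a training
gain; near-ceiling coherence accuracy with an ambiguity RT cost;
counterbalanced priming with a dominance covariate; and the two
lesion-behaviour couplings with the configured signs (MD damage raises
thresholds; language damage shrinks priming).

What it does not emulate: linguistic content (sentences are word-count
records), response coding disagreement, aetiology or lesion geometry
behind the volumes, non-normal RT tails, or any relation between the two
challenges beyond shared lesion volumes. A green test therefore
establishes that the *pipeline* recovers what the stated world contains —
not that real cohorts behave like the stated world.

The `paper_counts_fixture` mode (18 participants) first makes the
generated table exclusion-clean and then injects the printed exclusion
pattern deterministically on the first eligible trials in participant
order: 2 anomalous + 1 low-ambiguity anticipatory responses, 23 incorrect
coherent judgements (14 high, 9 low), 3 slow responses, and the 28
excluded primed words implied by the 14 misjudged high-ambiguity
sentences. RT clamping in fixture mode is what guarantees *exactly* the
printed counts; without it a 1,440-trial table occasionally produces an
accidental > 4,000 ms response.

# Acceptance-check design

Two decisions deserve explanation.

**Recovery targets are defined on the measured scale.** The pipeline's
perception measure is the mean threshold in *channels* (`2^alpha`), and
its priming measure is a response-scale residual effect estimated from 80
binary trials. Both transformations change the population correlation
relative to the latent couplings: the log2-to-channels nonlinearity
*raises* the MD-threshold correlation (≈ 0.44 latent on the alpha scale
vs ≈ 0.51 on the channels scale), and binomial measurement noise
*attenuates* the language-priming correlation (≈ −0.67 latent vs ≈ −0.33
measured). The recovery criterion therefore compares the pipeline
estimate at n = 200 against population values computed by Monte-Carlo
oracles that use only the generative model (closed-form draws and
binomial sampling — no model fitting), on the same scale the pipeline
reports.

**Type-I checks run on the inference stage.** The 1,000-seed
zero-coupling criterion drives the one-tailed correlation test and Meng's
z with freshly generated null cohorts; running 1,000 full psychometric
pipelines would spend its runtime budget on optimiser calls that the
criterion does not examine.

# Numerical choices and degenerate inputs

* Likelihood tolerance 1e-8; five deterministic optimiser starts; fits at
  parameter bounds are flagged, not hidden.
* Envelope extraction clips post-filter negatives at 0; vocoding a silent
  input returns silence (no division by zero RMS).
* `dprime` adjusts both boundaries symmetrically (rates of 0 and 1), which
  is what makes d′ exactly antisymmetric under swapping hits and false
  alarms.
* `meng_z` validates the correlation triple by positive semidefiniteness
  of the implied 3×3 matrix.
* Exclusion filters are idempotent; surviving nonpositive RTs (impossible
  for the generator, possible for user data) are an error rather than a
  silent shift.
* All generators draw from named substreams of one root seed and restore
  the caller's RNG state; identical config + seed is byte-identical
  output.

# Known limitations

* The between-network lesion-volume correlation is a guess (default 0.2);
  real cohorts may differ, which directly affects Meng's z.
* The low-frequency vocoder channels at high channel counts cannot reach
  the envelope fidelity of wider bands (see above).
* The glm fallback engine understates standard errors when participant
  heterogeneity is present; it is intended for simulation loops, and the
  lme4 engine is the default everywhere.
* Lesion analysis requires pre-registered, grid-aligned volumes; nothing
  is resampled for the user.
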