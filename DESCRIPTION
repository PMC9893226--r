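Package: speechlesion
Title: Lesion-Behaviour Analysis of Perceptual and Semantic Challenges to Speech Comprehension
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for lesion-behaviour mapping of two
    challenges to spoken-sentence comprehension. Challenge one degrades speech
    acoustically by noise vocoding and measures perception and adaptation via
    logistic psychometric thresholds over vocoder channel counts; challenge two
    measures comprehension of semantically ambiguous sentences (coherence
    judgements, d-prime with boundary corrections, response-time costs) and
    subsequent word-meaning priming in a word association task. Behavioural
    effects are related to lesion volumes inside two functionally defined brain
    networks (language-selective and domain-general multiple demand) by
    one-tailed Pearson correlations, and dependent correlations are compared
    with Meng's z. A synthetic-data module generates cohorts, trial tables, toy
    audio and toy imaging volumes with the statistical structure the analysis
    assumes, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
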