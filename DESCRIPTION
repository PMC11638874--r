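Package: evadint
Title: Composite Behavioral Scoring of Acute Drug-Induced Neurotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the EvADINT (Evaluation of Acute Drug-Induced
    NeuroToxicity) composite behavioral score for mice observed over 24 h
    after intracerebral compound administration: a weighted rubric over
    seizure and hyperactivity severity plus interval-censored recovery
    latencies for four motor milestones, with a fixed override score for
    death. Provides rubric configuration and validation, CSV ingestion of
    per-checkpoint observation sheets, blinded scoring, group comparison by
    one-way ANOVA with Tukey HSD, a weight-perturbation rank-stability
    analysis, and a seeded synthetic cohort simulator for end-to-end
    testing without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
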