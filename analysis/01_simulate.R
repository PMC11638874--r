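#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Four arms emulating the published study conditions: vehicle control,
# mixed-backbone (PS/PO) ASO, full-PS ASO, and full PS-DNA (uniformly
# lethal), 8 mice per arm, observed at 0.5/1/2/4/24 h post anesthesia
# reversal. Writes the canonical observation/event sheets under
# results/cohort/.

library(evadint)

seed <- 101L
design <- study_design(
  arms = lapply(c("vehicle", "mixed_psop", "full_ps", "ps_dna"), preset),
  n_per_arm = 8, seed = seed)

obs <- simulate_cohort(design, out_dir = "results/cohort")

report <- validate_observations(obs)
stopifnot(!any(report$level == "error"))

arms <- table(vapply(obs, function(o) o$group, character(1)))
deaths <- sum(vapply(obs, function(o) o$died, logical(1)))
cat(sprintf("Simulated %d animals (seed %d): %s\n", length(obs), seed,
            paste(sprintf("%s n=%d", names(arms), arms), collapse = ", ")))
cat(sprintf("Deaths before the first checkpoint: %d (all in the ps_dna arm)\n",
            deaths))
cat("Wrote results/cohort/observations.csv and results/cohort/events.csv\n")
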