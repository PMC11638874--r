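#!/usr/bin/env Rscript
# Step 2 — blinded scoring.
#
# Reads the observation sheets written by 01_simulate.R, blinds animal ids
# and arm labels, scores every animal under the default rubric, unblinds,
# and writes per-animal scores (results/scores.tsv) and per-arm summaries
# (results/summary.tsv).

library(evadint)

obs <- read_observations("results/cohort/observations.csv",
                         "results/cohort/events.csv")

bl <- assign_blinding(obs, seed = 202L)
blinded_scores <- score_cohort(bl$blinded)$scores

groups <- stats::setNames(vapply(obs, function(o) o$group, character(1)),
                          vapply(obs, function(o) o$animal_id, character(1)))
scores <- unblind(blinded_scores, bl$map, groups)
scores <- scores[order(scores$group, scores$animal_id), ]

cohort <- score_cohort(obs)  # unblinded cross-check
stopifnot(identical(sort(scores$total), sort(cohort$scores$total)))

write_scores(structure(list(scores = scores, rubric = default_rubric(),
                            provenance = list(input = "results/cohort")),
                       class = "cohort_scores"),
             "results/scores.tsv")
summary <- summarize_cohort(scores)
utils::write.table(summary, "results/summary.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat("Per-arm EvADINT totals (mean ± SEM):\n")
for (i in seq_len(nrow(summary)))
  cat(sprintf("  %-12s %5.1f ± %4.1f  (n=%d, deaths=%d, range %g-%g)\n",
              summary$group[i], summary$mean[i], summary$sem[i],
              summary$n[i], summary$deaths[i], summary$min[i],
              summary$max[i]))
flagged <- sum(scores$exceeds_death_flag)
cat(sprintf("Surviving totals above the death score: %d\n", flagged))
cat("Wrote results/scores.tsv and results/summary.tsv\n")
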