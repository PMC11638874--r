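#!/usr/bin/env Rscript
# Step 3 — group comparison.
#
# One-way ANOVA on EvADINT totals across arms, with the Tukey HSD post hoc
# table; writes results/anova.tsv and results/tukey.tsv.

library(evadint)

scores <- utils::read.delim("results/scores.tsv")

a <- withCallingHandlers(
  anova_oneway(scores),
  warning = function(w) {
    message("note: ", conditionMessage(w)); invokeRestart("muffleWarning")
  })
cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
            a$df_between, a$df_within, a$F, a$p))

tukey <- suppressWarnings(tukey_hsd(scores))
cat("Tukey HSD pairwise comparisons:\n")
for (i in seq_len(nrow(tukey)))
  cat(sprintf("  %-12s vs %-12s diff %6.1f  q %6.2f  p_adj %.3g\n",
              tukey$group_a[i], tukey$group_b[i], tukey$mean_diff[i],
              tukey$q[i], tukey$p_adj[i]))

utils::write.table(
  data.frame(F = a$F, df_between = a$df_between, df_within = a$df_within,
             p = a$p, grand_mean = a$grand_mean),
  "results/anova.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(tukey, "results/tukey.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("Wrote results/anova.tsv and results/tukey.tsv\n")
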