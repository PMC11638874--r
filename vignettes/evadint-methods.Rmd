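---
title: "EvADINT: model, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EvADINT: model, design choices, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evadint)
```

## The score

EvADINT (Evaluation of Acute Drug-Induced NeuroToxicity) quantifies the
transient motor phenotypes mice show in the first 24 h after a compound —
typically an antisense oligonucleotide (ASO) — is injected into the CNS.
The phenotypes range from hypoactivity (loss of sternal posture, ataxia,
absent grooming) through hyperactivity and seizures to death, are usually
worst in the first 1–3 h, and resolve by 24 h in survivors.

A blinded observer records, at checkpoints 0.5, 1, 2, 4 and 24 h after
anesthesia reversal (t = 0), whether the animal is alive and whether it has
regained four motor milestones, plus any seizure or hyperactivity episodes
(duration in minutes and an intensity grade). The composite score is then

* **death override** — an animal that dies within the window scores a fixed
  75 points, regardless of anything recorded before death;
* otherwise the exact integer sum of six components: seizure severity
  points (0/10/15/20 for none/mild/moderate/severe), hyperactivity severity
  points (0/5/10/15), and one latency row per milestone, read at the
  checkpoint from which the milestone was durably regained —
  sternal posture 0/4/8/12/20, unstimulated movement 0/3/6/9/15, movement
  without ataxia 0/2/4/6/10, grooming/eating/nesting 0/1/2/3/5 for
  0.5/1/2/4/"24 h or never".

The weights encode relative severity: righting is a prerequisite for every
other behavior and simpler than coordinated movement, so its row is the
heaviest latency row; seizures and death outweigh all latencies. The final
column deliberately conflates recovery at 24 h with no recovery — by the
last checkpoint the acute episode is over either way.

```{r}
default_rubric()
```

### Event severity

An episode's severity is the maximum of a duration band and an intensity
grade ("and/or" in the rubric's footnotes): < 10 min is mild, 10–30 min
moderate, > 30 min severe; `high_or_constant` intensity forces severe,
`moderate` forces at least moderate. Boundary durations (exactly 10 or
30 min) fall to the moderate band, because the printed bands are "<10" and
">30". Multiple episodes of one category aggregate by maximum, not sum: the
rubric allots one severity cell per category, and "short and infrequent
bursts" are already folded into the mild definition. Seizure and
hyperactivity are scored independently and additively; nothing in the
rubric makes them exclusive, and we do not attempt to decide whether one
episode "caused" the other. The three-level intensity vocabulary is our
operationalization of qualitative field descriptions ("constant or
high-intensity contractions", "slight hopping"); it is an input convention,
not a measurement instrument.

### Recovery latencies

Milestone recovery is interval-censored at the checkpoints: a mouse that
rights itself at 1 h 40 min is scored at the 2 h column (8 points for
posture — the canonical worked example). Scoring uses a
*sustained-recovery* rule: the earliest checkpoint from which the flag is
true at that and every later checkpoint. Relapses (recovered at 1 h, lost
at 2 h) are not defined by the rubric — it scores *maintenance* of each
behavior — so validation emits a warning and scoring uses the start of the
final sustained run.

### Uncapped surviving totals

The six row maxima sum to 85, which exceeds the death score of 75. We sum
without capping — the published rule is "death scores 75; otherwise the sum
of all other scores" — and raise `exceeds_death_flag` on any surviving
total above the death score, leaving the interpretation to the analyst.
The exhaustive enumeration test confirms 85 is the attainable surviving
maximum.

## Group comparison

Arms are compared by one-way ANOVA on the totals with a Tukey HSD post hoc
table (Tukey–Kramer q for unequal n), the standard analysis for this kind
of figure. Scores are treated as continuous despite the integer rubric.
When an arm is all-tied — typically a uniformly lethal arm at 75 — the
ANOVA still runs (as it does in the field) but a warning notes the strained
assumptions. Tail probabilities of the studentized range come from
`ptukey`; the k = 2 identity q = √2·|t| is verified in the tests to 1e-6.
Summaries report both SD and SEM, since figure conventions alternate
between the two.

## Weight-perturbation rank stability

The claim the analysis supports is *empirical*: arm toxicity rankings
survive re-weighting of the rubric. Neither the number nor the magnitude of
re-weightings is published, so the defaults here are ours and are labeled
in every report: 1000 perturbations, each multiplying the six category rows
by independent factors drawn log-uniformly from [1/2, 2] (log-uniform so
up- and down-weighting are symmetric), with the death score tied to the
seizure factor — death is listed with seizures in the rubric and shares its
row. A `per_cell` scope (jitter every cell, re-sort within rows to keep
monotonicity) is available for finer-grained sensitivity.

Concordance between the baseline and perturbed rankings of arm mean totals
is Kendall tau-b (tie-corrected); means rather than medians because the
figures this mirrors compare means. Two numerical details: a perturbed
death score that falls below a perturbed row maximum is raised to that
maximum so every perturbed rubric satisfies the rubric invariants; and
tau values within 1e-9 of 1 count as perfect concordance, since the
pair-counting arithmetic can land at 1 − ε.

For arms whose score distributions are strictly ordered under *every*
admissible weighting — a clean control near 0 versus a lethal arm at the
death score — perfect concordance is guaranteed, and the acceptance suite
checks exactly that configuration. For overlapping intermediate arms
(mixed-backbone vs full-PS), concordance is high but not perfect at factor
2; the analysis reports the fraction rather than asserting it.

## The synthetic cohort generator

No per-animal trajectories are published, so the generator is calibrated to
the qualitative phenomenology and the two printed anchors: vehicle totals
never exceed 4, and lethal-arm animals all score 75. Each arm is a
phenomenological preset:

* `vehicle` (θ = 0): no deaths, no events; posture and unstimulated
  movement always recovered before 0.5 h, the other milestones by 1 h,
  bounding the total at 0+0+0+0+2+1 = 3 ≤ 4.
* `mixed_psop` (θ = 0.35): occasional mild/moderate events, recovery over
  1–4 h.
* `full_ps` (θ = 0.7): frequent mild/moderate events, recovery over 2–24 h.
* `ps_dna` (θ = 1): severe seizures and certain death before the first
  checkpoint ("within minutes" of reversal).

Milestone recovery times are a log-normal base (sternal posture) plus three
gamma-distributed non-negative increments, so the hierarchy posture ≤
unstimulated movement ≤ no-ataxia ≤ grooming holds in every animal by
construction — the same ordering rationale as the weights. Log-normal/gamma
were chosen for positive support and a heavy right tail; the parameter
values are package constants, not published estimates. Where an anchor must
hold *surely* rather than with high probability (the vehicle ceiling),
draws are truncated below per-milestone caps by inverse-CDF sampling.
Event durations are drawn inside the sampled severity band (mild U(1,10)
min, moderate U(10,30), severe 30 + Exp(mean 15)), recorded to 0.1 min and
clamped inside the band so the recorded duration classifies back to the
sampled severity; intensities match the band.

Randomness is hierarchical: each animal's draws come from a substream keyed
by (design seed, arm index, animal index), so adding or removing an arm
does not change any other arm's animals, and every CSV the generator writes
is byte-identical across reruns of the same design.

What the generator does **not** emulate: dose–response, pharmacokinetics,
mechanism (protein binding, divalent-ion chelation), inter-observer
disagreement, relapses, deaths after the first checkpoint (configurable but
not used by presets), or correlations between event severity and recovery
latency beyond what the shared arm preset induces. Passing tests therefore
show that the *pipeline* is correct and that the scoring behaves as
specified on data with the assumed structure — not that the presets are
faithful to any real cohort.

## Problem sizes and tolerances

The test suite and acceptance checks use sizes chosen to make the
properties sharp at desk scale: exhaustive scoring enumeration over all
4×4×5⁴ = 10,000 severity/checkpoint combinations against an independent
table-lookup oracle; 100 seeded vehicle cohorts of n = 8 for the ceiling
anchor; 200 seeded four-arm cohorts of n = 8 for the stochastic-ordering
and rank-recovery properties (ranking recovered in ≥ 95% of seeds); 1000
weight perturbations at factor 2 for the stability claim. Integer component
sums are asserted exactly; ANOVA decompositions to 1e-9; studentized-range
identities to 1e-6.

## Known limitations

Observations are checkpoint-resolved only — continuous observation between
checkpoints is out of scope. The intensity grades are an input convention.
The rubric ships with one schedule shared by all four latency rows (the
table has a single header row); per-row schedules are not supported. The
robustness defaults are package choices; conclusions about weight
sensitivity should cite the factor range and count actually used, which
every report records.
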