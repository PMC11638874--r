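# Fixture builders and independent oracles, all constructed in code.

SCHEDULE <- c(0.5, 1, 2, 4, 24)
MILESTONES <- c("sternal_posture", "unstimulated_movement",
                "movement_without_ataxia", "grooming_eating_nesting")

# One event row; severity shortcut draws a canonical (duration, intensity)
# inside the band.
make_event <- function(category, duration_min, intensity,
                       descriptor = "fixture") {
  data.frame(category = category, duration_min = duration_min,
             intensity = intensity, descriptor = descriptor,
             stringsAsFactors = FALSE)
}

canonical_event <- function(category, severity) {
  switch(severity,
         mild = make_event(category, 5, "low"),
         moderate = make_event(category, 20, "moderate"),
         severe = make_event(category, 40, "high_or_constant"))
}

# Build an observation from four recovery times (hours; Inf = never) and an
# optional event table; died = TRUE makes a first-checkpoint death.
make_obs <- function(id = "m1", group = "g", recovery = rep(0.5, 4),
                     events = empty_events(), died = FALSE,
                     schedule = SCHEDULE) {
  ck <- data.frame(time_h = schedule, alive = !died)
  for (i in seq_along(MILESTONES))
    ck[[MILESTONES[i]]] <- if (died) NA else schedule >= recovery[i]
  mouse_observation(id, group, ck, events, died = died,
                    death_time_h = if (died) schedule[1] else NULL)
}

# --- Independent oracles -------------------------------------------------

# Direct table lookup + summation over the printed rubric; shares no code
# with the scoring engine.
ORACLE_EVENT_POINTS <- list(
  seizure = c(none = 0, mild = 10, moderate = 15, severe = 20),
  hyperactivity = c(none = 0, mild = 5, moderate = 10, severe = 15))
ORACLE_LATENCY_POINTS <- list(
  sternal_posture = c(0, 4, 8, 12, 20),
  unstimulated_movement = c(0, 3, 6, 9, 15),
  movement_without_ataxia = c(0, 2, 4, 6, 10),
  grooming_eating_nesting = c(0, 1, 2, 3, 5))

oracle_total <- function(seizure_sev, hyper_sev, recovery) {
  col <- function(t) if (is.infinite(t)) 5L else match(t, SCHEDULE)
  ORACLE_EVENT_POINTS$seizure[[seizure_sev]] +
    ORACLE_EVENT_POINTS$hyperactivity[[hyper_sev]] +
    sum(vapply(seq_along(MILESTONES), function(i)
      ORACLE_LATENCY_POINTS[[MILESTONES[i]]][col(recovery[i])], numeric(1)))
}

# Kendall tau-b by explicit concordant/discordant pair counting.
kendall_oracle <- function(a, b) {
  n <- length(a)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  ta <- sum(sapply(table(a), function(t) t * (t - 1) / 2))
  tb <- sum(sapply(table(b), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - ta) * (n0 - tb))
}

four_preset_design <- function(seed, n_per_arm = 8) {
  study_design(lapply(c("vehicle", "mixed_psop", "full_ps", "ps_dna"),
                      preset),
               n_per_arm = n_per_arm, seed = seed)
}
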