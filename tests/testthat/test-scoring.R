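test_that("event severity honors duration bands and the and/or intensity clause", {
  expect_equal(classify_event_severity(35, "moderate"), "severe")
  expect_equal(classify_event_severity(5, "low"), "mild")
  expect_equal(classify_event_severity(15, "high_or_constant"), "severe")
  expect_equal(classify_event_severity(15, "moderate"), "moderate")
  # boundaries fall to the moderate band: mild is <10 min, severe >30 min
  expect_equal(classify_event_severity(10, "low"), "moderate")
  expect_equal(classify_event_severity(30, "low"), "moderate")
  expect_equal(classify_event_severity(30.1, "low"), "severe")
  expect_equal(classify_event_severity(0, "low"), "mild")
})

test_that("events in one category aggregate by maximum severity", {
  expect_equal(overall_event_severity(empty_events(), "seizure"), "none")
  two <- rbind(canonical_event("seizure", "mild"),
               canonical_event("seizure", "moderate"))
  expect_equal(overall_event_severity(two, "seizure"), "moderate")
  mixed <- rbind(canonical_event("seizure", "severe"),
                 canonical_event("seizure", "mild"),
                 canonical_event("hyperactivity", "moderate"))
  expect_equal(overall_event_severity(mixed, "seizure"), "severe")
  expect_equal(overall_event_severity(mixed, "hyperactivity"), "moderate")
})

test_that("recovery uses the sustained-recovery rule", {
  worked <- make_obs(recovery = c(2, 0.5, 0.5, 0.5))
  expect_equal(recovery_checkpoint(worked, "sternal_posture"), 2)
  expect_equal(recovery_checkpoint(make_obs(), "grooming_eating_nesting"), 0.5)
  expect_equal(recovery_checkpoint(make_obs(recovery = c(0.5, 0.5, 0.5, Inf)),
                                   "grooming_eating_nesting"), Inf)
  # transient recovery followed by relapse does not count
  rel <- make_obs()
  rel$checkpoints$unstimulated_movement <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(recovery_checkpoint(rel, "unstimulated_movement"), 4)
})

test_that("latency points read the rubric column, with no-recovery at the end", {
  r <- default_rubric()
  expect_equal(latency_points(2, r$latency$sternal_posture, r$checkpoints), 8)
  for (row in r$latency)
    expect_equal(latency_points(0.5, row, r$checkpoints), 0)
  expect_equal(latency_points(Inf, r$latency$sternal_posture, r$checkpoints), 20)
  expect_equal(latency_points(24, r$latency$sternal_posture, r$checkpoints), 20)
  expect_error(latency_points(3, r$latency$sternal_posture, r$checkpoints),
               "schedule")
})

test_that("per-animal totals match the published scoring rules", {
  r <- default_rubric()
  # death override, regardless of recorded phenotypes
  expect_equal(score_mouse(make_obs(died = TRUE), r)$total, 75)
  # a phenotype-free survivor scores zero
  zero <- score_mouse(make_obs(), r)
  expect_equal(zero$total, 0)
  expect_false(zero$exceeds_death_flag)
  # the worked example: posture regained between 1 and 2 h scores 8
  worked <- score_mouse(make_obs(recovery = c(2, 0.5, 0.5, 0.5)), r)
  expect_equal(worked$sternal_posture, 8)
  expect_equal(worked$total, 8)
  # worst surviving phenotype: every row maximum, flagged above death score
  worst <- score_mouse(make_obs(
    recovery = rep(Inf, 4),
    events = rbind(canonical_event("seizure", "severe"),
                   canonical_event("hyperactivity", "severe"))), r)
  expect_equal(worst$total, 85)
  expect_true(worst$exceeds_death_flag)
})

test_that("a hand-scored four-animal cohort reproduces manual sums", {
  # components written out per the printed table:
  #   a: seizure moderate 15 + posture@1h 4 + unstim@2h 6 + ataxia@4h 6 +
  #      grooming never 5                                          = 36
  #   b: hyperactivity mild 5 + all milestones by 0.5 h            = 5
  #   c: no events, posture@2h 8, unstim@2h 6, ataxia@24h 10,
  #      grooming@24h 5                                            = 29
  #   d: died                                                      = 75
  obs <- list(
    make_obs("a", "g1", recovery = c(1, 2, 4, Inf),
             events = canonical_event("seizure", "moderate")),
    make_obs("b", "g1", recovery = rep(0.5, 4),
             events = canonical_event("hyperactivity", "mild")),
    make_obs("c", "g2", recovery = c(2, 2, 24, 24)),
    make_obs("d", "g2", died = TRUE))
  sc <- score_cohort(obs)$scores
  expect_equal(sc$total, c(36, 5, 29, 75))
  expect_equal(sc$died, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("totals agree with brute-force table lookup over the full grid", {
  # exhaustive over all severity pairs x a milestone checkpoint sub-grid
  r <- default_rubric()
  recopts <- c(0.5, 2, Inf)
  sev <- c("none", "mild", "moderate", "severe")
  for (ss in sev) for (sh in sev) {
    ev <- empty_events()
    if (ss != "none") ev <- rbind(ev, canonical_event("seizure", ss))
    if (sh != "none") ev <- rbind(ev, canonical_event("hyperactivity", sh))
    for (r1 in recopts) for (r4 in recopts) {
      rec <- c(r1, r1, r4, r4)
      got <- score_mouse(make_obs(recovery = rec, events = ev), r)$total
      expect_equal(got, oracle_total(ss, sh, rec))
    }
  }
})

test_that("scores are monotone in recovery delay and event severity", {
  r <- default_rubric()
  sev <- c("none", "mild", "moderate", "severe")
  set.seed(31)
  for (rep_i in 1:25) {
    rec <- sample(c(SCHEDULE, Inf), 4, replace = TRUE)
    ss <- sample(sev, 1)
    ev <- if (ss == "none") empty_events() else canonical_event("seizure", ss)
    base <- score_mouse(make_obs(recovery = rec, events = ev), r)$total
    # delay one milestone to the next checkpoint
    i <- sample(4, 1)
    opts <- c(SCHEDULE, Inf)
    pos <- match(rec[i], opts)
    if (pos < length(opts)) {
      rec2 <- rec; rec2[i] <- opts[pos + 1]
      expect_gte(score_mouse(make_obs(recovery = rec2, events = ev), r)$total,
                 base)
    }
    # raise the seizure severity one level
    spos <- match(ss, sev)
    if (spos < 4) {
      ev2 <- canonical_event("seizure", sev[spos + 1])
      expect_gte(score_mouse(make_obs(recovery = rec, events = ev2), r)$total,
                 base)
    }
  }
})

test_that("surviving totals are exact integer component sums", {
  obs <- simulate_cohort(four_preset_design(seed = 6))
  sc <- score_cohort(obs)$scores
  surv <- sc[!sc$died, ]
  comp <- as.matrix(surv[, c("seizure", "hyperactivity", MILESTONES)])
  expect_identical(surv$total, unname(rowSums(comp)))
  expect_true(all(sc$total[sc$died] == 75))
})

test_that("cohort scoring is permutation-invariant and blind-safe", {
  obs <- simulate_cohort(four_preset_design(seed = 12, n_per_arm = 4))
  sc <- score_cohort(obs)$scores
  perm <- sample(seq_along(obs))
  sc_perm <- score_cohort(obs[perm])$scores
  expect_equal(sc_perm[order(sc_perm$animal_id), ],
               sc[order(sc$animal_id), ], ignore_attr = TRUE)

  bl <- assign_blinding(obs, seed = 3)
  sc_blind <- score_cohort(bl$blinded)$scores
  groups <- stats::setNames(vapply(obs, function(o) o$group, character(1)),
                            vapply(obs, function(o) o$animal_id, character(1)))
  restored <- unblind(sc_blind, bl$map, groups)
  expect_equal(restored[order(restored$animal_id), ],
               sc[order(sc$animal_id), ], ignore_attr = TRUE)
})

test_that("scoring refuses cohorts with blocking validation errors", {
  bad <- make_obs()
  bad$checkpoints$time_h[3] <- 3
  expect_error(score_cohort(list(bad)), "validation")
  expect_error(score_cohort(list(make_obs("x"), make_obs("x"))), "duplicate")
})
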