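# Scoring engine: per-animal component scores and totals under a rubric.
#
# A dead animal receives the rubric's fixed death score in place of a
# component sum; a surviving animal's total is the exact integer sum of the
# six components (two event severities, four recovery latencies). Surviving
# totals are never capped at the death score; exceeding it raises a flag.

#' Classify the severity of one motor event
#'
#' Severity is the maximum of a duration-based class (< 10 min mild,
#' 10-30 min moderate, > 30 min severe; the bands are shared by seizure and
#' hyperactivity) and an intensity-based class (`high_or_constant` is
#' severe, `moderate` is moderate, `low` at most mild), matching the
#' rubric's "and/or" footnotes. Boundary durations fall to the moderate
#' band: exactly 10 and exactly 30 min are moderate.
#'
#' @param duration_min Event duration in minutes.
#' @param intensity One of `low`, `moderate`, `high_or_constant`.
#' @return One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
classify_event_severity <- function(duration_min, intensity) {
  stopifnot(is.finite(duration_min), duration_min >= 0,
            intensity %in% INTENSITY_LEVELS)
  by_duration <- if (duration_min > 30) 4L else if (duration_min >= 10) 3L else 2L
  by_intensity <- switch(intensity, low = 2L, moderate = 3L,
                         high_or_constant = 4L)
  SEVERITY_LEVELS[max(by_duration, by_intensity)]
}

#' Overall event severity for one category
#'
#' Multiple events in a category aggregate by maximum severity, not by sum:
#' the rubric allots a single severity cell per category.
#'
#' @param events Event data frame (see [mouse_observation()]).
#' @param category `"seizure"` or `"hyperactivity"`.
#' @return A severity level; `"none"` when the animal has no such events.
#' @export
overall_event_severity <- function(events, category) {
  ev <- events[events$category == category, , drop = FALSE]
  if (!nrow(ev)) return("none")
  sev <- mapply(classify_event_severity, ev$duration_min, ev$intensity)
  SEVERITY_LEVELS[max(match(sev, SEVERITY_LEVELS))]
}

#' Checkpoint at which a behavior was durably regained
#'
#' Applies the sustained-recovery rule: the earliest scheduled checkpoint
#' from which the milestone flag is true at that and every later observed
#' checkpoint. A transient recovery followed by relapse does not count
#' (the rubric scores *maintenance* of each behavior).
#'
#' @param obs A `mouse_observation`.
#' @param behavior A latency category name.
#' @return The checkpoint time in hours, or `Inf` for "no recovery".
#' @export
recovery_checkpoint <- function(obs, behavior) {
  ck <- obs$checkpoints[obs$checkpoints$alive, , drop = FALSE]
  f <- ck[[behavior]]
  if (!length(f) || !any(f)) return(Inf)
  # last run of TRUEs reaching the end of observation
  last_false <- if (any(!f)) max(which(!f)) else 0L
  if (last_false == length(f)) return(Inf)
  ck$time_h[last_false + 1L]
}

#' Points for a recovery latency
#'
#' Looks up the rubric row column for the checkpoint at which the behavior
#' was regained; `Inf` ("no recovery") maps to the final column, which the
#' rubric shares with recovery at the last checkpoint.
#'
#' @param checkpoint_h Checkpoint time in hours, or `Inf` for no recovery.
#' @param weights A latency row: named points vector from a rubric.
#' @param checkpoints The rubric's checkpoint schedule.
#' @return Points (numeric scalar).
#' @export
latency_points <- function(checkpoint_h, weights, checkpoints) {
  if (is.infinite(checkpoint_h)) return(unname(weights[[length(weights)]]))
  i <- match(checkpoint_h, checkpoints)
  if (is.na(i))
    stop(sprintf("checkpoint %g h is not in the rubric schedule",
                 checkpoint_h), call. = FALSE)
  unname(weights[[i]])
}

# Rubric-independent scoring features of one animal: event severities,
# recovery checkpoints, survival. Everything score_features() needs, so the
# robustness analysis can re-score under many rubrics without re-deriving.
extract_score_features <- function(obs) {
  ck <- obs$checkpoints
  live <- ck$alive
  times <- ck$time_h[live]
  recovery <- vapply(LATENCY_CATEGORIES, function(b) {
    f <- ck[[b]][live]
    if (!length(f) || !any(f)) return(Inf)
    last_false <- if (any(!f)) max(which(!f)) else 0L
    if (last_false == length(f)) Inf else times[last_false + 1L]
  }, numeric(1))
  list(
    animal_id = obs$animal_id,
    group = obs$group,
    died = obs$died,
    severity = stats::setNames(
      vapply(EVENT_CATEGORIES, function(cat)
        overall_event_severity(obs$events, cat), character(1)),
      EVENT_CATEGORIES),
    recovery = recovery
  )
}

score_features <- function(feat, r) {
  if (feat$died) {
    comp <- stats::setNames(rep(NA_real_, 6),
                            c(EVENT_CATEGORIES, LATENCY_CATEGORIES))
    total <- r$death_score
    flag <- FALSE
  } else {
    ev <- c(r$events$seizure[[feat$severity[["seizure"]]]],
            r$events$hyperactivity[[feat$severity[["hyperactivity"]]]])
    lat <- vapply(LATENCY_CATEGORIES, function(b)
      latency_points(feat$recovery[[b]], r$latency[[b]], r$checkpoints),
      numeric(1))
    comp <- stats::setNames(c(ev, lat), c(EVENT_CATEGORIES, LATENCY_CATEGORIES))
    total <- sum(comp)
    flag <- total > r$death_score
  }
  out <- c(list(animal_id = feat$animal_id, group = feat$group),
           as.list(comp),
           list(total = total, died = feat$died, exceeds_death_flag = flag))
  structure(out, class = "data.frame", row.names = 1L)
}

#' Score one animal
#'
#' Computes the six EvADINT components and the total. Death within the
#' observation window overrides everything: the total is the rubric's death
#' score and components are not applicable. Otherwise the total is the sum
#' of the seizure and hyperactivity severity points and the four recovery
#' latency points; a surviving total above the death score is flagged
#' rather than capped.
#'
#' @param obs A `mouse_observation` (assumed free of validation errors; see
#'   [validate_observations()]).
#' @param r An `evadint_rubric`.
#' @return One-row data frame: `animal_id`, `group`, the six component
#'   columns, `total`, `died`, `exceeds_death_flag`.
#' @export
#' @examples
#' obs <- mouse_observation("m1", "vehicle", data.frame(
#'   time_h = c(0.5, 1, 2, 4, 24), alive = TRUE,
#'   sternal_posture = c(FALSE, FALSE, TRUE, TRUE, TRUE),
#'   unstimulated_movement = TRUE, movement_without_ataxia = TRUE,
#'   grooming_eating_nesting = TRUE))
#' score_mouse(obs, default_rubric())$sternal_posture  # 8
score_mouse <- function(obs, r = default_rubric()) {
  score_features(extract_score_features(obs), r)
}

#' Score a cohort
#'
#' Validates, then maps [score_mouse()] over every animal. Validation
#' errors abort; warnings (e.g. relapses) are emitted as R warnings and
#' scoring proceeds under the sustained-recovery rule. The result is
#' independent of animal order up to row order.
#'
#' @param obs List of `mouse_observation` with unique ids.
#' @param r An `evadint_rubric`.
#' @param provenance Optional list recorded alongside the scores (input
#'   path, seed, ...).
#' @return A `cohort_scores` object: list with `scores` (data frame, one
#'   row per animal), `rubric`, `provenance`.
#' @export
score_cohort <- function(obs, r = default_rubric(), provenance = list()) {
  ids <- vapply(obs, function(o) o$animal_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate animal ids in cohort", call. = FALSE)
  rep <- validate_observations(obs, r)
  if (any(rep$level == "error"))
    stop("observations failed validation:\n  - ",
         paste(sprintf("%s: %s", rep$animal_id[rep$level == "error"],
                       rep$message[rep$level == "error"]), collapse = "\n  - "),
         call. = FALSE)
  for (i in which(rep$level == "warning"))
    warning(sprintf("%s: %s", rep$animal_id[i], rep$message[i]),
            call. = FALSE)
  scores <- do.call(rbind, lapply(obs, score_mouse, r = r))
  rownames(scores) <- NULL
  structure(list(scores = scores, rubric = r, provenance = provenance),
            class = "cohort_scores")
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("<cohort_scores> %d animals in %d groups; death score %g\n",
              nrow(x$scores), length(unique(x$scores$group)),
              x$rubric$death_score))
  print(x$scores, ...)
  invisible(x)
}

#' Write cohort scores as TSV
#'
#' @param cohort A `cohort_scores`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(cohort, path) {
  utils::write.table(cohort$scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
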