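# Observation data model, CSV ingestion/writing, validation, blinding.
#
# Canonical files:
#   observations.csv: animal_id, group, time_h, alive, sternal_posture,
#     unstimulated_movement, movement_without_ataxia, grooming_eating_nesting
#   events.csv: animal_id, category, duration_min, intensity, descriptor
# t = 0 is anesthesia reversal; all times are hours post-reversal.

OBS_COLUMNS <- c("animal_id", "group", "time_h", "alive", LATENCY_CATEGORIES)
EVENT_COLUMNS <- c("animal_id", "category", "duration_min", "intensity",
                   "descriptor")
INTENSITY_LEVELS <- c("low", "moderate", "high_or_constant")

#' Construct a single-animal observation record
#'
#' @param animal_id Animal identifier (unique within a cohort).
#' @param group Treatment arm label.
#' @param checkpoints Data frame with columns `time_h`, `alive`, and one
#'   logical column per recovery milestone (see [default_rubric()] category
#'   names). Milestone flags at dead checkpoints are ignored.
#' @param events Data frame of motor events with columns `category`
#'   (`seizure`/`hyperactivity`), `duration_min`, `intensity`
#'   (`low`/`moderate`/`high_or_constant`), `descriptor`; may be empty.
#' @param died Logical; defaults to whether any checkpoint has `alive = FALSE`.
#' @param death_time_h Hours post-reversal; defaults to the first dead
#'   checkpoint.
#' @return A `mouse_observation` object.
#' @export
mouse_observation <- function(animal_id, group, checkpoints,
                              events = empty_events(),
                              died = NULL, death_time_h = NULL) {
  checkpoints <- checkpoints[order(checkpoints$time_h), , drop = FALSE]
  rownames(checkpoints) <- NULL
  if (nrow(events)) {
    events$animal_id <- as.character(animal_id)
    if (!"descriptor" %in% names(events)) events$descriptor <- ""
    events <- events[, EVENT_COLUMNS, drop = FALSE]
  }
  rownames(events) <- NULL
  dead_at <- checkpoints$time_h[!checkpoints$alive]
  if (is.null(died)) died <- length(dead_at) > 0
  if (is.null(death_time_h)) death_time_h <- if (died) min(dead_at) else NA_real_
  structure(list(
    animal_id = as.character(animal_id),
    group = as.character(group),
    checkpoints = checkpoints,
    events = events,
    died = died,
    death_time_h = death_time_h
  ), class = "mouse_observation")
}

#' @export
print.mouse_observation <- function(x, ...) {
  cat(sprintf("<mouse_observation> %s (group %s)%s, %d checkpoints, %d events\n",
              x$animal_id, x$group,
              if (x$died) sprintf(", died at %g h", x$death_time_h) else "",
              nrow(x$checkpoints), nrow(x$events)))
  invisible(x)
}

#' An empty motor-event table
#' @return Zero-row data frame with the canonical event columns.
#' @export
empty_events <- function() {
  data.frame(animal_id = character(0), category = character(0),
             duration_min = numeric(0), intensity = character(0),
             descriptor = character(0), stringsAsFactors = FALSE)
}

parse_strict_logical <- function(x, file, rows) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "yes")] <- TRUE
  out[x0 %in% c("0", "false", "no")] <- FALSE
  bad <- which(!(x0 %in% c("1", "true", "yes", "0", "false", "no", "", "na")))
  if (length(bad))
    stop(sprintf("%s: unparseable boolean '%s' at row %d",
                 file, x0[bad[1]], rows[bad[1]]), call. = FALSE)
  out
}

#' Read observation sheets
#'
#' Ingests the canonical two-file layout (checkpoint table plus event table
#' keyed by `animal_id`) into a list of [mouse_observation()] records, one
#' per animal, rows grouped and time-sorted. Booleans are parsed strictly
#' from 0/1, true/false, yes/no. Milestone flags may be empty on rows with
#' `alive = 0`.
#'
#' @param observations_path Path to `observations.csv`.
#' @param events_path Optional path to `events.csv`; when `NULL` all animals
#'   get empty event lists.
#' @return List of `mouse_observation`, in first-appearance order.
#' @export
read_observations <- function(observations_path, events_path = NULL) {
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(obs), OBS_COLUMNS))
    stop(sprintf("%s: header must be exactly: %s", observations_path,
                 paste(OBS_COLUMNS, collapse = ",")), call. = FALSE)
  rows <- seq_len(nrow(obs)) + 1L  # file row numbers incl. header
  obs$time_h <- suppressWarnings(as.numeric(obs$time_h))
  if (anyNA(obs$time_h))
    stop(sprintf("%s: unparseable time_h at row %d", observations_path,
                 rows[which(is.na(obs$time_h))[1]]), call. = FALSE)
  obs$alive <- parse_strict_logical(obs$alive, observations_path, rows)
  if (anyNA(obs$alive))
    stop(sprintf("%s: missing alive at row %d", observations_path,
                 rows[which(is.na(obs$alive))[1]]), call. = FALSE)
  for (col in LATENCY_CATEGORIES) {
    obs[[col]] <- parse_strict_logical(obs[[col]], observations_path, rows)
    miss <- which(is.na(obs[[col]]) & obs$alive)
    if (length(miss))
      stop(sprintf("%s: missing %s on a live checkpoint at row %d",
                   observations_path, col, rows[miss[1]]), call. = FALSE)
  }
  dup <- duplicated(obs[c("animal_id", "time_h")])
  if (any(dup))
    stop(sprintf("%s: duplicated (animal_id, time_h) at row %d",
                 observations_path, rows[which(dup)[1]]), call. = FALSE)

  ev_all <- if (is.null(events_path)) empty_events() else {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!identical(names(ev), EVENT_COLUMNS))
      stop(sprintf("%s: header must be exactly: %s", events_path,
                   paste(EVENT_COLUMNS, collapse = ",")), call. = FALSE)
    ev$duration_min <- suppressWarnings(as.numeric(ev$duration_min))
    bad <- which(is.na(ev$duration_min) | !ev$category %in% EVENT_CATEGORIES |
                   !ev$intensity %in% INTENSITY_LEVELS)
    if (length(bad))
      stop(sprintf("%s: unparseable event at row %d", events_path,
                   bad[1] + 1L), call. = FALSE)
    ev
  }

  ids <- unique(obs$animal_id)
  lapply(ids, function(id) {
    sub <- obs[obs$animal_id == id, , drop = FALSE]
    grp <- unique(sub$group)
    if (length(grp) != 1)
      stop(sprintf("animal %s appears under multiple groups", id),
           call. = FALSE)
    ck <- sub[order(sub$time_h), c("time_h", "alive", LATENCY_CATEGORIES)]
    ev <- ev_all[ev_all$animal_id == id, , drop = FALSE]
    rownames(ev) <- NULL
    mouse_observation(id, grp, ck, ev)
  })
}

#' Write observation sheets
#'
#' Writes the canonical `observations.csv` / `events.csv` pair.
#' `read_observations()` on the output reproduces the input records
#' (milestone flags at dead checkpoints are written empty).
#'
#' @param obs List of `mouse_observation`.
#' @param observations_path,events_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_observations <- function(obs, observations_path, events_path) {
  fmt_flag <- function(x) ifelse(is.na(x), "", ifelse(x, "1", "0"))
  rows <- lapply(obs, function(o) {
    ck <- o$checkpoints
    df <- data.frame(animal_id = o$animal_id, group = o$group,
                     time_h = format_checkpoint(ck$time_h),
                     alive = fmt_flag(ck$alive), stringsAsFactors = FALSE)
    for (col in LATENCY_CATEGORIES)
      df[[col]] <- ifelse(ck$alive, fmt_flag(ck[[col]]), "")
    df
  })
  utils::write.csv(do.call(rbind, rows), observations_path, row.names = FALSE,
                   quote = FALSE)
  ev <- do.call(rbind, c(list(empty_events()),
                         lapply(obs, function(o) {
                           e <- o$events
                           if (nrow(e)) e$animal_id <- o$animal_id
                           e
                         })))
  ev$duration_min <- format_checkpoint(ev$duration_min)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  invisible(c(observations_path, events_path))
}

#' Validate observations against a rubric
#'
#' Produces a report distinguishing errors, which block scoring (checkpoint
#' times outside the rubric schedule, scheduled checkpoints missing before
#' death, events with negative durations or unknown categories/intensities),
#' from warnings (behavioral relapse — a milestone flag true at one
#' checkpoint and false at a later live one — and milestone flags recorded
#' after death). The report is independent of animal order.
#'
#' @param obs List of `mouse_observation`.
#' @param r An `evadint_rubric`.
#' @return Data frame with columns `animal_id`, `level` (`error`/`warning`),
#'   `message`; zero rows when fully clean.
#' @export
validate_observations <- function(obs, r = default_rubric()) {
  out <- list()
  add <- function(id, level, msg)
    out[[length(out) + 1L]] <<- data.frame(animal_id = id, level = level,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  sched <- r$checkpoints
  for (o in obs) {
    ck <- o$checkpoints
    extra <- setdiff(ck$time_h, sched)
    if (length(extra))
      add(o$animal_id, "error",
          sprintf("checkpoint at %g h not in the rubric schedule", extra[1]))
    expected <- if (o$died) sched[sched <= o$death_time_h] else sched
    missing <- setdiff(expected, ck$time_h)
    if (length(missing))
      add(o$animal_id, "error",
          sprintf("missing scheduled checkpoint at %g h", missing[1]))
    if (o$died && !is.na(o$death_time_h) &&
        o$death_time_h > r$observation_window_h)
      add(o$animal_id, "error", "death time beyond the observation window")
    live <- ck[ck$alive, , drop = FALSE]
    for (col in LATENCY_CATEGORIES) {
      f <- live[[col]]
      if (length(f) > 1 && any(diff(f) < 0))
        add(o$animal_id, "warning",
            sprintf("relapse in %s (recovered then lost)", col))
      if (any(!ck$alive & !is.na(ck[[col]])))
        add(o$animal_id, "warning",
            sprintf("%s flag recorded after death", col))
    }
    if (nrow(o$events)) {
      if (any(o$events$duration_min < 0 | !is.finite(o$events$duration_min)))
        add(o$animal_id, "error", "event with negative or non-finite duration")
      if (any(!o$events$category %in% EVENT_CATEGORIES))
        add(o$animal_id, "error", "event with unknown category")
      if (any(!o$events$intensity %in% INTENSITY_LEVELS))
        add(o$animal_id, "error", "event with unknown intensity")
    }
  }
  if (!length(out))
    return(data.frame(animal_id = character(0), level = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$animal_id, rep$level, rep$message), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Assign blinding codes
#'
#' Replaces animal ids with opaque codes and strips group labels, so scoring
#' can be performed blind to treatment arm; the returned map inverts the
#' coding exactly. The same seed always yields the same codes.
#'
#' @param obs List of `mouse_observation` with unique ids.
#' @param seed Integer seed for the code permutation.
#' @return List with `map` (a `blinding_map`: `code_by_animal` named vector,
#'   `seed`) and `blinded` (the recoded observations).
#' @export
assign_blinding <- function(obs, seed) {
  ids <- vapply(obs, function(o) o$animal_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate animal ids; blinding requires unique ids", call. = FALSE)
  codes <- local({
    set.seed(seed)
    sprintf("BL%03d", sample.int(length(ids)))
  })
  map <- structure(list(code_by_animal = stats::setNames(codes, ids),
                        seed = seed), class = "blinding_map")
  blinded <- lapply(seq_along(obs), function(i) {
    o <- obs[[i]]
    o$animal_id <- codes[i]
    o$group <- "blinded"
    if (nrow(o$events)) o$events$animal_id <- codes[i]
    o
  })
  list(map = map, blinded = blinded)
}

#' Reverse a blinding
#'
#' @param blinded Blinded observations or a scores data frame holding a
#'   `animal_id` column of codes.
#' @param map The `blinding_map` from [assign_blinding()].
#' @param groups Optional named vector animal_id -> group to restore labels.
#' @return The input with original animal ids (and groups) restored.
#' @export
unblind <- function(blinded, map, groups = NULL) {
  decode <- stats::setNames(names(map$code_by_animal), map$code_by_animal)
  if (is.data.frame(blinded)) {
    blinded$animal_id <- unname(decode[blinded$animal_id])
    if (!is.null(groups)) blinded$group <- unname(groups[blinded$animal_id])
    return(blinded)
  }
  lapply(blinded, function(o) {
    o$animal_id <- unname(decode[o$animal_id])
    if (!is.null(groups)) o$group <- unname(groups[o$animal_id])
    if (nrow(o$events)) o$events$animal_id <- o$animal_id
    o
  })
}
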