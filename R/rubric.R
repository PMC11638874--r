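# Rubric model: the EvADINT scoring table, its defaults, validation,
# and YAML (de)serialization.

#' Default EvADINT scoring rubric
#'
#' Returns the published scoring table: per-severity points for seizure and
#' hyperactivity events, per-checkpoint points for the four recovery
#' milestones (sternal posture, unstimulated movement, movement without
#' ataxia, normal grooming/eating/nesting), the death override score (75),
#' and the checkpoint schedule (0.5, 1, 2, 4, 24 h post anesthesia
#' reversal). The last checkpoint column also covers "no recovery".
#'
#' @return An object of class `evadint_rubric`: a list with elements
#'   `events` (named list of severity->points vectors), `latency` (named
#'   list of checkpoint->points vectors), `checkpoints` (numeric schedule),
#'   `death_score`, and `observation_window_h`.
#' @export
#' @examples
#' r <- default_rubric()
#' r$latency$sternal_posture[["2"]]  # 8 points for recovery in (1, 2] h
default_rubric <- function() {
  checkpoints <- c(0.5, 1, 2, 4, 24)
  lat <- function(points) stats::setNames(points, format_checkpoint(checkpoints))
  r <- structure(list(
    events = list(
      seizure       = stats::setNames(c(0, 10, 15, 20), SEVERITY_LEVELS),
      hyperactivity = stats::setNames(c(0, 5, 10, 15), SEVERITY_LEVELS)
    ),
    latency = list(
      sternal_posture         = lat(c(0, 4, 8, 12, 20)),
      unstimulated_movement   = lat(c(0, 3, 6, 9, 15)),
      movement_without_ataxia = lat(c(0, 2, 4, 6, 10)),
      grooming_eating_nesting = lat(c(0, 1, 2, 3, 5))
    ),
    checkpoints = checkpoints,
    death_score = 75,
    observation_window_h = 24
  ), class = "evadint_rubric")
  r
}

# Canonical text form of a checkpoint time used as a names key ("0.5", "24").
format_checkpoint <- function(x) {
  vapply(x, function(t) format(t, trim = TRUE, scientific = FALSE),
         character(1))
}

#' Validate a rubric
#'
#' Checks every structural invariant of the scoring table: non-negative
#' points; points at severity `none` equal to zero and non-decreasing in
#' severity; a strictly ascending checkpoint schedule shared by all latency
#' categories; zero points at the first checkpoint and non-decreasing points
#' across checkpoints; and a death score at least as large as every single
#' category's maximum.
#'
#' @param r An `evadint_rubric`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_rubric <- function(r) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (!is.list(r) || !all(c("events", "latency", "checkpoints",
                            "death_score") %in% names(r))) {
    return("rubric is not a well-formed evadint_rubric list")
  }
  ck <- r$checkpoints
  if (length(ck) < 2 || any(!is.finite(ck)) || any(diff(ck) <= 0))
    note("checkpoint schedule must be finite and strictly ascending")
  ck_keys <- format_checkpoint(ck)

  for (cat in EVENT_CATEGORIES) {
    w <- r$events[[cat]]
    if (is.null(w) || !identical(names(w), SEVERITY_LEVELS)) {
      note(sprintf("event category '%s' missing or misnamed severities", cat))
      next
    }
    if (any(w < 0)) note(sprintf("event '%s': negative points", cat))
    if (w[["none"]] != 0) note(sprintf("event '%s': points(none) must be 0", cat))
    if (any(diff(w) < 0))
      note(sprintf("event '%s': points must be non-decreasing in severity", cat))
  }
  for (cat in LATENCY_CATEGORIES) {
    w <- r$latency[[cat]]
    if (is.null(w)) {
      note(sprintf("latency category '%s' missing", cat))
      next
    }
    if (!identical(names(w), ck_keys))
      note(sprintf("latency '%s': checkpoint columns differ from the schedule", cat))
    if (any(w < 0)) note(sprintf("latency '%s': negative points", cat))
    if (length(w) && w[[1]] != 0)
      note(sprintf("latency '%s': first-checkpoint points must be 0", cat))
    if (any(diff(w) < 0))
      note(sprintf("latency '%s': points must be non-decreasing across checkpoints", cat))
  }
  if (!is.numeric(r$death_score) || length(r$death_score) != 1 ||
      r$death_score < 0) {
    note("death_score must be a single non-negative number")
  } else {
    maxima <- c(vapply(r$events, max, numeric(1)),
                vapply(r$latency, max, numeric(1)))
    over <- maxima[maxima > r$death_score]
    for (nm in names(over))
      note(sprintf("death_score (%g) below maximum of category '%s' (%g)",
                   r$death_score, nm, over[[nm]]))
  }
  bad
}

stop_if_invalid_rubric <- function(r) {
  bad <- validate_rubric(r)
  if (length(bad))
    stop("invalid rubric:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(r)
}

#' Load a rubric from a YAML configuration
#'
#' Reads a YAML document (file path or literal text) of overrides and merges
#' it onto [default_rubric()]. Recognised top-level keys: `events`
#' (category -> named severity points), `latency` (category -> vector of
#' points in checkpoint order, or named by checkpoint), `checkpoints`,
#' `death_score`, `observation_window_h`. An empty document yields the
#' default rubric. The merged rubric must pass [validate_rubric()].
#'
#' @param config Path to a YAML file, or a YAML string.
#' @return A validated `evadint_rubric`.
#' @export
load_rubric <- function(config) {
  doc <- tryCatch({
    if (length(config) == 1 && !grepl("[\n:]", config) && file.exists(config))
      yaml::read_yaml(config)
    else
      yaml::yaml.load(paste(config, collapse = "\n"))
  }, error = function(e) stop("rubric config failed to parse: ",
                              conditionMessage(e), call. = FALSE))
  r <- default_rubric()
  if (is.null(doc)) return(r)
  if (!is.list(doc)) stop("rubric config must be a YAML mapping", call. = FALSE)

  if (!is.null(doc$checkpoints)) {
    r$checkpoints <- as.numeric(doc$checkpoints)
    keys <- format_checkpoint(r$checkpoints)
    # re-key default latency rows if lengths agree, else flagged by validation
    r$latency <- lapply(r$latency, function(w) {
      if (length(w) == length(keys)) stats::setNames(as.numeric(w), keys) else w
    })
  }
  if (!is.null(doc$death_score)) r$death_score <- as.numeric(doc$death_score)
  if (!is.null(doc$observation_window_h))
    r$observation_window_h <- as.numeric(doc$observation_window_h)

  for (cat in names(doc$events)) {
    if (!cat %in% EVENT_CATEGORIES)
      stop("unknown event category in config: ", cat, call. = FALSE)
    w <- unlist(doc$events[[cat]])
    if (is.null(names(w)) && length(w) == length(SEVERITY_LEVELS))
      names(w) <- SEVERITY_LEVELS
    r$events[[cat]][names(w)] <- as.numeric(w)
  }
  keys <- format_checkpoint(r$checkpoints)
  for (cat in names(doc$latency)) {
    if (!cat %in% LATENCY_CATEGORIES)
      stop("unknown latency category in config: ", cat, call. = FALSE)
    w <- unlist(doc$latency[[cat]])
    if (is.null(names(w))) {
      if (length(w) != length(keys))
        stop(sprintf("latency '%s': expected %d values (one per checkpoint)",
                     cat, length(keys)), call. = FALSE)
      names(w) <- keys
    }
    r$latency[[cat]][names(w)] <- as.numeric(w)
  }
  stop_if_invalid_rubric(r)
  r
}

#' Serialize a rubric to YAML
#'
#' Inverse of [load_rubric()]: `load_rubric(serialize_rubric(r))` is the
#' identity on valid rubrics.
#'
#' @param r An `evadint_rubric`.
#' @param path Optional file path; when given the YAML is written there.
#' @return The YAML text, invisibly when `path` is given.
#' @export
serialize_rubric <- function(r, path = NULL) {
  doc <- list(
    checkpoints = r$checkpoints,
    death_score = r$death_score,
    observation_window_h = r$observation_window_h,
    events = lapply(r$events, as.list),
    latency = lapply(r$latency, as.list)
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.evadint_rubric <- function(x, ...) {
  cat("EvADINT rubric\n")
  cat("  checkpoints (h):", paste(x$checkpoints, collapse = ", "), "\n")
  for (cat_ in EVENT_CATEGORIES)
    cat(sprintf("  %-24s %s\n", cat_,
                paste(x$events[[cat_]], collapse = "/")))
  for (cat_ in LATENCY_CATEGORIES)
    cat(sprintf("  %-24s %s\n", cat_,
                paste(x$latency[[cat_]], collapse = "/")))
  cat("  death score:", x$death_score, "\n")
  invisible(x)
}
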