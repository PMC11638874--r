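write_obs_text <- function(lines, events = NULL) {
  op <- withr::local_tempfile(fileext = ".csv",
                              .local_envir = parent.frame())
  writeLines(c(paste(c("animal_id", "group", "time_h", "alive",
                       MILESTONES), collapse = ","), lines), op)
  ep <- NULL
  if (!is.null(events)) {
    ep <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
    writeLines(c("animal_id,category,duration_min,intensity,descriptor",
                 events), ep)
  }
  list(obs = op, events = ep)
}

full_rows <- function(id, flags_by_time) {
  vapply(seq_along(SCHEDULE), function(i)
    sprintf("%s,arm1,%s,1,%s", id, format(SCHEDULE[i]),
            paste(flags_by_time[[i]], collapse = ",")), character(1))
}

test_that("CSV ingestion groups rows per animal and parses strictly", {
  rows <- c(full_rows("a", rep(list(c(1, 1, 1, 1)), 5)),
            full_rows("b", rep(list(c(0, 0, 0, 0)), 5)))
  f <- write_obs_text(rows)
  obs <- read_observations(f$obs)
  expect_length(obs, 2)
  expect_equal(vapply(obs, function(o) o$animal_id, character(1)), c("a", "b"))
  expect_true(all(vapply(obs, function(o) nrow(o$events) == 0, logical(1))))
  expect_equal(obs[[1]]$checkpoints$time_h, SCHEDULE)
  expect_false(obs[[2]]$died)
})

test_that("a dead checkpoint marks the animal dead at that time", {
  rows <- c("a,arm1,0.5,1,0,0,0,0", "a,arm1,1,0,,,,")
  f <- write_obs_text(rows)
  obs <- read_observations(f$obs)
  expect_true(obs[[1]]$died)
  expect_equal(obs[[1]]$death_time_h, 1)
})

test_that("malformed input is rejected with the offending row", {
  f <- write_obs_text(c("a,arm1,0.5,1,1,1,1,1", "a,arm1,0.5,1,1,1,1,1"))
  expect_error(read_observations(f$obs), "row 3")

  f2 <- write_obs_text("a,arm1,0.5,maybe,1,1,1,1")
  expect_error(read_observations(f2$obs), "boolean")

  op <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,group,time_h", "a,g,0.5"), op)
  expect_error(read_observations(op), "header")

  f3 <- write_obs_text(full_rows("a", rep(list(c(1, 1, 1, 1)), 5)),
                       events = "a,levitation,5,low,x")
  expect_error(read_observations(f3$obs, f3$events), "unparseable event")
})

test_that("write-then-read round-trips records and bytes", {
  obs <- simulate_cohort(four_preset_design(seed = 9, n_per_arm = 3))
  d1 <- withr::local_tempdir()
  write_observations(obs, file.path(d1, "o.csv"), file.path(d1, "e.csv"))
  back <- read_observations(file.path(d1, "o.csv"), file.path(d1, "e.csv"))
  for (i in seq_along(obs)) {
    a <- obs[[i]]
    attributes(a) <- attributes(a)[c("names", "class")]
    expect_equal(back[[i]], a)
  }
  d2 <- withr::local_tempdir()
  write_observations(back, file.path(d2, "o.csv"), file.path(d2, "e.csv"))
  expect_identical(readLines(file.path(d2, "o.csv")),
                   readLines(file.path(d1, "o.csv")))
  expect_identical(readLines(file.path(d2, "e.csv")),
                   readLines(file.path(d1, "e.csv")))
})

test_that("validation separates blocking errors from warnings", {
  clean <- make_obs(recovery = rep(0.5, 4))
  expect_equal(nrow(validate_observations(list(clean))), 0)

  relapse <- make_obs(recovery = c(1, 0.5, 0.5, 0.5))
  relapse$checkpoints$sternal_posture <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  rep <- validate_observations(list(relapse))
  expect_equal(rep$level, "warning")
  expect_match(rep$message, "relapse")

  off <- make_obs()
  off$checkpoints$time_h[3] <- 3
  rep2 <- validate_observations(list(off))
  expect_true(any(rep2$level == "error" & grepl("schedule", rep2$message)))
  expect_true(any(grepl("missing", rep2$message)))

  neg <- make_obs(events = make_event("seizure", -5, "low"))
  expect_true(any(validate_observations(list(neg))$level == "error"))
})

test_that("validation is invariant to animal order", {
  set.seed(4)
  obs <- simulate_cohort(four_preset_design(seed = 4, n_per_arm = 4))
  obs[[2]]$checkpoints$time_h[2] <- 1.5  # plant one error
  a <- validate_observations(obs)
  b <- validate_observations(rev(obs))
  expect_equal(a, b)
})

test_that("blinding is deterministic, invertible, and seed-sensitive", {
  obs <- simulate_cohort(four_preset_design(seed = 2, n_per_arm = 3))
  bl <- assign_blinding(obs, seed = 7)
  expect_equal(anyDuplicated(bl$map$code_by_animal), 0)
  expect_true(all(vapply(bl$blinded, function(o) o$group == "blinded",
                         logical(1))))
  expect_equal(assign_blinding(obs, seed = 7)$map$code_by_animal,
               bl$map$code_by_animal)
  expect_false(identical(assign_blinding(obs, seed = 8)$map$code_by_animal,
                         bl$map$code_by_animal))
  groups <- vapply(obs, function(o) o$group, character(1))
  names(groups) <- vapply(obs, function(o) o$animal_id, character(1))
  restored <- unblind(bl$blinded, bl$map, groups)
  for (i in seq_along(obs)) expect_equal(restored[[i]], obs[[i]],
                                         ignore_attr = TRUE)
  expect_error(assign_blinding(c(obs, obs[1]), 1), "duplicate")
})
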