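test_that("key names normalise case-insensitively through the alias table", {
  expect_equal(normalize_key(c("ArrowDown", "DOWN", "down")),
               rep("ArrowDown", 3))
  expect_equal(normalize_key(c("Semicolon", ";")), c(";", ";"))
  expect_equal(normalize_key("S"), "s")
})

test_that("an empty log with a valid header parses to an empty cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("participant_id,group,task,hand,trial,state,key,",
                   "t_press_ms,t_release_ms", sep = ""), f)
  expect_length(read_keystroke_log(f), 0)
})

test_that("events group into sessions keyed by participant/task/hand/trial", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,group,task,hand,trial,state,key,t_press_ms,t_release_ms",
    "p1,PD,DFT,left,1,none,ArrowDown,0,90",
    "p1,PD,DFT,left,1,none,ArrowDown,300,380",
    "p1,PD,DFT,left,1,none,ArrowDown,600,NA"), f)
  recs <- read_keystroke_log(f)
  expect_length(recs, 1)
  expect_length(recs[[1]]$sessions, 1)
  s <- recs[[1]]$sessions[[1]]
  expect_equal(nrow(s$events), 3)
  expect_true(is.na(s$events$t_release[3]))  # unreleased kept
})

test_that("schema and record-level validation errors name the problem", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,task,hand,trial,state,key,t_press_ms",
               "p1,PD,DFT,left,1,none,ArrowDown,0"), f)
  expect_error(read_keystroke_log(f), "t_release_ms")
  df <- data.frame(participant_id = "p1", group = "PD", task = "DFT",
                   hand = "left", trial = 1, state = "none",
                   key = "ArrowDown", t_press_ms = 100, t_release_ms = 50)
  expect_error(keystroke_frame_to_records(df), "row 1")
  df$t_release_ms <- 150; df$task <- "WALK"
  expect_error(keystroke_frame_to_records(df), "unknown task")
  df$task <- "DFT"; df$hand <- "both"
  expect_error(keystroke_frame_to_records(df), "unknown hand")
  df$hand <- "left"; df$t_press_ms <- -5
  expect_error(keystroke_frame_to_records(df), "press time")
})

test_that("parsing is order-insensitive and the log round-trips", {
  set.seed(101)
  records <- generate_cohort(n_pd = 3, n_control = 3, tasks = "DFT")
  f <- withr::local_tempfile(fileext = ".csv")
  write_keystroke_log(records, f)
  back <- read_keystroke_log(f)
  expect_length(back, 6)
  s0 <- records[[1]]$sessions[[1]]
  ids <- vapply(back, function(r) r$participant_id, "")
  s1 <- back[[which(ids == records[[1]]$participant_id)]]$sessions[[1]]
  expect_equal(s1$events$t_press, s0$events$t_press)
  expect_equal(s1$events$t_release, s0$events$t_release)
  expect_equal(s1$events$key, s0$events$key)
  # shuffle the rows: identical sessions after the stable sort
  df <- read.csv(f, stringsAsFactors = FALSE)
  df <- df[sample(nrow(df)), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  back2 <- read_keystroke_log(f2)
  ids2 <- vapply(back2, function(r) r$participant_id, "")
  s2 <- back2[[which(ids2 == records[[1]]$participant_id)]]$sessions[[1]]
  expect_equal(s2$events$t_press, s0$events$t_press)
  # jsonl round-trips too
  f3 <- withr::local_tempfile(fileext = ".jsonl")
  write_keystroke_log(records, f3, format = "jsonl")
  back3 <- read_keystroke_log(f3, format = "jsonl")
  ids3 <- vapply(back3, function(r) r$participant_id, "")
  s3 <- back3[[which(ids3 == records[[1]]$participant_id)]]$sessions[[1]]
  expect_equal(s3$events$t_press, s0$events$t_press)
})

test_that("hold-key coverage is measured as window fraction", {
  full <- make_tap_session(seq(0, 19000, by = 500))
  r <- validate_session(full)
  expect_equal(r$hold_coverage, 1.0)
  expect_true(r$valid)

  none <- make_tap_session(seq(0, 19000, by = 500), hold = FALSE)
  r2 <- validate_session(none)
  expect_equal(r2$hold_coverage, 0)
  expect_false(r2$valid)

  # hold released halfway: coverage 0.5, invalid at the 0.90 default
  half <- tap_session("p", "DFT", "left", events = data.frame(
    key = c("ArrowLeft", rep("ArrowDown", 3)),
    t_press = c(0, 100, 400, 700),
    t_release = c(10000, 150, 450, 750)))
  expect_equal(validate_session(half)$hold_coverage, 0.5)
  expect_false(validate_session(half)$valid)
  expect_true(validate_session(half, hold_threshold = 0.4)$valid)
})

test_that("off-target, unreleased and out-of-window events are counted", {
  ev <- data.frame(
    key = c("ArrowLeft", rep("ArrowDown", 50), "Enter", "Enter"),
    t_press = c(0, seq(100, by = 300, length.out = 50), 500, 900),
    t_release = c(20000, seq(100, by = 300, length.out = 50) + 80, 550, 950))
  ev$t_release[5] <- NA
  ev <- rbind(ev, data.frame(key = "ArrowDown", t_press = 25000,
                             t_release = 25100))
  s <- tap_session("p", "DFT", "left", events = ev)
  r <- validate_session(s)
  expect_equal(r$n_off_target, 2)
  expect_equal(r$n_unreleased, 1)
  expect_equal(r$n_outside_window, 1)
})

test_that("score tables round-trip bit-identically at the written precision", {
  set.seed(55)
  records <- generate_cohort(n_pd = 2, n_control = 2, tasks = "DFT")
  scores <- score_cohort(records)
  expect_equal(nrow(scores), 8)  # 4 participants x 2 hands
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, f, digits = 6)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$ks, scores$ks)
  expect_equal(back$at, round(scores$at, 6))
  expect_equal(back$is_, round(scores$is_, 6))
  # empty cohort -> header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_scores(score_cohort(list()), f2)
  expect_equal(nrow(read.csv(f2)), 0)
})
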