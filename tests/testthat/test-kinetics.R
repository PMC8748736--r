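test_that("the window is half-open and key-filtered", {
  s <- make_tap_session(c(0, 19999, 20000), dwells = 50)
  expect_equal(nrow(target_taps(s)), 2)  # press at 20 000 ms excluded
  expect_equal(kinesia_score(s), 2)

  only_hold <- tap_session("p", "DFT", "left", events = data.frame(
    key = "ArrowLeft", t_press = 0, t_release = 20000))
  expect_equal(nrow(target_taps(only_hold)), 0)

  b <- tap_session("p", "BRAIN", "left", events = data.frame(
    key = c("s", ";", "Enter", "a", "s"),
    t_press = c(0, 300, 600, 900, 1200),
    t_release = c(80, 380, 680, 980, 1280)))
  expect_equal(target_taps(b)$key, c("s", ";", "s"))
})

test_that("KS counts presses including unreleased ones", {
  expect_equal(kinesia_score(tap_session("p", "DFT", "left")), 0)
  p <- seq(0, by = 250, length.out = 80)
  expect_equal(kinesia_score(make_tap_session(p)), 80)
  ev <- data.frame(key = "ArrowDown", t_press = c(0, 300, 600),
                   t_release = c(90, NA, 690))
  expect_equal(kinesia_score(tap_session("p", "DFT", "left", events = ev)), 3)
})

test_that("AT is the mean dwell over complete taps", {
  s <- tap_session("p", "DFT", "left", events = data.frame(
    key = "ArrowDown", t_press = c(0, 500, 1000),
    t_release = c(100, 620, 1140)))
  expect_equal(akinesia_time(s), 120)
  one <- tap_session("p", "DFT", "left", events = data.frame(
    key = "ArrowDown", t_press = 10, t_release = 105))
  expect_equal(akinesia_time(one), 95)
  expect_true(is.na(akinesia_time(tap_session("p", "DFT", "left"))))
  # unreleased tap excluded from the mean but not from KS
  ev <- data.frame(key = "ArrowDown", t_press = c(0, 500),
                   t_release = c(100, NA))
  s2 <- tap_session("p", "DFT", "left", events = ev)
  expect_equal(akinesia_time(s2), 100)
  expect_equal(kinesia_score(s2), 2)
})

test_that("IS is the n-1 variance of flight times with exclusions", {
  # travelling times {100, 200} -> sample variance 5000
  s <- tap_session("p", "DFT", "left", events = data.frame(
    key = "ArrowDown", t_press = c(0, 150, 400),
    t_release = c(50, 200, 450)))
  expect_equal(incoordination_score(s), 5000)
  # perfectly rhythmic -> 0
  p <- seq(0, by = 250, length.out = 40)
  expect_equal(incoordination_score(make_tap_session(p, dwells = 100)), 0)
  # interval adjacent to an unreleased tap is skipped
  ev <- data.frame(key = "ArrowDown",
                   t_press = c(0, 250, 500, 750, 1000),
                   t_release = c(100, NA, 600, 850, 1100))
  # intervals touching the unreleased tap 2 drop out; the rest are 150 ms
  expect_equal(incoordination_score(tap_session("p", "DFT", "left",
                                                events = ev)),
               0)
  # negative flight time (overlap) excluded from IS, kept for KS/AT
  ev2 <- data.frame(key = "ArrowDown",
                    t_press = c(0, 80, 300, 520),
                    t_release = c(100, 180, 400, 620))
  s2 <- tap_session("p", "DFT", "left", events = ev2)
  expect_equal(kinesia_score(s2), 4)
  expect_equal(incoordination_score(s2), var(c(120, 120)))
  expect_true(is.na(incoordination_score(make_tap_session(c(0, 300)))))
})

test_that("score_session bundles parameters with validity flags", {
  empty <- score_session(tap_session("p", "DFT", "left"))
  expect_equal(empty$ks, 0)
  expect_true(is.na(empty$at) && is.na(empty$is_))
  expect_false(empty$valid)

  p <- seq(0, by = 250, length.out = 80)
  sc <- score_session(make_tap_session(p, dwells = 100))
  expect_equal(sc$ks, 80)
  expect_equal(sc$at, 100)
  expect_equal(sc$is_, 0)
  expect_true(sc$valid)

  # BRAIN alternation errors counted, not subtracted
  b <- tap_session("p", "BRAIN", "left", events = data.frame(
    key = c("s", "s", ";", ";", "s"),
    t_press = c(0, 300, 600, 900, 1200),
    t_release = c(80, 380, 680, 980, 1280)))
  sb <- score_session(b)
  expect_equal(sb$ks, 5)
  expect_equal(sb$alternation_errors, 2)
})

test_that("scores are invariant to time shifts and out-of-window padding", {
  set.seed(42)
  for (i in 1:20) {
    s <- random_session()
    base <- score_session(s)
    shifted <- s
    shifted$t0 <- s$t0 + 1234.5
    shifted$events$t_press <- s$events$t_press + 1234.5
    shifted$events$t_release <- s$events$t_release + 1234.5
    sc <- score_session(shifted)
    expect_equal(sc$ks, base$ks)
    expect_equal(sc$at, base$at)
    expect_equal(sc$is_, base$is_)
    # pad with events beyond the window: nothing changes
    win <- 1000 * s$window_s
    pad <- s
    pad$events <- rbind(s$events, data.frame(
      key = task_keys(s$task)[1],
      t_press = win + c(100, 900), t_release = win + c(200, 1000)))
    sp <- score_session(pad)
    expect_equal(sp$ks, base$ks)
    expect_equal(sp$at, base$at)
    expect_equal(sp$is_, base$is_)
  }
})

test_that("KS ignores dwells; AT ignores travelling times", {
  p <- seq(0, by = 250, length.out = 50)
  a <- make_tap_session(p, dwells = 60)
  b <- make_tap_session(p, dwells = 140)
  expect_equal(kinesia_score(a), kinesia_score(b))
  # same dwells on different press grids -> same AT
  c1 <- make_tap_session(seq(0, by = 200, length.out = 50), dwells = 90)
  c2 <- make_tap_session(seq(0, by = 390, length.out = 50), dwells = 90)
  expect_equal(akinesia_time(c1), akinesia_time(c2))
  # adding a constant to every travelling time leaves IS unchanged
  d1 <- make_tap_session(cumsum(c(0, rep(c(250, 350), 20))), dwells = 100)
  d2 <- make_tap_session(cumsum(c(0, rep(c(300, 400), 20))), dwells = 100)
  expect_equal(incoordination_score(d1), incoordination_score(d2))
})

test_that("score_session agrees with the brute-force scorer on random sessions", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_session()
    got <- score_session(s)
    want <- brute_force_score(s)
    expect_identical(got$ks, want$ks)
    expect_equal(got$at, want$at, tolerance = 1e-12)
    expect_equal(got$is_, want$is_, tolerance = 1e-12)
  }
})
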