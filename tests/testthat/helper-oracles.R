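# Independent brute-force oracles, deliberately written with plain loops
# and no shared code with the package internals.

# naive scorer: loop over events, apply the definitions literally
brute_force_score <- function(session) {
  win_lo <- session$t0
  win_hi <- session$t0 + 1000 * session$window_s
  targets <- task_keys(session$task)
  ev <- session$events
  press <- numeric(0); release <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    if (ev$key[i] %in% targets &&
        ev$t_press[i] >= win_lo && ev$t_press[i] < win_hi) {
      press <- c(press, ev$t_press[i])
      release <- c(release, ev$t_release[i])
    }
  }
  o <- order(press)
  press <- press[o]; release <- release[o]
  ks <- length(press)
  dwells <- c()
  for (i in seq_along(press)) {
    if (!is.na(release[i])) dwells <- c(dwells, release[i] - press[i])
  }
  at <- if (length(dwells)) sum(dwells) / length(dwells) else NA_real_
  travels <- c()
  if (ks >= 2) {
    for (i in 1:(ks - 1)) {
      if (!is.na(release[i])) {
        tt <- press[i + 1] - release[i]
        if (tt >= 0) travels <- c(travels, tt)
      }
    }
  }
  is_ <- if (length(travels) >= 2) {
    m <- sum(travels) / length(travels)
    sum((travels - m)^2) / (length(travels) - 1)
  } else NA_real_
  list(ks = ks, at = at, is_ = is_)
}

# exhaustive pairwise concordance AUC, ties 1/2
brute_force_auc <- function(cases, controls, direction) {
  cs <- if (direction == "low") -cases else cases
  ct <- if (direction == "low") -controls else controls
  total <- 0
  for (x in cs) for (y in ct) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(cs) * length(ct))
}

# quick builder: complete taps at given press times with given dwells
make_tap_session <- function(presses, dwells = 100, task = "DFT",
                             key = NULL, hold = TRUE, t0 = 0, ...) {
  n <- length(presses)
  dwells <- rep_len(dwells, n)
  keys <- if (!is.null(key)) rep_len(key, n)
          else if (task == "DFT") rep("ArrowDown", n)
          else rep_len(c("s", ";"), n)
  ev <- data.frame(key = keys, t_press = presses,
                   t_release = presses + dwells)
  if (task == "DFT" && hold) {
    ev <- rbind(data.frame(key = "ArrowLeft", t_press = t0,
                           t_release = t0 + 1000 * task_window_s(task)),
                ev)
  }
  tap_session("p1", task, "left", events = ev, t0 = t0, ...)
}

# random session with messy features: off-target keys, unreleased
# presses, out-of-window events, occasional overlaps
random_session <- function(task = sample(c("DFT", "BRAIN"), 1)) {
  win <- 1000 * task_window_s(task)
  n <- sample(0:60, 1)
  press <- sort(runif(n, -500, win + 500))
  dwell <- runif(n, 10, 400)
  release <- press + dwell
  release[runif(n) < 0.05] <- NA  # unreleased
  keys <- if (task == "DFT") rep("ArrowDown", n) else
    sample(c("s", ";"), n, replace = TRUE)
  extra_n <- sample(0:5, 1)
  ev <- data.frame(key = keys, t_press = press, t_release = release)
  if (extra_n) {
    ep <- runif(extra_n, 0, win)
    ev <- rbind(ev, data.frame(key = sample(c("Enter", "a", "Space"),
                                            extra_n, replace = TRUE),
                               t_press = ep, t_release = ep + 50))
  }
  if (task == "DFT" && runif(1) < 0.9) {
    ev <- rbind(ev, data.frame(key = "ArrowLeft", t_press = 0,
                               t_release = win))
  }
  ev$t_press <- pmax(ev$t_press, 0)
  ev$t_release <- pmax(ev$t_release, ev$t_press)
  tap_session("r1", task, "left", events = ev)
}
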