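# Key-name normalisation. Browser keymaps disagree on arrow-key names
# ("ArrowDown" vs "Down") and on punctuation ("Semicolon" vs ";"), so all
# key identifiers are mapped case-insensitively onto one canonical token
# before any scoring logic sees them.

.key_aliases <- c(
  "arrowdown"  = "ArrowDown",  "down"  = "ArrowDown",
  "arrowup"    = "ArrowUp",    "up"    = "ArrowUp",
  "arrowleft"  = "ArrowLeft",  "left"  = "ArrowLeft",
  "arrowright" = "ArrowRight", "right" = "ArrowRight",
  ";" = ";", "semicolon" = ";",
  " " = "Space", "space" = "Space", "spacebar" = "Space",
  "enter" = "Enter", "return" = "Enter"
)

#' Normalise a key identifier
#'
#' Maps symbolic key names onto canonical tokens, case-insensitively, so
#' that logs captured by different browsers score identically. Single
#' printable characters are lower-cased; known aliases (e.g. `"Down"` and
#' `"ArrowDown"`) collapse onto one token.
#'
#' @param key character vector of key identifiers.
#' @return character vector of canonical key tokens.
#' @examples
#' normalize_key(c("ArrowDown", "DOWN", "Semicolon", "S"))
#' @export
normalize_key <- function(key) {
  key <- as.character(key)
  low <- tolower(trimws(key))
  out <- unname(.key_aliases[low])
  miss <- is.na(out)
  out[miss] <- low[miss]
  out
}

#' Task key sets
#'
#' The target (tapped) keys and, for the DFT task, the hold key that the
#' middle finger must keep depressed throughout the window.
#'
#' @param task `"DFT"` or `"BRAIN"`.
#' @return `task_keys()`: character vector of canonical target keys.
#'   `hold_key()`: the canonical hold key, or `NA_character_` for tasks
#'   without one.
#' @examples
#' task_keys("BRAIN")
#' hold_key("DFT")
#' @export
task_keys <- function(task) {
  switch(match.arg(task, c("DFT", "BRAIN")),
    DFT   = "ArrowDown",
    BRAIN = c("s", ";")
  )
}

#' @rdname task_keys
#' @export
hold_key <- function(task) {
  switch(match.arg(task, c("DFT", "BRAIN")),
    DFT   = "ArrowLeft",
    BRAIN = NA_character_
  )
}

#' Task window length in seconds
#'
#' @param task `"DFT"` (20 s) or `"BRAIN"` (30 s).
#' @return window length in seconds.
#' @export
task_window_s <- function(task) {
  switch(match.arg(task, c("DFT", "BRAIN")), DFT = 20, BRAIN = 30)
}
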