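.R3_FORBIDDEN <- data.frame(
  from = c("AA", "QA", "QS", "QS"),
  to   = c("QS", "QS", "AA", "QA"),
  stringsAsFactors = FALSE
)

.is_r3_violation <- function(from, to) {
  any(.R3_FORBIDDEN$from == from & .R3_FORBIDDEN$to == to)
}

#' Locate sleep onset
#'
#' Sleep onset is the start of the first sleep run (AS or QS) that reaches
#' the minimum accepted duration (default 6 epochs = 3 min). Epochs before
#' it form the falling-asleep window, inside which short AA, QA and AS runs
#' are accepted (infants drift between drowsy wake and active sleep within
#' 3 min while falling asleep).
#'
#' @param h a behavioral `hypnogram`.
#' @param min_run_epochs minimum accepted run length in epochs.
#' @return 0-based epoch index of onset, or `NA` if no sustained sleep run
#'   exists.
#' @export
find_sleep_onset <- function(h, min_run_epochs = 6L) {
  .assert_hypnogram(h, "behavioral")
  r <- runs_of(h)
  hit <- which(r$state %in% c("AS", "QS") & r$length_epochs >= min_run_epochs)
  if (length(hit) == 0L) return(NA_integer_)
  r$start_epoch[hit[1]]
}

#' Minimum-duration smoothing of a behavioral hypnogram
#'
#' Enforces the rule that only state changes lasting longer than 3 min
#' (default 6 epochs of 30 s) are accepted as a new state, with two
#' exceptions: vocalization (V) episodes of any length are kept, and short
#' AA/QA/AS runs lying wholly inside the falling-asleep window are kept.
#' Short runs are absorbed shortest-first (ties: earliest) into the
#' preceding run's state; if joining its neighbours would break the rule
#' that QS never borders AA or QA, the run becomes AS (the buffer state),
#' and a short AS run already buffering such a pair is absorbed backward —
#' the minimum-duration rule takes precedence and any remaining forbidden
#' adjacency is left for [validate_hypnogram()]. Iterates to a fixed point,
#' so the result is idempotent.
#'
#' @param h a behavioral `hypnogram`.
#' @param config a [bsa_config()] list (uses `$rules$min_run_epochs`).
#' @return A list with `hypnogram` (smoothed) and `log` (data.frame of
#'   relabeled runs: `start_epoch`, `length_epochs`, `from`, `to`).
#' @export
smooth_hypnogram <- function(h, config = bsa_config()) {
  .assert_hypnogram(h, "behavioral")
  min_run <- config$rules$min_run_epochs
  labels <- h$labels
  log_start <- integer(0); log_len <- integer(0)
  log_from <- character(0); log_to <- character(0)
  repeat {
    r <- rle(labels)
    st <- r$values; len <- r$lengths
    start <- cumsum(len) - len
    # the falling-asleep window is recomputed as runs coalesce, so the
    # stopping condition depends only on the current labels (idempotence)
    sleepy <- which(st %in% c("AS", "QS") & len >= min_run)
    onset <- if (length(sleepy) > 0L) start[sleepy[1]] else NA_integer_
    exempt <- st == "V"
    if (!is.na(onset)) {
      exempt <- exempt |
        (st %in% c("AA", "QA", "AS") & (start + len) <= onset)
    }
    cand <- which(len < min_run & !exempt)
    if (length(cand) == 0L) break
    i <- cand[order(len[cand], start[cand])][1]
    prev_state <- if (i > 1L) st[i - 1L] else NA_character_
    next_state <- if (i < length(st)) st[i + 1L] else NA_character_
    new <- if (!is.na(prev_state)) prev_state else next_state
    # absorbing the run joins its neighbours; when that pairing is itself a
    # forbidden wake/QS adjacency, fall back to the AS buffer state. A short
    # AS run between forbidden neighbours is instead absorbed backward (the
    # duration rule wins; any remaining adjacency is validation's business).
    if (!is.na(prev_state) && !is.na(next_state) &&
        .is_r3_violation(prev_state, next_state) && st[i] != "AS") {
      new <- "AS"
    }
    log_start <- c(log_start, start[i]); log_len <- c(log_len, len[i])
    log_from <- c(log_from, st[i]); log_to <- c(log_to, new)
    labels[seq.int(start[i] + 1L, length.out = len[i])] <- new
  }
  list(
    hypnogram = hypnogram(labels, h$epoch_length_s, h$start_time_s,
                          "behavioral"),
    log = data.frame(start_epoch = log_start, length_epochs = log_len,
                     from = log_from, to = log_to, stringsAsFactors = FALSE)
  )
}

#' Validate the wake/quiet-sleep transition rule
#'
#' Quiet sleep cannot directly follow quiet or active wakefulness, and wake
#' cannot directly follow quiet sleep — active sleep always buffers the two.
#' Such an adjacency is assumed to be annotator error.
#'
#' @param h a behavioral `hypnogram`.
#' @return A data.frame of violations in epoch order: `rule`,
#'   `boundary_epoch` (first epoch of the offending run), `from`, `to`;
#'   zero rows when the hypnogram is legal.
#' @export
validate_hypnogram <- function(h) {
  .assert_hypnogram(h, "behavioral")
  r <- runs_of(h)
  n <- nrow(r)
  if (n < 2L) {
    return(data.frame(rule = character(0), boundary_epoch = integer(0),
                      from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  from <- r$state[-n]; to <- r$state[-1]
  bad <- paste(from, to) %in% paste(.R3_FORBIDDEN$from, .R3_FORBIDDEN$to)
  data.frame(rule = rep("R3", sum(bad)),
             boundary_epoch = r$start_epoch[-1][bad],
             from = from[bad], to = to[bad], stringsAsFactors = FALSE)
}

#' Repair forbidden transitions
#'
#' Optional automatic alternative to re-annotation: for each violating run
#' pair, the shorter of the two runs (ties: the later one) is relabeled AS,
#' the buffer state, and validation is repeated to a fixed point. Legal
#' input is returned unchanged.
#'
#' @param h a behavioral `hypnogram`.
#' @return A behavioral `hypnogram` with zero validation violations.
#' @export
repair_hypnogram <- function(h) {
  .assert_hypnogram(h, "behavioral")
  labels <- h$labels
  repeat {
    r <- rle(labels)
    st <- r$values; len <- r$lengths
    start <- cumsum(len) - len
    n <- length(st)
    if (n < 2L) break
    bad <- which(paste(st[-n], st[-1]) %in%
                 paste(.R3_FORBIDDEN$from, .R3_FORBIDDEN$to))
    if (length(bad) == 0L) break
    v <- bad[1]
    pick <- if (len[v] < len[v + 1L]) v else v + 1L
    labels[seq.int(start[pick] + 1L, length.out = len[pick])] <- "AS"
  }
  hypnogram(labels, h$epoch_length_s, h$start_time_s, "behavioral")
}
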