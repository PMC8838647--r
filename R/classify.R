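#' Build the Prechtl observation vector for an epoch
#'
#' The four observational properties that define the behavioral states:
#' eyes open, respiration regular, gross movements, vocalization. Eyes and
#' respiration can be `"unknown"` (eyes invisible; too few clean breath
#' cycles). Vocalization encodes the video-confirmed crying judgment — it is
#' driven by the cry channel and never by the audio envelope alone.
#'
#' @param f one row of [recording_features()].
#' @param config a [bsa_config()] list.
#' @param prev_eyes the previous epoch's eyes judgment, used only to break an
#'   exact 50/50 open/closed tie; the first epoch ties to the sleep side
#'   (`"no"`).
#' @return A list with fields `eyes_open`, `respiration_regular`
#'   (`"yes"`/`"no"`/`"unknown"`), `gross_movements`, `vocalization`
#'   (`"yes"`/`"no"`).
#' @export
observation_vector <- function(f, config = bsa_config(), prev_eyes = "no") {
  cc <- config$classify
  eyes <- if (is.na(f$eyes_open_fraction)) {
    "unknown"
  } else if (f$eyes_open_fraction > cc$eyes_open_min_fraction) {
    "yes"
  } else if (f$eyes_open_fraction < cc$eyes_open_min_fraction) {
    "no"
  } else {
    if (prev_eyes %in% c("yes", "no")) prev_eyes else "no"
  }
  resp <- switch(f$resp_verdict,
                 REGULAR = "yes", IRREGULAR = "no", UNDETERMINED = "unknown")
  gross <- if (f$gross_count >= 1L) "yes" else "no"
  voc <- if (f$cry_fraction >= cc$cry_min_fraction) "yes" else "no"
  list(eyes_open = eyes, respiration_regular = resp,
       gross_movements = gross, vocalization = voc)
}

#' Classify an observation vector into a behavioral state
#'
#' Pure lookup in the Prechtl state table. Crying always yields V (the table
#' leaves eyes free for state 5). Otherwise eyes and respiration are the
#' discriminating properties: closed eyes with regular respiration is QS,
#' closed with irregular is AS, open with regular and no gross movement is
#' QA, open with irregular is AA. Gross movement cannot hard-exclude the
#' sleep rows (infants show gross movements during AS and occasionally QS),
#' so it only splits the wake rows and flags ambiguity: closed or open eyes
#' with regular respiration plus gross movement matches no row and returns
#' `"UNDECIDED"`, as does any vector with a required property unknown.
#'
#' @param v an [observation_vector()].
#' @return A behavioral state token or `"UNDECIDED"`.
#' @export
classify_vector <- function(v) {
  if (v$vocalization == "yes") return("V")
  if (v$eyes_open == "unknown" || v$respiration_regular == "unknown") {
    return("UNDECIDED")
  }
  if (v$eyes_open == "no") {
    if (v$respiration_regular == "no") return("AS")
    if (v$gross_movements == "yes") return("UNDECIDED")
    return("QS")
  }
  # eyes open
  if (v$respiration_regular == "no") return("AA")
  if (v$gross_movements == "yes") return("UNDECIDED")
  "QA"
}

#' Wake/sleep movement heuristics for ambiguous epochs
#'
#' When the vector lookup is blocked, movement observations discriminate
#' wake from sleep: twitches and long quiet intervals point to sleep; many
#' closely spaced movements or sustained gross movement point to wake. Each
#' cue contributes one vote.
#'
#' @param f one row of [recording_features()].
#' @param config a [bsa_config()] list.
#' @return `"sleep-leaning"`, `"wake-leaning"` or `"neutral"`.
#' @export
movement_fallback <- function(f, config = bsa_config()) {
  cc <- config$classify
  score <- 0L
  if (f$twitch_count >= 1L) score <- score + 1L
  mib <- f$mean_inter_burst_s
  if (f$burst_count == 0L || (!is.na(mib) && mib >= cc$sleep_interval_s)) {
    score <- score + 1L
  }
  if (f$burst_count >= cc$wake_burst_count &&
      !is.na(mib) && mib < cc$wake_interval_s) {
    score <- score - 1L
  }
  if (f$max_gross_duration_s >= cc$sustained_s) score <- score - 1L
  if (score > 0L) "sleep-leaning" else if (score < 0L) "wake-leaning" else "neutral"
}

#' Decide the behavioral state of one epoch
#'
#' The full decision cascade: the vector lookup wins when it decides;
#' otherwise the movement fallback splits sleep from wake (sleep side: AS
#' when respiration is irregular or unknown with heavy movement noise,
#' else QS; wake side: AA with gross movement, else QA); a neutral fallback
#' carries the previous epoch's state forward (states are held until a
#' transition is complete). A neutral first epoch defaults to AS, the hub
#' state adjacent to every other state in the transition graph.
#'
#' @param v an [observation_vector()].
#' @param f one row of [recording_features()].
#' @param fallback result of [movement_fallback()].
#' @param prev_state previous epoch's state or `NULL`.
#' @param config a [bsa_config()] list.
#' @return A list with `state` and `rationale`
#'   (`"vector"`, `"movement-fallback"`, `"carry-forward"`).
#' @export
resolve_epoch <- function(v, f, fallback, prev_state = NULL,
                          config = bsa_config()) {
  cc <- config$classify
  s <- classify_vector(v)
  if (s != "UNDECIDED") return(list(state = s, rationale = "vector"))
  if (fallback == "sleep-leaning") {
    state <- if (v$respiration_regular == "no") {
      "AS"
    } else if (v$respiration_regular == "unknown" &&
               f$movement_noise_fraction >= cc$active_noise_fraction) {
      "AS"
    } else {
      "QS"
    }
    return(list(state = state, rationale = "movement-fallback"))
  }
  if (fallback == "wake-leaning") {
    state <- if (v$gross_movements == "yes") "AA" else "QA"
    return(list(state = state, rationale = "movement-fallback"))
  }
  state <- if (is.null(prev_state)) "AS" else prev_state
  list(state = state, rationale = "carry-forward")
}

#' Classify a whole recording into a behavioral hypnogram
#'
#' Extracts features per 30-s epoch and runs the decision cascade in epoch
#' order, with the per-second majority inside each epoch determining the
#' eyes and cry inputs (the state comprising the greatest portion of an
#' epoch is assigned). Returns the hypnogram together with a per-epoch audit
#' of every decision and its rationale.
#'
#' @param channels a [channel_set()].
#' @param config a [bsa_config()] list.
#' @return A list with `hypnogram` (behavioral), `audit` (data.frame with
#'   columns `epoch`, `state`, `rationale`, `eyes`, `resp`, `gross`, `voc`)
#'   and `features` (the [recording_features()] table).
#' @export
classify_recording <- function(channels, config = bsa_config()) {
  feats <- recording_features(channels, config)
  n <- nrow(feats)
  states <- character(n)
  audit <- vector("list", n)
  prev_state <- NULL
  prev_eyes <- "no"
  for (i in seq_len(n)) {
    f <- feats[i, ]
    v <- observation_vector(f, config, prev_eyes = prev_eyes)
    fb <- movement_fallback(f, config)
    d <- resolve_epoch(v, f, fb, prev_state, config)
    states[i] <- d$state
    audit[[i]] <- data.frame(
      epoch = f$epoch, state = d$state, rationale = d$rationale,
      eyes = v$eyes_open, resp = v$respiration_regular,
      gross = v$gross_movements, voc = v$vocalization,
      stringsAsFactors = FALSE
    )
    prev_state <- d$state
    if (v$eyes_open %in% c("yes", "no")) prev_eyes <- v$eyes_open
  }
  list(
    hypnogram = hypnogram(states, config$epoch_length_s, 0, "behavioral"),
    audit = do.call(rbind, audit),
    features = feats
  )
}
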