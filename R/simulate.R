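#' Simulator configuration
#'
#' Defaults encode the architecture of a daytime infant nap: bout durations
#' drawn from truncated normal distributions with mean 26 min for AS and
#' 28 min for QS (an AS+QS cycle of ~54 min, inside the 50-60 min range
#' typical of infant sleep cycles, and matching a mean naptime of ~54 min),
#' short wake and vocalization bouts, and a transition graph in which wake
#' states and QS communicate only through AS, with V reachable only from and
#' to AA. Respiration is regular (rate jitter well under the 20 cycles/min
#' criterion) in QS/QA and irregular (alternating slow/fast breaths spanning
#' more than 20 cycles/min, plus occasional apneic pauses) in AS/AA/V.
#' Movement bursts follow state-conditional Poisson rates: rare in the quiet
#' states, frequent twitches and gross movements in AS, sustained gross
#' movement in AA.
#'
#' @param ... named overrides merged over the defaults.
#' @return A nested list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    duration_min = 55,
    fs = 16,
    seed = 1L,
    initial_state = "AA",
    bouts = list(
      mean_min = c(AS = 26, QS = 28, AA = 4, QA = 1.5, V = 2),
      rel_sd = 0.15,
      min_min = 1.5
    ),
    transitions = list(
      AA = c(AS = 0.7, QA = 0.1, V = 0.2),
      QA = c(AS = 0.8, AA = 0.2),
      AS = c(QS = 0.85, AA = 0.1, QA = 0.05),
      QS = c(AS = 1),
      V  = c(AA = 1)
    ),
    resp = list(
      base_rate_cpm = 35,
      regular_jitter_cpm = 4,
      irregular_swing_cpm = 13,
      irregular_jitter_cpm = 2,
      apnea_per_min = 0.1,
      apnea_range_s = c(3, 8),
      amplitude = 1,
      amp_jitter = 0.1
    ),
    movement = list(
      gross_per_min = c(QS = 0.1, AS = 1.0, QA = 0.2, AA = 4, V = 3),
      twitch_per_min = c(QS = 0.1, AS = 1.5, QA = 0, AA = 0, V = 0),
      gross_duration_s = c(1, 3),
      sustained_duration_s = c(5, 8),
      twitch_duration_s = c(0.15, 0.35),
      gross_amplitude = 1,
      twitch_amplitude = 0.18,
      baseline_sd = 0.01,
      resp_noise_gain = 1.5
    ),
    eyes = list(
      open_prob = c(QS = 0.02, AS = 0.03, QA = 0.9, AA = 0.9, V = 0.85),
      unknown_prob = 0.1
    ),
    audio = list(
      baseline = 0.02,
      cry_level = 1.0,
      sleep_sound_level = 0.4,
      sleep_sound_epoch_frac = 0.2
    )
  )
  structure(.merge_cfg(cfg, list(...)), class = c("sim_config", "list"))
}

.derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + 17L * k
}

.validate_sim_config <- function(cfg) {
  b <- cfg$bouts
  if (cfg$duration_min <= 0) stop("duration_min must be positive")
  if (any(b$mean_min <= 0) || b$min_min <= 0) stop("bout durations must be positive")
  for (s in names(cfg$transitions)) {
    w <- cfg$transitions[[s]]
    if (any(w < 0) || sum(w) <= 0) stop("invalid transition weights from ", s)
    bad <- c(if (s == "QS") c("AA", "QA", "V"),
             if (s %in% c("AA", "QA")) "QS",
             if (s == "V") c("QS", "AS", "QA"),
             if (s %in% c("QS", "AS", "QA")) "V")
    if (any(names(w)[w > 0] %in% bad)) {
      stop("transition graph allows a forbidden edge from ", s)
    }
  }
  p <- c(cfg$eyes$open_prob, cfg$eyes$unknown_prob)
  if (any(p < 0 | p > 1)) stop("eyes probabilities must be in [0,1]")
  invisible(cfg)
}

#' Sample a ground-truth behavioral state sequence
#'
#' Semi-Markov draw: bout states follow the legal transition graph and bout
#' durations are truncated normal with the configured means; the continuous
#' bout sequence is discretized to 30-s epochs by majority overlap. Bouts are
#' floored at 1.5 min, so no bout can vanish during discretization and the
#' resulting hypnogram is always free of forbidden transitions.
#'
#' @param cfg a [sim_config()].
#' @return A list with `hypnogram` (behavioral, 30-s epochs) and `bouts`
#'   (data.frame `state`, `start_s`, `duration_s`).
#' @export
sample_state_sequence <- function(cfg = sim_config()) {
  .validate_sim_config(cfg)
  dur_s <- cfg$duration_min * 60
  b <- cfg$bouts
  state <- cfg$initial_state
  t <- 0
  states <- character(0); starts <- numeric(0); durs <- numeric(0)
  while (t < dur_s) {
    m <- b$mean_min[[state]] * 60
    lo <- max(b$min_min * 60, 0.5 * m)
    hi <- 1.5 * m
    d <- stats::rnorm(1, m, b$rel_sd * m)
    d <- min(max(d, lo), hi)
    states <- c(states, state); starts <- c(starts, t); durs <- c(durs, d)
    t <- t + d
    w <- cfg$transitions[[state]]
    state <- sample(names(w), 1, prob = w)
  }
  n_ep <- floor(dur_s / 30)
  labels <- character(n_ep)
  ends <- starts + durs
  for (e in seq_len(n_ep)) {
    w0 <- (e - 1) * 30; w1 <- e * 30
    ov <- pmin(ends, w1) - pmax(starts, w0)
    labels[e] <- states[which.max(ov)]  # ties resolve to the earlier bout
  }
  list(
    hypnogram = hypnogram(labels, 30, 0, "behavioral"),
    bouts = data.frame(state = states, start_s = starts, duration_s = durs,
                       stringsAsFactors = FALSE)
  )
}

#' Synthesize a state-conditional respiration waveform
#'
#' Builds the signal breath by breath: each cycle is one full sinusoid whose
#' duration is set by the state at its onset. In the regular states (QS/QA)
#' per-breath rates jitter a few cycles/min around the base rate, keeping the
#' within-epoch rate range well below the 20 cycles/min criterion; in the
#' irregular states (AS/AA/V) breaths alternate between slow and fast so the
#' range clears 20 cycles/min, and apneic pauses of 3-8 s are inserted at the
#' configured rate. The waveform is continuous at state boundaries.
#'
#' @param truth behavioral `hypnogram` of the nap.
#' @param cfg a [sim_config()].
#' @return A list with `wave`, `truth_regularity` (per-epoch REGULAR /
#'   IRREGULAR), and `apneas` (data.frame `onset_s`, `duration_s`).
#' @export
synth_respiration <- function(truth, cfg = sim_config()) {
  rp <- cfg$resp
  fs <- cfg$fs
  n_ep <- n_epochs(truth)
  n <- n_ep * 30 * fs
  pieces <- list()
  total <- 0L
  toggle <- TRUE
  ap_on <- numeric(0); ap_dur <- numeric(0)
  # apneas/min divided by breaths/min = per-breath apnea probability
  p_apnea_per_breath <- rp$apnea_per_min / rp$base_rate_cpm
  while (total < n) {
    t_now <- total / fs
    ep <- min(floor(t_now / 30) + 1L, n_ep)
    st <- truth$labels[ep]
    irregular <- st %in% c("AS", "AA", "V")
    if (irregular && stats::runif(1) < p_apnea_per_breath) {
      d <- stats::runif(1, rp$apnea_range_s[1], rp$apnea_range_s[2])
      m <- max(1L, round(d * fs))
      pieces[[length(pieces) + 1L]] <- stats::rnorm(m, 0, 0.01 * rp$amplitude)
      ap_on <- c(ap_on, t_now); ap_dur <- c(ap_dur, m / fs)
      total <- total + m
      next
    }
    rate <- if (irregular) {
      r <- rp$base_rate_cpm +
        (if (toggle) rp$irregular_swing_cpm else -rp$irregular_swing_cpm) +
        stats::runif(1, -rp$irregular_jitter_cpm, rp$irregular_jitter_cpm)
      toggle <- !toggle
      r
    } else {
      rp$base_rate_cpm +
        stats::runif(1, -rp$regular_jitter_cpm, rp$regular_jitter_cpm)
    }
    m <- max(2L, round(60 / rate * fs))
    A <- rp$amplitude * (1 + stats::runif(1, -rp$amp_jitter, rp$amp_jitter))
    pieces[[length(pieces) + 1L]] <- A * sin(2 * pi * seq(0, m - 1) / m)
    total <- total + m
  }
  wave <- unlist(pieces, use.names = FALSE)[seq_len(n)]
  list(
    wave = wave,
    truth_regularity = ifelse(truth$labels %in% c("QS", "QA"),
                              "REGULAR", "IRREGULAR"),
    apneas = data.frame(onset_s = ap_on, duration_s = ap_dur)
  )
}

.hann <- function(m) {
  if (m == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
}

#' Synthesize a state-conditional movement waveform
#'
#' Per-epoch Poisson burst counts at state-conditional rates: seldom in the
#' quiet states, frequent gross movements and twitches in AS, and sustained
#' (5-8 s) gross movement in AA — each AA epoch is guaranteed at least one
#' sustained burst. Bursts are smooth amplitude bumps on a near-zero noise
#' baseline.
#'
#' @param truth behavioral `hypnogram`.
#' @param cfg a [sim_config()].
#' @return A list with `wave` and `bursts` (data.frame `onset_s`,
#'   `duration_s`, `amplitude`, `kind`).
#' @export
synth_movement <- function(truth, cfg = sim_config()) {
  mv <- cfg$movement
  fs <- cfg$fs
  n_ep <- n_epochs(truth)
  n <- n_ep * 30 * fs
  wave <- stats::rnorm(n, 0, mv$baseline_sd)
  on <- numeric(0); du <- numeric(0); am <- numeric(0); ki <- character(0)
  for (e in seq_len(n_ep)) {
    st <- truth$labels[e]
    w0 <- (e - 1) * 30
    ng <- stats::rpois(1, mv$gross_per_min[[st]] * 0.5)
    if (st == "AA" && mv$gross_per_min[["AA"]] > 0) {
      ng <- max(1L, ng)  # AA always shows sustained movement
    }
    nt <- stats::rpois(1, mv$twitch_per_min[[st]] * 0.5)
    if (ng > 0L) {
      rng <- if (st == "AA") mv$sustained_duration_s else mv$gross_duration_s
      d <- stats::runif(ng, rng[1], rng[2])
      o <- stats::runif(ng, 0, 30 - min(29, max(d)))
      a <- mv$gross_amplitude * stats::runif(ng, 0.7, 1.3)
      on <- c(on, w0 + o); du <- c(du, d); am <- c(am, a)
      ki <- c(ki, rep("gross", ng))
    }
    if (nt > 0L) {
      d <- stats::runif(nt, mv$twitch_duration_s[1], mv$twitch_duration_s[2])
      o <- stats::runif(nt, 0, 29)
      a <- mv$twitch_amplitude * stats::runif(nt, 0.8, 1.2)
      on <- c(on, w0 + o); du <- c(du, d); am <- c(am, a)
      ki <- c(ki, rep("twitch", nt))
    }
  }
  if (length(on) > 0L) {
    for (i in seq_along(on)) {
      i0 <- floor(on[i] * fs) + 1L
      m <- max(2L, round(du[i] * fs))
      i1 <- min(n, i0 + m - 1L)
      seg <- seq.int(i0, i1)
      wave[seg] <- wave[seg] + am[i] * .hann(m)[seq_along(seg)]
    }
  }
  list(wave = wave,
       bursts = data.frame(onset_s = on, duration_s = du, amplitude = am,
                           kind = ki, stringsAsFactors = FALSE))
}

#' Synthesize eyes, audio-envelope and cry channels
#'
#' Eyes are open with high probability per second in the wake states and
#' closed in sleep, with a configurable per-second chance of being unknown
#' (eyes covered by an arm or blanket). Cry is 1 throughout V bouts and 0
#' elsewhere. The audio envelope is elevated during V and during a fraction
#' of AS epochs (sleep sounds: whimpers and moans), which exercises the rule
#' that vocalization is never scored from audio alone.
#'
#' @param truth behavioral `hypnogram`.
#' @param cfg a [sim_config()].
#' @return A list with `eyes` and `cry` (1 Hz) and `audio_env` (at `cfg$fs`).
#' @export
synth_eyes_audio_cry <- function(truth, cfg = sim_config()) {
  ey <- cfg$eyes; au <- cfg$audio
  fs <- cfg$fs
  n_ep <- n_epochs(truth)
  nsec <- n_ep * 30
  sec_state <- truth$labels[pmin(n_ep, (seq_len(nsec) - 1) %/% 30 + 1)]
  p_open <- ey$open_prob[sec_state]
  eyes <- as.integer(stats::runif(nsec) < p_open)
  eyes[stats::runif(nsec) < ey$unknown_prob] <- NA_integer_
  cry <- as.integer(sec_state == "V")
  sound_as <- truth$labels == "AS" &
    stats::runif(n_ep) < au$sleep_sound_epoch_frac
  lvl_ep <- ifelse(truth$labels == "V", au$cry_level,
                   ifelse(sound_as, au$sleep_sound_level, 0))
  n <- nsec * fs
  ep_of_sample <- pmin(n_ep, (seq_len(n) - 1) %/% (30 * fs) + 1)
  audio_env <- lvl_ep[ep_of_sample] + au$baseline * abs(stats::rnorm(n))
  list(eyes = eyes, cry = cry, audio_env = audio_env)
}

#' Simulate a complete ground-truth nap
#'
#' Composes the state-sequence, respiration, movement and eyes/audio/cry
#' generators into one recording. Deterministic given `cfg$seed`: a single
#' root seed derives one fixed sub-stream per component, so regenerating one
#' channel never perturbs the others. Gross movement bursts are also added
#' into the respiration channel (scaled by `resp_noise_gain`) — movement is
#' noise in the respiration signal, and the classifier treats its extent as
#' information.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_output` with `channels` ([channel_set()]),
#'   `truth` (behavioral `hypnogram`), `truth_regularity`, `bouts`, and
#'   `events` (`bursts`, `apneas`).
#' @export
simulate_nap <- function(cfg = sim_config()) {
  .validate_sim_config(cfg)
  set.seed(.derive_seed(cfg$seed, 1L))
  seq_out <- sample_state_sequence(cfg)
  truth <- seq_out$hypnogram
  set.seed(.derive_seed(cfg$seed, 2L))
  resp <- synth_respiration(truth, cfg)
  set.seed(.derive_seed(cfg$seed, 3L))
  mov <- synth_movement(truth, cfg)
  set.seed(.derive_seed(cfg$seed, 4L))
  eac <- synth_eyes_audio_cry(truth, cfg)

  wave_resp <- resp$wave
  gr <- mov$bursts[mov$bursts$kind == "gross", , drop = FALSE]
  if (nrow(gr) > 0L && cfg$movement$resp_noise_gain > 0) {
    fs <- cfg$fs
    n <- length(wave_resp)
    for (i in seq_len(nrow(gr))) {
      i0 <- floor(gr$onset_s[i] * fs) + 1L
      m <- max(2L, round(gr$duration_s[i] * fs))
      i1 <- min(n, i0 + m - 1L)
      seg <- seq.int(i0, i1)
      bump <- gr$amplitude[i] * cfg$movement$resp_noise_gain * .hann(m)
      wave_resp[seg] <- wave_resp[seg] +
        bump[seq_along(seg)] * sin(2 * pi * 4 * seg / fs)
    }
  }
  channels <- channel_set(
    resp = wave_resp, move = mov$wave, audio_env = eac$audio_env,
    eyes = eac$eyes, cry = eac$cry, fs = cfg$fs
  )
  structure(
    list(channels = channels, truth = truth,
         truth_regularity = resp$truth_regularity,
         bouts = seq_out$bouts,
         events = list(bursts = mov$bursts, apneas = resp$apneas)),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output: %d epochs>\n", n_epochs(x$truth)))
  print(x$truth)
  invisible(x)
}
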