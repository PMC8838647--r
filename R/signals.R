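#' Detect breath cycles in a respiration waveform
#'
#' Band-pass filters the signal to the infant breathing band (default
#' 0.2-2.0 Hz) and segments it into cycles between successive upward
#' zero-crossings. Each cycle carries its minute-extrapolated rate
#' `60 / duration`, the quantity the regularity criterion compares.
#'
#' @param resp numeric respiration waveform.
#' @param fs sample rate in Hz.
#' @param config a [bsa_config()] list (only `$signals` is used).
#' @return A data.frame with columns `onset_s`, `duration_s`, `rate_cpm`,
#'   ordered and non-overlapping. A flat signal yields zero rows.
#' @export
detect_breath_cycles <- function(resp, fs, config = bsa_config()) {
  if (fs <= 0) stop("fs must be positive")
  sc <- config$signals
  x <- resp - mean(resp)
  if (max(abs(x)) < .Machine$double.eps) {
    return(.empty_cycles())
  }
  band <- sc$resp_band_hz
  ny <- fs / 2
  hi <- min(band[2], 0.95 * ny)
  bf <- signal::butter(2, c(band[1], hi) / ny, type = "pass")
  xf <- signal::filtfilt(bf, x)
  # upward zero-crossings: sample i with xf[i] <= 0 and xf[i+1] > 0
  up <- which(xf[-length(xf)] <= 0 & xf[-1] > 0)
  if (length(up) < 2L) return(.empty_cycles())
  # amplitude gate: a crossing only starts a breath if the excursion that
  # follows it reaches a fraction of the typical breath amplitude, so an
  # apneic pause (low-level noise) extends the enclosing cycle instead of
  # fragmenting into spurious mini-cycles
  peaks <- vapply(seq_len(length(up) - 1L), function(i) {
    max(abs(xf[up[i]:up[i + 1L]]))
  }, numeric(1))
  gate <- sc$amp_gate_frac * stats::median(peaks)
  up <- up[c(peaks >= gate, TRUE)]
  if (length(up) < 2L) return(.empty_cycles())
  onset <- (up - 1) / fs
  dur <- diff(onset)
  onset <- onset[-length(onset)]
  keep <- dur >= sc$min_cycle_s
  onset <- onset[keep]; dur <- dur[keep]
  if (length(dur) == 0L) return(.empty_cycles())
  data.frame(onset_s = onset, duration_s = dur, rate_cpm = 60 / dur)
}

.empty_cycles <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             rate_cpm = numeric(0))
}

#' Respiration regularity within a window
#'
#' Applies the regularity criterion: restrict to cycles whose onset falls in
#' the window, extrapolate each cycle to a per-minute rate, and compare the
#' longest and shortest cycles. A rate range below 20 cycles/min is REGULAR;
#' 20 or more is IRREGULAR; fewer than `min_cycles` cycles (default 5) gives
#' UNDETERMINED so that the movement heuristics can take over.
#'
#' @param cycles a data.frame from [detect_breath_cycles()].
#' @param window numeric length-2 `c(start_s, end_s)`, half-open.
#' @param config a [bsa_config()] list.
#' @return A list with `verdict` (`"REGULAR"`, `"IRREGULAR"`,
#'   `"UNDETERMINED"`), `rate_range_cpm` (NA when undetermined), `n_cycles`.
#' @export
breath_regularity <- function(cycles, window, config = bsa_config()) {
  if (length(window) != 2L || !(window[2] > window[1])) {
    stop("window must be a nonempty interval c(start, end)")
  }
  sc <- config$signals
  inw <- cycles$onset_s >= window[1] & cycles$onset_s < window[2]
  r <- cycles$rate_cpm[inw]
  n <- length(r)
  if (n < sc$min_cycles) {
    return(list(verdict = "UNDETERMINED", rate_range_cpm = NA_real_,
                n_cycles = n))
  }
  rng <- max(r) - min(r)
  verdict <- if (rng < sc$regularity_threshold_cpm) "REGULAR" else "IRREGULAR"
  list(verdict = verdict, rate_range_cpm = rng, n_cycles = n)
}

#' Detect movement bursts
#'
#' A burst is a maximal interval where the smoothed rectified envelope of the
#' movement waveform exceeds `median + k * mad` of the whole-recording
#' envelope; bursts separated by less than `merge_gap_s` are merged. Bursts
#' are split into twitches (brief, low amplitude — the small sleep movements)
#' and gross movements: a burst is a twitch iff its duration is at most
#' `twitch_max_duration_s` and its peak amplitude at most `twitch_amp_frac`
#' of the 95th-percentile peak of the longer (gross-candidate) bursts.
#'
#' @param move numeric movement waveform.
#' @param fs sample rate in Hz.
#' @param config a [bsa_config()] list.
#' @return A data.frame with columns `onset_s`, `duration_s`,
#'   `peak_amplitude`, `kind` (`"twitch"` or `"gross"`); zero rows when the
#'   channel is quiet.
#' @export
detect_movement_bursts <- function(move, fs, config = bsa_config()) {
  if (fs <= 0) stop("fs must be positive")
  sc <- config$signals
  env <- abs(move - stats::median(move))
  w <- max(1L, round(sc$envelope_smooth_s * fs))
  if (w > 1L) {
    env <- stats::filter(env, rep(1 / w, w), sides = 2)
    env[is.na(env)] <- 0
    env <- as.numeric(env)
  }
  base <- stats::median(env)
  spread <- stats::mad(env)
  thr <- base + sc$burst_k * max(spread, .Machine$double.eps)
  above <- env > thr
  if (!any(above)) return(.empty_bursts())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(s = starts[r$values], e = ends[r$values])
  # merge segments separated by less than merge_gap_s
  gap <- sc$merge_gap_s * fs
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      if (seg$s[i] - merged$e[nrow(merged)] < gap) {
        merged$e[nrow(merged)] <- seg$e[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  onset <- (merged$s - 1) / fs
  dur <- (merged$e - merged$s + 1) / fs
  peak <- vapply(seq_len(nrow(merged)),
                 function(i) max(env[merged$s[i]:merged$e[i]]), numeric(1))
  keep <- dur >= sc$min_burst_s
  onset <- onset[keep]; dur <- dur[keep]; peak <- peak[keep]
  if (length(onset) == 0L) return(.empty_bursts())
  gross_peaks <- peak[dur > sc$twitch_max_duration_s]
  amp_cut <- if (length(gross_peaks) > 0L) {
    sc$twitch_amp_frac * stats::quantile(gross_peaks, 0.95, names = FALSE)
  } else {
    Inf
  }
  kind <- ifelse(dur <= sc$twitch_max_duration_s & peak <= amp_cut,
                 "twitch", "gross")
  data.frame(onset_s = onset, duration_s = dur, peak_amplitude = peak,
             kind = kind, stringsAsFactors = FALSE)
}

.empty_bursts <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             peak_amplitude = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Fraction of a window covered by movement bursts
#'
#' Movement noise in the respiration signal is information: heavy coverage
#' marks the active states. Returns the fraction of the window covered by
#' the union of burst intervals, always in `[0, 1]`.
#'
#' @param bursts a data.frame from [detect_movement_bursts()].
#' @param window numeric length-2 `c(start_s, end_s)`.
#' @export
movement_noise_fraction <- function(bursts, window) {
  if (length(window) != 2L || !(window[2] > window[1])) {
    stop("window must be a nonempty interval c(start, end)")
  }
  if (nrow(bursts) == 0L) return(0)
  s <- pmax(bursts$onset_s, window[1])
  e <- pmin(bursts$onset_s + bursts$duration_s, window[2])
  keep <- e > s
  if (!any(keep)) return(0)
  iv <- data.frame(s = s[keep], e = e[keep])
  iv <- iv[order(iv$s), ]
  tot <- 0
  cur_s <- iv$s[1]; cur_e <- iv$e[1]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$s[i] <= cur_e) {
        cur_e <- max(cur_e, iv$e[i])
      } else {
        tot <- tot + (cur_e - cur_s)
        cur_s <- iv$s[i]; cur_e <- iv$e[i]
      }
    }
  }
  tot <- tot + (cur_e - cur_s)
  min(1, tot / (window[2] - window[1]))
}

#' Per-epoch feature summary
#'
#' Computes the scalar features one 30-s epoch contributes to classification.
#' Breath cycles overlapping a detected movement burst are discarded before
#' the regularity computation (movement is noise in the respiration signal;
#' its extent is preserved separately as `movement_noise_fraction`).
#'
#' @param channels a [channel_set()].
#' @param epoch_index 0-based epoch index.
#' @param epoch_length_s epoch duration in seconds.
#' @param config a [bsa_config()] list.
#' @param cycles,bursts optional precomputed whole-recording cycle and burst
#'   tables (computed from `channels` when omitted).
#' @return A one-row data.frame with columns `epoch`, `resp_verdict`,
#'   `rate_range_cpm`, `n_cycles`, `burst_count`, `twitch_count`,
#'   `gross_count`, `max_gross_duration_s`, `mean_inter_burst_s`,
#'   `movement_noise_fraction`, `eyes_open_fraction`, `cry_fraction`,
#'   `audio_rms`.
#' @export
epoch_features <- function(channels, epoch_index,
                           epoch_length_s = config$epoch_length_s,
                           config = bsa_config(),
                           cycles = NULL, bursts = NULL) {
  if (!inherits(channels, "channel_set")) stop("expected a channel_set")
  w0 <- epoch_index * epoch_length_s
  w1 <- w0 + epoch_length_s
  if (epoch_index < 0 || w1 > channels$duration_s + 1e-9) {
    stop("epoch ", epoch_index, " lies outside the recording")
  }
  if (is.null(cycles)) {
    cycles <- detect_breath_cycles(channels$resp, channels$fs, config)
  }
  if (is.null(bursts)) {
    bursts <- detect_movement_bursts(channels$move, channels$fs, config)
  }
  # suppress breath cycles overlapping any movement burst
  if (nrow(bursts) > 0L && nrow(cycles) > 0L) {
    be <- bursts$onset_s + bursts$duration_s
    overlapped <- vapply(seq_len(nrow(cycles)), function(i) {
      cs <- cycles$onset_s[i]; ce <- cs + cycles$duration_s[i]
      any(cs < be & ce > bursts$onset_s)
    }, logical(1))
    cycles <- cycles[!overlapped, , drop = FALSE]
  }
  reg <- breath_regularity(cycles, c(w0, w1), config)

  inb <- bursts$onset_s >= w0 & bursts$onset_s < w1
  eb <- bursts[inb, , drop = FALSE]
  burst_count <- nrow(eb)
  twitch_count <- sum(eb$kind == "twitch")
  gross_count <- burst_count - twitch_count
  gross_dur <- eb$duration_s[eb$kind == "gross"]
  max_gross <- if (length(gross_dur) > 0L) max(gross_dur) else 0
  mib <- if (burst_count >= 2L) mean(diff(sort(eb$onset_s))) else NA_real_
  mnf <- movement_noise_fraction(bursts, c(w0, w1))

  sec <- seq.int(floor(w0) + 1L, min(ceiling(w1), length(channels$eyes)))
  ey <- channels$eyes[sec]
  eyes_frac <- if (all(is.na(ey))) NA_real_ else mean(ey, na.rm = TRUE)
  cry_frac <- mean(channels$cry[sec])

  i0 <- floor(w0 * channels$fs) + 1L
  i1 <- min(length(channels$audio_env), ceiling(w1 * channels$fs))
  audio_rms <- sqrt(mean(channels$audio_env[i0:i1]^2))

  data.frame(
    epoch = epoch_index,
    resp_verdict = reg$verdict,
    rate_range_cpm = reg$rate_range_cpm,
    n_cycles = reg$n_cycles,
    burst_count = burst_count,
    twitch_count = twitch_count,
    gross_count = gross_count,
    max_gross_duration_s = max_gross,
    mean_inter_burst_s = mib,
    movement_noise_fraction = mnf,
    eyes_open_fraction = eyes_frac,
    cry_fraction = cry_frac,
    audio_rms = audio_rms,
    stringsAsFactors = FALSE
  )
}

#' Feature table for a whole recording
#'
#' Runs cycle and burst detection once and summarizes every full epoch.
#'
#' @inheritParams epoch_features
#' @return A data.frame with one row per epoch (see [epoch_features()]).
#' @export
recording_features <- function(channels, config = bsa_config()) {
  L <- config$epoch_length_s
  n <- floor(channels$duration_s / L + 1e-9)
  if (n < 1L) stop("recording shorter than one epoch")
  cycles <- detect_breath_cycles(channels$resp, channels$fs, config)
  bursts <- detect_movement_bursts(channels$move, channels$fs, config)
  do.call(rbind, lapply(seq_len(n) - 1L, function(i) {
    epoch_features(channels, i, L, config, cycles = cycles, bursts = bursts)
  }))
}
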