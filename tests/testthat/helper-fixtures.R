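# Shared fixtures built in code.

# behavioral hypnogram from run-length notation, e.g. bh(AS = 10, QS = 3, AS = 10)
bh <- function(...) {
  runs <- c(...)
  hypnogram(rep(names(runs), runs), label_space = "behavioral")
}

ph <- function(labels) hypnogram(labels, label_space = "psg")

# a tiny synthetic channel_set: sinusoidal respiration at base_hz, optional
# movement pulses (data.frame onset_s, duration_s, amplitude), constant
# eyes/cry values; duration in seconds, fs in Hz
toy_channels <- function(duration_s = 60, fs = 16, base_hz = 0.6,
                         pulses = NULL, eyes = 0, cry = 0,
                         audio = 0.01) {
  n <- duration_s * fs
  t <- (seq_len(n) - 1) / fs
  resp <- sin(2 * pi * base_hz * t)
  move <- rnorm(n, 0, 0.01)
  if (!is.null(pulses)) {
    for (i in seq_len(nrow(pulses))) {
      idx <- which(t >= pulses$onset_s[i] &
                   t < pulses$onset_s[i] + pulses$duration_s[i])
      move[idx] <- move[idx] + pulses$amplitude[i]
    }
  }
  nsec <- duration_s
  channel_set(resp, move, rep(audio, n),
              rep(eyes, nsec), rep(cry, nsec), fs)
}

# a random legal-or-not behavioral hypnogram for property tests
random_hypnogram <- function(n) {
  hypnogram(sample(BEHAVIORAL_STATES, n, replace = TRUE),
            label_space = "behavioral")
}

# default features row, overridable field by field; used to exercise the
# classifier without running signal processing
feat_row <- function(resp_verdict = "REGULAR", rate_range_cpm = 5,
                     n_cycles = 15, burst_count = 0, twitch_count = 0,
                     gross_count = 0, max_gross_duration_s = 0,
                     mean_inter_burst_s = NA_real_,
                     movement_noise_fraction = 0,
                     eyes_open_fraction = 0, cry_fraction = 0,
                     audio_rms = 0.01, epoch = 0) {
  data.frame(epoch = epoch, resp_verdict = resp_verdict,
             rate_range_cpm = rate_range_cpm, n_cycles = n_cycles,
             burst_count = burst_count, twitch_count = twitch_count,
             gross_count = gross_count,
             max_gross_duration_s = max_gross_duration_s,
             mean_inter_burst_s = mean_inter_burst_s,
             movement_noise_fraction = movement_noise_fraction,
             eyes_open_fraction = eyes_open_fraction,
             cry_fraction = cry_fraction, audio_rms = audio_rms,
             stringsAsFactors = FALSE)
}

obs <- function(eyes = "no", resp = "yes", gross = "no", voc = "no") {
  list(eyes_open = eyes, respiration_regular = resp,
       gross_movements = gross, vocalization = voc)
}

# independent brute-force kappa oracle: explicit elementwise p_o / p_e sums
kappa_oracle <- function(m) {
  n <- 0; po <- 0
  k <- nrow(m)
  for (i in seq_len(k)) for (j in seq_len(k)) n <- n + m[i, j]
  for (i in seq_len(k)) po <- po + m[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(k)) {
    ri <- 0; ci <- 0
    for (j in seq_len(k)) { ri <- ri + m[i, j]; ci <- ci + m[j, i] }
    pe <- pe + (ri / n) * (ci / n)
  }
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

random_confusion <- function(max_labels = 6, max_n = 200) {
  k <- sample(2:max_labels, 1)
  n <- sample(1:max_n, 1)
  cells <- as.vector(rmultinom(1, n, runif(k * k)))
  matrix(cells, k, k)
}
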