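test_that("observation vector maps features to the four properties", {
  v <- observation_vector(feat_row(eyes_open_fraction = 1,
                                   resp_verdict = "REGULAR"))
  expect_equal(v, obs("yes", "yes", "no", "no"))

  # crying judgment comes from the (video-derived) cry channel, never audio
  v <- observation_vector(feat_row(cry_fraction = 1, audio_rms = 0))
  expect_equal(v$vocalization, "yes")
  v <- observation_vector(feat_row(cry_fraction = 0, audio_rms = 5))
  expect_equal(v$vocalization, "no")

  v <- observation_vector(feat_row(eyes_open_fraction = NA,
                                   resp_verdict = "UNDETERMINED"))
  expect_equal(v$eyes_open, "unknown")
  expect_equal(v$respiration_regular, "unknown")

  # exact 50/50 tie inherits the previous judgment
  f <- feat_row(eyes_open_fraction = 0.5)
  expect_equal(observation_vector(f, prev_eyes = "yes")$eyes_open, "yes")
  expect_equal(observation_vector(f, prev_eyes = "no")$eyes_open, "no")

  v <- observation_vector(feat_row(gross_count = 2))
  expect_equal(v$gross_movements, "yes")
})

test_that("state table lookup matches the Prechtl vectors", {
  expect_equal(classify_vector(obs("no", "yes", "no", "no")), "QS")
  expect_equal(classify_vector(obs("no", "no", "no", "no")), "AS")
  expect_equal(classify_vector(obs("no", "no", "yes", "no")), "AS")
  expect_equal(classify_vector(obs("yes", "yes", "no", "no")), "QA")
  expect_equal(classify_vector(obs("yes", "no", "yes", "no")), "AA")
  expect_equal(classify_vector(obs("yes", "no", "no", "no")), "AA")
  # crying dominates regardless of eyes
  expect_equal(classify_vector(obs("yes", "no", "yes", "yes")), "V")
  expect_equal(classify_vector(obs("no", "yes", "no", "yes")), "V")
  # unknowns block the lookup
  expect_equal(classify_vector(obs("no", "unknown", "yes", "no")),
               "UNDECIDED")
  expect_equal(classify_vector(obs("unknown", "yes", "no", "no")),
               "UNDECIDED")
})

test_that("lookup is total and deterministic over all fully-known vectors", {
  grid <- expand.grid(eyes = c("yes", "no"), resp = c("yes", "no"),
                      gross = c("yes", "no"), voc = c("yes", "no"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 16)
  out <- character(16)
  for (i in seq_len(16)) {
    v <- obs(grid$eyes[i], grid$resp[i], grid$gross[i], grid$voc[i])
    out[i] <- classify_vector(v)
    expect_identical(classify_vector(v), out[i])  # deterministic
    expect_true(out[i] %in% c(BEHAVIORAL_STATES, "UNDECIDED"))
    if (grid$voc[i] == "yes") expect_equal(out[i], "V")
  }
  expect_true(all(c("QS", "AS", "QA", "AA", "V") %in% out))
})

test_that("movement fallback scores the wake/sleep contrasts", {
  # twitches plus sparse movement -> sleep
  f <- feat_row(twitch_count = 2, burst_count = 2, mean_inter_burst_s = 12)
  expect_equal(movement_fallback(f), "sleep-leaning")
  # frequent closely-spaced bursts with sustained gross movement -> wake
  f <- feat_row(burst_count = 8, gross_count = 8, mean_inter_burst_s = 5,
                max_gross_duration_s = 6)
  expect_equal(movement_fallback(f), "wake-leaning")
  # stillness -> sleep (interval criterion)
  expect_equal(movement_fallback(feat_row(burst_count = 0)),
               "sleep-leaning")
  # one sleep cue against one wake cue -> neutral
  f <- feat_row(twitch_count = 1, burst_count = 5, gross_count = 4,
                mean_inter_burst_s = 4)
  expect_equal(movement_fallback(f), "neutral")
})

test_that("epoch resolution cascade is total and respects precedence", {
  cfg <- bsa_config()
  # decided vector ignores the fallback
  d <- resolve_epoch(obs("no", "yes", "no", "no"), feat_row(),
                     "wake-leaning", prev_state = NULL, config = cfg)
  expect_equal(d$state, "QS")
  expect_equal(d$rationale, "vector")

  # sleep-leaning with unknown respiration and heavy movement noise -> AS
  f <- feat_row(resp_verdict = "UNDETERMINED", eyes_open_fraction = NA,
                movement_noise_fraction = 0.6, twitch_count = 1)
  d <- resolve_epoch(observation_vector(f, cfg), f, "sleep-leaning",
                     NULL, cfg)
  expect_equal(d$state, "AS")
  expect_equal(d$rationale, "movement-fallback")

  # sleep-leaning with quiet signal -> QS
  f <- feat_row(resp_verdict = "UNDETERMINED", eyes_open_fraction = NA,
                movement_noise_fraction = 0)
  d <- resolve_epoch(observation_vector(f, cfg), f, "sleep-leaning",
                     NULL, cfg)
  expect_equal(d$state, "QS")

  # wake-leaning splits on gross movement
  f <- feat_row(resp_verdict = "UNDETERMINED", eyes_open_fraction = NA,
                gross_count = 2)
  d <- resolve_epoch(observation_vector(f, cfg), f, "wake-leaning", NULL, cfg)
  expect_equal(d$state, "AA")
  f <- feat_row(resp_verdict = "UNDETERMINED", eyes_open_fraction = NA)
  d <- resolve_epoch(observation_vector(f, cfg), f, "wake-leaning", NULL, cfg)
  expect_equal(d$state, "QA")

  # neutral carries the previous state; first epoch defaults to AS
  v <- obs("unknown", "unknown")
  expect_equal(resolve_epoch(v, feat_row(), "neutral", "QS", cfg)$state, "QS")
  expect_equal(resolve_epoch(v, feat_row(), "neutral", NULL, cfg)$state, "AS")
  expect_equal(resolve_epoch(v, feat_row(), "neutral", "QS", cfg)$rationale,
               "carry-forward")

  # the cascade never returns UNDECIDED
  set.seed(8)
  for (i in 1:40) {
    f <- feat_row(
      resp_verdict = sample(c("REGULAR", "IRREGULAR", "UNDETERMINED"), 1),
      eyes_open_fraction = sample(c(NA, 0, 0.5, 1), 1),
      twitch_count = sample(0:3, 1),
      burst_count = sample(0:8, 1),
      gross_count = 0,
      mean_inter_burst_s = sample(c(NA, 3, 40), 1),
      movement_noise_fraction = runif(1),
      cry_fraction = sample(c(0, 1), 1)
    )
    f$gross_count <- max(0, f$burst_count - f$twitch_count)
    v <- observation_vector(f)
    d <- resolve_epoch(v, f, movement_fallback(f),
                       sample(c(list(NULL), as.list(BEHAVIORAL_STATES)), 1)[[1]])
    expect_true(d$state %in% BEHAVIORAL_STATES)
  }
})

test_that("per-second majority inside an epoch decides the eyes input", {
  set.seed(9)
  ch <- toy_channels(duration_s = 30, eyes = 0)
  # 20 s closed + 10 s open -> eyes closed for the epoch
  ch$eyes <- c(rep(0, 20), rep(1, 10))
  out <- classify_recording(ch)
  expect_equal(out$audit$eyes[1], "no")
  # 25 s open -> eyes open, regular respiration, no movement -> QA
  ch$eyes <- c(rep(1, 25), rep(0, 5))
  out <- classify_recording(ch)
  expect_equal(out$audit$eyes[1], "yes")
  expect_equal(out$hypnogram$labels[1], "QA")
})

test_that("classification of a recording is deterministic", {
  sim <- simulate_nap(sim_config(seed = 13, duration_min = 6))
  a <- classify_recording(sim$channels)
  b <- classify_recording(sim$channels)
  expect_identical(a$hypnogram$labels, b$hypnogram$labels)
  expect_identical(a$audit, b$audit)
  expect_error(classify_recording(toy_channels(duration_s = 10)),
               "shorter than one epoch")
})

test_that("classifier recovers the simulated truth before smoothing", {
  sim <- simulate_nap(sim_config(seed = 21))
  out <- classify_recording(sim$channels)
  acc <- mean(out$hypnogram$labels == sim$truth$labels)
  expect_gte(acc, 0.80)
})
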