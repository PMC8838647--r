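test_that("simulation is deterministic given the seed", {
  a <- simulate_nap(sim_config(seed = 5, duration_min = 6))
  b <- simulate_nap(sim_config(seed = 5, duration_min = 6))
  expect_identical(a$channels$resp, b$channels$resp)
  expect_identical(a$channels$move, b$channels$move)
  expect_identical(a$channels$eyes, b$channels$eyes)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- simulate_nap(sim_config(seed = 6, duration_min = 6))
  expect_false(identical(a$channels$resp, c$channels$resp))
})

test_that("a one-minute nap yields two epochs", {
  sim <- simulate_nap(sim_config(seed = 1, duration_min = 1))
  expect_equal(n_epochs(sim$truth), 2)
  expect_equal(length(sim$channels$resp), 2 * 30 * sim$channels$fs)
})

test_that("sampled state sequences follow the legal transition graph", {
  for (s in 1:25) {
    set.seed(s)
    h <- sample_state_sequence(sim_config())$hypnogram
    expect_equal(nrow(validate_hypnogram(h)), 0)
    # V borders only AA
    r <- runs_of(h)
    iv <- which(r$state == "V")
    for (i in iv) {
      if (i > 1) expect_equal(r$state[i - 1], "AA")
      if (i < nrow(r)) expect_equal(r$state[i + 1], "AA")
    }
  }
})

test_that("invalid simulator configs are rejected", {
  cfg <- sim_config(duration_min = -5)
  expect_error(sample_state_sequence(cfg), "positive")
  cfg <- sim_config(transitions = list(QS = c(AA = 1)))
  expect_error(sample_state_sequence(cfg), "forbidden")
  cfg <- sim_config(eyes = list(unknown_prob = 2))
  expect_error(simulate_nap(cfg), "probabilities")
})

test_that("respiration is regular in quiet and irregular in active states", {
  cfg <- sim_config(seed = 2)
  truth <- hypnogram(c(rep("QS", 4), rep("AS", 4)))
  set.seed(2)
  r <- synth_respiration(truth, cfg)
  expect_equal(r$truth_regularity,
               c(rep("REGULAR", 4), rep("IRREGULAR", 4)))
  cyc <- detect_breath_cycles(r$wave, cfg$fs)
  for (e in 0:3) {
    expect_equal(breath_regularity(cyc, c(e * 30, (e + 1) * 30))$verdict,
                 "REGULAR")
  }
  for (e in 4:7) {
    expect_equal(breath_regularity(cyc, c(e * 30, (e + 1) * 30))$verdict,
                 "IRREGULAR")
  }
})

test_that("an apneic pause shows up as a long breath cycle", {
  cfg <- sim_config(seed = 3, resp = list(apnea_per_min = 6))
  truth <- hypnogram(rep("AS", 4))
  set.seed(3)
  r <- synth_respiration(truth, cfg)
  expect_gt(nrow(r$apneas), 0)
  expect_true(all(r$apneas$duration_s >= 3 - 1 / cfg$fs &
                  r$apneas$duration_s <= 8 + 1 / cfg$fs))
  cyc <- detect_breath_cycles(r$wave, cfg$fs)
  expect_gt(max(cyc$duration_s), 3)
})

test_that("zero-jitter regular respiration has a near-zero rate range", {
  cfg <- sim_config(resp = list(regular_jitter_cpm = 0, amp_jitter = 0,
                                apnea_per_min = 0))
  truth <- hypnogram(rep("QS", 2))
  set.seed(4)
  r <- synth_respiration(truth, cfg)
  cyc <- detect_breath_cycles(r$wave, cfg$fs)
  rng <- breath_regularity(cyc, c(0, 60))$rate_range_cpm
  expect_lt(rng, 3)  # only sampling quantization remains
})

test_that("movement rates are state-conditional", {
  cfg <- sim_config()
  # quiet sleep: expected 3 gross bursts in 30 min at 0.1/min;
  # observed count within the Poisson 99% interval
  truth_qs <- hypnogram(rep("QS", 60))
  set.seed(10)
  m <- synth_movement(truth_qs, cfg)
  ngross <- sum(m$bursts$kind == "gross")
  expect_true(ngross >= qpois(0.005, 3) && ngross <= qpois(0.995, 3))

  # zero rates -> flat channel (baseline noise only), no bursts
  cfg0 <- sim_config(movement = list(
    gross_per_min = c(QS = 0, AS = 0, QA = 0, AA = 0, V = 0),
    twitch_per_min = c(QS = 0, AS = 0, QA = 0, AA = 0, V = 0)))
  set.seed(10)
  m0 <- synth_movement(truth_qs, cfg0)
  expect_equal(nrow(m0$bursts), 0)
  expect_lt(max(abs(m0$wave)), 0.1)

  # every AA epoch carries at least one sustained (>= 5 s) burst
  truth_aa <- hypnogram(rep("AA", 10))
  set.seed(11)
  m <- synth_movement(truth_aa, cfg)
  for (e in 0:9) {
    inb <- m$bursts$onset_s >= e * 30 & m$bursts$onset_s < (e + 1) * 30
    expect_true(any(m$bursts$duration_s[inb] >= 5))
  }
})

test_that("eyes, cry and audio channels encode the state", {
  cfg <- sim_config()
  truth <- hypnogram(c(rep("AA", 4), rep("V", 4), rep("AS", 4)))
  set.seed(12)
  e <- synth_eyes_audio_cry(truth, cfg)
  # cry exactly covers the V bout
  expect_true(all(e$cry[121:240] == 1))
  expect_true(all(e$cry[c(1:120, 241:360)] == 0))
  # eyes mostly open in AA, mostly closed in AS
  expect_gt(mean(e$eyes[1:120], na.rm = TRUE), 0.6)
  expect_lt(mean(e$eyes[241:360], na.rm = TRUE), 0.3)

  # all-unknown masking
  cfg2 <- sim_config(eyes = list(unknown_prob = 1))
  set.seed(12)
  e2 <- synth_eyes_audio_cry(truth, cfg2)
  expect_true(all(is.na(e2$eyes)))
})

test_that("elevated sleep sounds without crying never classify as V", {
  cfg <- sim_config(seed = 31, audio = list(sleep_sound_epoch_frac = 1,
                                            sleep_sound_level = 1))
  sim <- simulate_nap(cfg)
  out <- classify_recording(sim$channels)
  as_epochs <- sim$truth$labels == "AS"
  expect_false(any(out$hypnogram$labels[as_epochs] == "V"))
  # and loud AS epochs really are loud
  expect_gt(mean(out$features$audio_rms[as_epochs]), 0.5)
})

test_that("sleep composition is balanced between QS and AS", {
  fr <- sapply(1:30, function(s) {
    set.seed(s)
    h <- sample_state_sequence(sim_config())$hypnogram
    sleep <- h$labels %in% c("QS", "AS")
    sum(h$labels == "QS") / sum(sleep)
  })
  expect_gt(mean(fr), 0.3)
  expect_lt(mean(fr), 0.7)
})
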