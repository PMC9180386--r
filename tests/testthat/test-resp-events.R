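# Amplitude envelopes, baselines, and apnea/hypopnea scoring rules.

test_that("the envelope has 60 points per complete epoch and drops tail windows", {
  fs <- 200
  x <- sin(2 * pi * (0:(fs * 90 - 1)) / (fs * 4))
  env <- amplitude_envelope(x, fs)
  expect_equal(sum(env$epoch_index == 0), 60)
  expect_equal(sum(env$epoch_index == 1), 60)
  # last epoch loses the windows that would cross the record end
  expect_equal(sum(env$epoch_index == 2), 60 - 9)
  expect_equal(nrow(env), (90 - 5) / 0.5 + 1)
})

test_that("envelope values follow the max-minus-min definition", {
  fs <- 200
  expect_true(all(amplitude_envelope(rep(3, fs * 30), fs)$value == 0))
  # a full 4-s breathing cycle inside every 5-s window: amplitude 2
  t <- (0:(fs * 60 - 1)) / fs
  env <- amplitude_envelope(sin(2 * pi * t / 4), fs)
  expect_equal(env$value, rep(2, nrow(env)), tolerance = 1e-3)
  expect_error(amplitude_envelope(numeric(10), fs), "shorter")
})

test_that("envelope equals brute-force window extrema on arbitrary signals", {
  set.seed(41)
  fs <- 40 # keeps the brute force cheap; window/step still 5 s / 0.5 s
  x <- rnorm(fs * 95) + sin((0:(fs * 95 - 1)) / 7)
  env <- amplitude_envelope(x, fs)
  brute <- vapply(seq_len(nrow(env)), function(k) {
    seg <- x[((k - 1) * fs * 0.5 + 1):((k - 1) * fs * 0.5 + fs * 5)]
    max(seg) - min(seg)
  }, numeric(1))
  expect_equal(env$value, brute)
  # and with a step that does not divide the window (generic path)
  env2 <- amplitude_envelope(x, fs, window_sec = 5, step_sec = 0.75)
  brute2 <- vapply(seq_len(nrow(env2)), function(k) {
    i0 <- (k - 1) * fs * 0.75
    seg <- x[(i0 + 1):(i0 + fs * 5)]
    max(seg) - min(seg)
  }, numeric(1))
  expect_equal(env2$value, brute2)
})

test_that("baselines are the previous epoch's mean envelope, undefined where unscorable", {
  env <- make_epoch_env(c(2, 2, 4, 2))
  grid <- make_grid(4)
  bl <- epoch_baselines(env, grid)
  expect_equal(bl$baseline, c(NA, 2, 2, 4))
  expect_equal(bl$defined, c(FALSE, TRUE, TRUE, TRUE))
  # unusable predecessor leaves the epoch unscored
  grid2 <- make_grid(4, usable = c(TRUE, FALSE, TRUE, TRUE))
  bl2 <- epoch_baselines(env, grid2)
  expect_equal(bl2$defined, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("apnea detection requires ratio < 0.1 sustained for at least 10 s", {
  grid <- make_grid(2)
  base <- rep(2, 60)
  # 12 s (24 points) at ratio 0.05 inside epoch 1
  v <- c(base, rep(2, 10), rep(0.1, 24), rep(2, 26))
  ev <- detect_apneas(make_env(v), epoch_baselines(make_env(v), grid), grid)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_sec, 12)
  expect_equal(ev$epoch_index, 1L)
  expect_equal(ev$onset_sec, 35) # 60 + 10 points into epoch 1
  expect_equal(ev$min_ratio, 0.05)
  # 8 s at ratio 0.05: below the duration floor
  v8 <- c(base, rep(2, 10), rep(0.1, 16), rep(2, 34))
  expect_equal(nrow(detect_apneas(make_env(v8),
                                  epoch_baselines(make_env(v8), grid), grid)), 0)
  # ratio 0.5 throughout: partial reduction is never an apnea
  v5 <- c(base, rep(1, 60))
  expect_equal(nrow(detect_apneas(make_env(v5),
                                  epoch_baselines(make_env(v5), grid), grid)), 0)
})

test_that("events are confined to scorable epochs", {
  # reduction in epoch 0: no baseline, no event
  v <- c(rep(0.1, 30), rep(2, 30), rep(2, 60))
  grid <- make_grid(2)
  expect_equal(nrow(detect_apneas(make_env(v),
                                  epoch_baselines(make_env(v), grid), grid)), 0)
  # same reduction in epoch 1 but epoch 1 unusable: no event
  v2 <- c(rep(2, 60), rep(0.1, 24), rep(2, 36))
  grid2 <- make_grid(2, usable = c(TRUE, FALSE))
  expect_equal(nrow(detect_apneas(make_env(v2),
                                  epoch_baselines(make_env(v2), grid2), grid2)), 0)
})

test_that("central apneas need BOTH effort envelopes suppressed for 10 s", {
  grid <- make_grid(2)
  ev <- tibble::tibble(onset_sec = 35, duration_sec = 12, epoch_index = 1L,
                       min_ratio = 0.05)
  eff_high <- make_epoch_env(c(2, 2))
  # both efforts at 10% of the epoch max, overlapping the event
  low_epoch <- c(rep(2, 8), rep(0.2, 30), rep(2, 22))
  eff_low <- make_env(c(rep(2, 60), low_epoch))
  out <- classify_apnea(ev, eff_low, eff_low, grid)
  expect_equal(out$type, "central_apnea")
  # efforts maintained at 80%: obstructive
  eff80 <- make_env(c(rep(2, 60), c(rep(2, 8), rep(1.6, 30), rep(2, 22))))
  expect_equal(classify_apnea(ev, eff80, eff80, grid)$type, "obstructive_apnea")
  # one channel suppressed, the other maintained: obstructive
  expect_equal(classify_apnea(ev, eff_low, eff_high, grid)$type, "obstructive_apnea")
  # suppression too short (8 s)
  short_low <- make_env(c(rep(2, 60), c(rep(2, 10), rep(0.2, 16), rep(2, 34))))
  expect_equal(classify_apnea(ev, short_low, short_low, grid)$type, "obstructive_apnea")
  # missing effort channel: conservative obstructive with a warning
  expect_warning(out2 <- classify_apnea(ev, NULL, NULL, grid), "missing")
  expect_equal(out2$type, "obstructive_apnea")
})

test_that("epoch desaturation is the epoch's SpO2 range, NA when unusable", {
  fs <- 200
  grid <- make_grid(2, fs)
  spo2 <- rep(97, fs * 60)
  expect_equal(epoch_desaturation(spo2, fs, grid), c(0, 0))
  # dip 97 -> 93 -> 97 inside epoch 1
  spo2[fs * 40 + seq_len(fs * 5)] <- 93
  expect_equal(epoch_desaturation(spo2, fs, grid), c(0, 4))
  grid2 <- make_grid(2, fs, usable = c(TRUE, FALSE))
  expect_equal(epoch_desaturation(spo2, fs, grid2), c(0, NA))
})

test_that("hypopneas need the ratio band AND a desaturation of at least 3 points", {
  fs <- 200
  grid <- make_grid(2, fs)
  base <- rep(2, 60)
  v <- c(base, c(rep(2, 10), rep(1, 24), rep(2, 26))) # ratio 0.5 for 12 s
  env <- make_env(v)
  bl <- epoch_baselines(env, grid)
  dip <- function(points) {
    s <- rep(97, fs * 60)
    s[fs * 40 + seq_len(fs * 5)] <- 97 - points
    s
  }
  ev <- detect_hypopneas(env, bl, dip(4), fs, grid)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "hypopnea")
  expect_equal(ev$duration_sec, 12)
  expect_equal(ev$desat_points, 4)
  # a 2-point desaturation does not qualify
  expect_equal(nrow(detect_hypopneas(env, bl, dip(2), fs, grid)), 0)
  # exactly 3 points qualifies (>= rule)
  expect_equal(nrow(detect_hypopneas(env, bl, dip(3), fs, grid)), 1)
  # a deep (apnea-range) reduction is never a hypopnea: disjoint bands
  va <- c(base, c(rep(2, 10), rep(0.1, 24), rep(2, 26)))
  enva <- make_env(va)
  expect_equal(nrow(detect_hypopneas(enva, epoch_baselines(enva, grid),
                                     dip(4), fs, grid)), 0)
})

test_that("every sustained reduction maps to at most one event kind", {
  set.seed(43)
  grid <- make_grid(2)
  for (r in c(0.05, 0.09, 0.11, 0.3, 0.7)) {
    v <- c(rep(2, 60), c(rep(2, 10), rep(2 * r, 30), rep(2, 20)))
    env <- make_env(v)
    bl <- epoch_baselines(env, grid)
    n_apnea <- nrow(detect_apneas(env, bl, grid))
    spo2 <- rep(97, 200 * 60); spo2[200 * 40 + 1:1000] <- 93
    n_hyp <- nrow(detect_hypopneas(env, bl, spo2, 200, grid))
    expect_equal(n_apnea + n_hyp, 1L)
    expect_equal(n_apnea, as.integer(r < 0.1))
  }
})

test_that("detections are invariant to global amplitude scaling of the flow", {
  ev <- synth_events(kind = c("obstructive_apnea", "hypopnea"),
                     epoch_index = c(3, 7))
  sim <- generate_psg(synth_spec(duration_sec = 600, events = ev,
                                 noise_sd = list(eeg = 1, emg = 0.3, flow = 0,
                                                 effort = 0, spo2 = 0.05),
                                 seed = 44))
  rec2 <- sim$recording
  rec2$channels$RF2 <- 37.5 * rec2$channels$RF2
  rec2$adc_limits$RF2 <- 37.5 * rec2$adc_limits$RF2
  s1 <- score_record(sim$recording)
  s2 <- score_record(rec2)
  expect_equal(s1$events$type, s2$events$type)
  expect_equal(s1$events$onset_sec, s2$events$onset_sec)
  expect_equal(s1$events$duration_sec, s2$events$duration_sec)
})

test_that("score_record recovers injected events with exact kinds and clean epochs", {
  ev <- synth_events(
    kind = c("obstructive_apnea", "central_apnea", "hypopnea",
             "obstructive_apnea", "central_apnea", "hypopnea",
             "obstructive_apnea"),
    epoch_index = c(3, 6, 9, 12, 15, 18, 21)
  )
  sim <- generate_psg(synth_spec(duration_sec = 900, events = ev, seed = 45))
  sc <- score_record(sim$recording)
  expect_equal(nrow(sc$events), 7)
  got <- sc$events[order(sc$events$epoch_index), ]
  expect_equal(got$epoch_index, ev$epoch_index)
  expect_equal(got$type, ev$kind)
  # durations are multiples of 0.5 s and >= 10 s
  expect_true(all(abs(got$duration_sec * 2 - round(got$duration_sec * 2)) < 1e-9))
  expect_true(all(got$duration_sec >= 10))
  # per-epoch flags match the event list
  expect_equal(which(sc$epoch_flags$obstructive_apnea == 1) - 1L, c(3L, 12L, 21L))
  expect_equal(which(sc$epoch_flags$central_apnea == 1) - 1L, c(6L, 15L))
  expect_equal(which(sc$epoch_flags$hypopnea == 1) - 1L, c(9L, 18L))
})

test_that("an event-free record yields an empty event list", {
  sim <- generate_psg(synth_spec(duration_sec = 600, seed = 46))
  sc <- score_record(sim$recording)
  expect_equal(nrow(sc$events), 0)
  expect_true(all(sc$epoch_flags$obstructive_apnea == 0))
})

test_that("events in epoch 0 or artifact epochs are not scored", {
  ev0 <- synth_events(kind = "obstructive_apnea", epoch_index = 0)
  expect_warning(spec0 <- synth_spec(duration_sec = 600, events = ev0, seed = 47),
                 "epoch 0")
  sim0 <- generate_psg(spec0, self_check = FALSE)
  expect_equal(nrow(score_record(sim0$recording)$events), 0)

  ev_art <- synth_events(kind = "obstructive_apnea", epoch_index = 5)
  sim_art <- generate_psg(synth_spec(duration_sec = 600, events = ev_art,
                                     artifact_epochs = 5, seed = 48),
                          self_check = FALSE)
  sc <- score_record(sim_art$recording)
  expect_equal(nrow(sc$events), 0)
  expect_false(sc$grid$usable[6])
})

test_that("missing respiratory channels error naming the role", {
  sim <- generate_psg(synth_spec(duration_sec = 600, seed = 49))
  rec <- sim$recording
  rec$channels$RF2 <- NULL
  rec$roles <- rec$roles[names(rec$roles) != "RF2"]
  expect_error(score_record(rec), "flow_pressure")
})
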