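# Band power, threshold classification, ROC/FPT calibration, regression,
# and the nine-combination search.

test_that("epoch band power accumulates in-band FFT magnitude", {
  fs <- 200
  expect_equal(epoch_band_power(numeric(6000), fs, c(8, 13)), 0)
  t <- (0:5999) / fs
  x10 <- sin(2 * pi * 10 * t) # 10 Hz sits exactly on a bin (1/30 Hz spacing)
  inband <- epoch_band_power(x10, fs, c(8, 13))
  total <- sum(Mod(stats::fft(x10))[1:3001])
  expect_gt(inband / total, 0.99)
  # an out-of-band tone, pre-filtered, contributes almost nothing
  # (interior epoch of a longer signal, clear of filter edge transients)
  b <- design_bandpass(c(8, 13), fs)
  tl <- (0:(fs * 90 - 1)) / fs
  x20 <- apply_filter(sin(2 * pi * 20 * tl), b)[6001:12000]
  expect_lt(epoch_band_power(x20, fs, c(8, 13)) / inband, 0.01)
  expect_error(epoch_band_power(numeric(100), fs, c(8, 13)), "samples")
})

test_that("band_power_series equals per-epoch application of epoch_band_power", {
  set.seed(9)
  fs <- 200
  x <- rnorm(fs * 90)
  bp <- band_power_series(x, fs, c(8, 13))
  expect_equal(bp$epoch_index, 0:2)
  for (i in 0:2) {
    block <- x[(i * 6000 + 1):((i + 1) * 6000)]
    expect_equal(bp$power[i + 1], epoch_band_power(block, fs, c(8, 13)))
  }
})

test_that("threshold classification is strict: sleep only below the threshold", {
  expect_equal(threshold_classify(c(1, 2), 10), c(1L, 1L))
  expect_equal(threshold_classify(c(3, 3), 3), c(0L, 0L)) # equality -> awake
  expect_equal(threshold_classify(c(5, 1, 4), 3), c(0L, 1L, 0L))
})

test_that("raising the threshold never flips an epoch from sleep to awake", {
  set.seed(10)
  powers <- runif(200, 0, 100)
  ths <- sort(runif(20, 0, 100))
  prev <- threshold_classify(powers, ths[1])
  for (th in ths[-1]) {
    cur <- threshold_classify(powers, th)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("ROC scan separates clusters perfectly and ties break to the smallest threshold", {
  powers <- c(10, 11, 12, 1, 2, 3) # awake high, sleep low
  expert <- c(0, 0, 0, 1, 1, 1)
  scan <- roc_scan(powers, expert)
  expect_equal(scan$auc, 1.0)
  expect_gt(scan$rot, 3); expect_lt(scan$rot, 10)
  # exhaustive case: powers 1..4, expert sleep on the two lowest;
  # J is maximized at any threshold in (2, 3]; smallest scanned wins
  scan2 <- roc_scan(c(1, 2, 3, 4), c(1, 1, 0, 0), n_thresholds = 100)
  grid <- seq(1, 4, length.out = 100)
  expect_equal(scan2$rot, min(grid[grid > 2]))
  expect_error(roc_scan(c(1, 2), c(1, 1)), "awake")
  expect_error(roc_scan(c(1, 2), c(0, 0)), "sleep")
})

test_that("AUC is ~0.5 for label-independent powers and invariant to monotone transforms", {
  set.seed(11)
  powers <- runif(300)
  expert <- rep(c(0L, 1L), 150)
  aucs <- replicate(200, roc_scan(powers, sample(expert))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # strictly increasing transform leaves AUC unchanged
  a1 <- roc_scan(powers, expert)$auc
  a2 <- roc_scan(exp(3 * powers) + 5, expert)$auc
  expect_equal(a1, a2, tolerance = 0.01)
})

test_that("FPT keeps false positives strictly below the cap by construction", {
  set.seed(12)
  # overlapping awake/sleep power distributions
  expert <- c(rep(0L, 120), rep(1L, 300))
  powers <- c(rnorm(120, 10, 3), rnorm(300, 4, 3))
  sel <- select_fpt(powers, expert, fp_rate = 0.10)
  expect_lt(sel$fp, 0.10 * 120)
  fp_observed <- sum(threshold_classify(powers, sel$fpt)[expert == 0])
  expect_equal(fp_observed, sel$fp)
  # with 10 awake epochs the strict cap (< 1) forces zero false positives
  expert10 <- c(rep(0L, 10), rep(1L, 30))
  powers10 <- c(rnorm(10, 10, 3), rnorm(30, 4, 3))
  sel10 <- select_fpt(powers10, expert10)
  expect_equal(sel10$fp, 0)
  # perfectly separated: FPT admits no false positives
  selp <- select_fpt(c(10, 11, 12, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(selp$fp, 0)
  expect_gt(selp$fpt, 3)
})

test_that("FPT falls back to the minimum threshold with a warning when the cap is unreachable", {
  powers <- c(1, 2, 10, 11, 12, 13)
  expert <- c(0, 0, 1, 1, 1, 1)
  # strict classification means the minimum threshold always has FP = 0, so
  # any positive cap is satisfiable there; a zero cap is not
  sel <- select_fpt(powers, expert, fp_rate = 0.10)
  expect_gte(sel$fpt, min(powers))
  expect_lt(sel$fp, 0.10 * 2)
  expect_warning(sel0 <- select_fpt(powers, expert, fp_rate = 0), "cap")
  expect_equal(sel0$fpt, min(powers))
})

test_that("the pooled regression recovers an injected linear relation", {
  pts <- synth_threshold_points(n_records = 20, n_channels = 6,
                                slope = 0.8, intercept = 0.05,
                                noise_sd = 0.02, seed = 21)
  fit <- fit_fpt_regression(pts, "eeg")
  expect_lt(abs(fit$slope - 0.8), 0.05)
  expect_gt(fit$r2, 0.7)
  # collinear points give r2 = 1
  col <- tibble::tibble(rot_norm = c(0.1, 0.2, 0.3, 0.4),
                        fpt_norm = 0.5 * c(0.1, 0.2, 0.3, 0.4) + 0.1)
  expect_equal(fit_fpt_regression(col, "emg")$r2, 1.0)
  expect_error(fit_fpt_regression(col[1:2, ], "emg"), "3 points")
})

test_that("the EEG cutoff drops high normalized ROTs before fitting", {
  set.seed(22)
  n <- 100
  rot <- c(runif(85, 0.05, 0.6), runif(15, 0.62, 0.95))
  pts <- tibble::tibble(rot_norm = rot,
                        fpt_norm = pmin(1, 0.8 * rot + 0.05 + rnorm(n, 0, 0.02)))
  fit <- fit_fpt_regression(pts, "eeg")
  expect_equal(fit$n_used, 85)
  expect_equal(fit$frac_retained, 0.85)
  # EMG applies no cutoff
  fit_emg <- fit_fpt_regression(pts, "emg")
  expect_equal(fit_emg$n_used, 100)
})

test_that("predict_fpt applies the regression on the normalized scale and clips", {
  ident <- list(slope = 1, intercept = 0)
  expect_equal(predict_fpt(42, 100, ident), 42)
  reg <- list(slope = 0.8, intercept = 0.05)
  expect_equal(predict_fpt(50, 100, reg), 45) # 0.8*0.5 + 0.05 = 0.45
  high <- list(slope = 2, intercept = 0.5)
  expect_equal(predict_fpt(90, 100, high), 100) # clipped to power_max
})

test_that("OR combination is identity on one series and unions sleep epochs", {
  expect_equal(combine_or(list(c(0L, 1L, 0L))), c(0L, 1L, 0L))
  expect_equal(combine_or(list(c(0, 0, 1), c(0, 1, 0))), c(0L, 1L, 1L))
  all_awake <- replicate(8, rep(0L, 5), simplify = FALSE)
  expect_equal(combine_or(all_awake), rep(0L, 5))
  expect_error(combine_or(list()), "non-empty")
})

test_that("OR combination is commutative, associative and idempotent", {
  set.seed(23)
  a <- rbinom(50, 1, 0.3); b <- rbinom(50, 1, 0.3); c <- rbinom(50, 1, 0.3)
  expect_equal(combine_or(list(a, b)), combine_or(list(b, a)))
  expect_equal(combine_or(list(combine_or(list(a, b)), c)),
               combine_or(list(a, combine_or(list(b, c)))))
  expect_equal(combine_or(list(a, a)), as.integer(a))
})

test_that("the combination search evaluates the nine sets and breaks ties in order", {
  roles <- c(O1 = "eeg_occipital", O2 = "eeg_occipital",
             F3 = "eeg_frontal", F4 = "eeg_frontal",
             C3 = "eeg_central", C4 = "eeg_central",
             EMG1 = "emg_chin", EMG2 = "emg_chin")
  combos <- staging_combinations(roles)
  expect_equal(names(combos), c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix"))
  expect_setequal(combos$i, c("O1", "O2", "F3", "F4", "C3", "C4"))
  expect_setequal(combos$iv, c("O1", "O2", "EMG1", "EMG2"))
  expect_equal(length(combos$iii), 8)

  set.seed(24)
  expert <- rbinom(200, 1, 0.7)
  # all channels perfect: every combination scores 1; tie-break -> (i)
  perfect <- stats::setNames(replicate(8, expert, simplify = FALSE), names(roles))
  res <- best_combination(perfect, expert, roles)
  expect_equal(res$combination_id, "i")
  expect_equal(res$success_rate, 1.0)

  # occipital channels perfect, everything else uninformative:
  # (iv) carries the fewest noisy channels in the OR and wins
  noisy <- lapply(seq_len(8), function(i) rbinom(200, 1, 0.5))
  names(noisy) <- names(roles)
  noisy$O1 <- expert; noisy$O2 <- expert
  res2 <- best_combination(noisy, expert, roles)
  expect_equal(res2$combination_id, "iv")
  expect_error(best_combination(noisy[-1], expert, roles), "O1")
})

test_that("record calibration returns 8 channel thresholds and a winning combination", {
  sim <- generate_psg(synth_spec(duration_sec = 900, seed = 31))
  cal <- calibrate_record(sim$recording, sim$hypnogram)
  expect_s3_class(cal, "psg_calibration")
  expect_equal(nrow(cal$thresholds), 8)
  expect_true(all(cal$thresholds$fp_at_fpt <
                    0.10 * sum(binarize_stages(sim$hypnogram) == 0)))
  expect_true(cal$combination_id %in% names(staging_combinations(sim$recording$roles)))
  expect_true(all(cal$thresholds$auc >= 0 & cal$thresholds$auc <= 1))
  g <- glance(cal)
  expect_equal(g$n_channels, 8)
  expect_equal(nrow(tidy(cal)), 8)
})

test_that("staging with a pooled regression reproduces the transfer path", {
  sim <- generate_psg(synth_spec(duration_sec = 900, seed = 32))
  reg <- list(
    eeg = fit_fpt_regression(synth_threshold_points(seed = 1), "eeg"),
    emg = fit_fpt_regression(synth_threshold_points(seed = 2, n_channels = 2), "emg")
  )
  cal <- calibrate_record(sim$recording, sim$hypnogram, regression = reg)
  th <- cal$thresholds
  for (i in seq_len(nrow(th))) {
    r <- if (grepl("^eeg", th$role[i])) reg$eeg else reg$emg
    expect_equal(th$fpt[i], predict_fpt(th$rot[i], th$power_max[i], r))
  }
  staging <- stage_record(sim$recording, cal)
  expect_equal(nrow(staging), 30)
  expect_true(all(staging$sleep %in% 0:1))
})

test_that("a hypnogram shorter than the recording truncates with a warning", {
  sim <- generate_psg(synth_spec(duration_sec = 900, seed = 33))
  short_hyp <- hypnogram(sim$hypnogram$stage[1:20])
  expect_warning(cal <- calibrate_record(sim$recording, short_hyp), "truncat")
  expect_equal(nrow(cal$thresholds), 8)
})
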