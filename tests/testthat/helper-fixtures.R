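# Fixtures built in code: tiny recordings, hand-made envelopes and grids.

# A small 12-channel recording (default 90 s) with plausible signal content.
tiny_recording <- function(duration_sec = 90, fs = 200, seed = 42) {
  set.seed(seed)
  n <- duration_sec * fs
  t <- (0:(n - 1)) / fs
  mk_eeg <- function() rnorm(n, sd = 1) + 2 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  channels <- list(
    O1 = mk_eeg(), O2 = mk_eeg(), F3 = mk_eeg(), F4 = mk_eeg(),
    C3 = mk_eeg(), C4 = mk_eeg(),
    EMG1 = rnorm(n, sd = 0.5), EMG2 = rnorm(n, sd = 0.5),
    RF2 = sin(2 * pi * t / 4), RE1 = sin(2 * pi * t / 4 + 0.2),
    RE2 = sin(2 * pi * t / 4 - 0.2), SO2 = 97 + rnorm(n, sd = 0.05)
  )
  psg_recording(
    channels, fs = fs,
    roles = c(O1 = "eeg_occipital", O2 = "eeg_occipital",
              F3 = "eeg_frontal", F4 = "eeg_frontal",
              C3 = "eeg_central", C4 = "eeg_central",
              EMG1 = "emg_chin", EMG2 = "emg_chin",
              RF2 = "flow_pressure", RE1 = "effort_thorax",
              RE2 = "effort_abdomen", SO2 = "spo2"),
    adc_limits = list(RF2 = c(-8, 8), SO2 = c(0, 100))
  )
}

# Build a psg_envelope directly from per-point values (0.5-s grid).
make_env <- function(values, step_sec = 0.5, window_sec = 5, epoch_sec = 30) {
  times <- (seq_along(values) - 1) * step_sec
  out <- tibble::tibble(
    time_sec = times, value = values,
    epoch_index = as.integer(times %/% epoch_sec)
  )
  class(out) <- c("psg_envelope", class(out))
  attr(out, "step_sec") <- step_sec
  attr(out, "window_sec") <- window_sec
  attr(out, "epoch_sec") <- epoch_sec
  out
}

# Per-epoch constant envelope over n_epochs epochs (60 points each).
make_epoch_env <- function(epoch_values, points_per_epoch = 60) {
  make_env(rep(epoch_values, each = points_per_epoch))
}

make_grid <- function(n_epochs, fs = 200, usable = rep(TRUE, n_epochs)) {
  epoch_grid(n_epochs, fs = fs, usable = usable)
}

# Prediction/truth series reproducing published-style confusion counts:
# counts named awake_awake (pred awake & truth awake), awake_sleep
# (pred awake & truth sleep), sleep_awake, sleep_sleep; 1 = sleep.
series_from_counts <- function(awake_awake, awake_sleep, sleep_awake, sleep_sleep) {
  pred <- c(rep(0L, awake_awake), rep(0L, awake_sleep),
            rep(1L, sleep_awake), rep(1L, sleep_sleep))
  truth <- c(rep(0L, awake_awake), rep(1L, awake_sleep),
             rep(0L, sleep_awake), rep(1L, sleep_sleep))
  list(pred = pred, truth = truth)
}
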