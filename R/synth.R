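# Synthetic PSG generator: multichannel recordings with a known hypnogram,
# injected respiratory events, ADC-saturation artifacts, and full
# reproducibility from a seed, so every pipeline stage can be exercised
# without patient data.

#' Specification for a synthetic PSG recording
#'
#' Collects every knob of the generator and validates their consistency.
#' The signal model: six EEG channels are pink-noise background plus an
#' independent narrowband 8-13 Hz component whose amplitude is
#' `alpha_awake_amp` in awake epochs and `alpha_sleep_amp` in sleep epochs
#' (alpha activity attenuates at sleep onset); two chin-EMG channels are
#' band-limited 24-45 Hz noise with stage-dependent RMS; flow is a
#' sinusoid at the breathing period (3-5 s), scaled down to the event's
#' amplitude ratio inside injected event intervals; the effort channels
#' are breathing-locked sinusoids, suppressed to `effort_fraction` during
#' central apneas and left intact during obstructive ones; SpO2 sits at a
#' 97% baseline with trapezoidal dips co-located with events that specify
#' a desaturation. Artifact epochs get a burst clipped to the flow
#' channel's ADC rail.
#'
#' @param duration_sec Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param epoch_sec Scoring epoch length.
#' @param hypnogram Optional stage vector or [hypnogram()]; when absent a
#'   stage sequence with `awake_fraction` awake epochs is built (an initial
#'   awake block plus one mid-night awakening).
#' @param awake_fraction Fraction of awake epochs for the built hypnogram.
#' @param alpha_awake_amp,alpha_sleep_amp Alpha-component RMS by stage
#'   (their ratio is the staging contrast).
#' @param epoch_jitter_sd Log-normal SD of per-epoch amplitude jitter
#'   applied to the alpha and EMG components (epoch-level noise).
#' @param emg_awake_rms,emg_sleep_rms EMG RMS by stage.
#' @param breath_period_sec Respiratory period, must lie in [3, 5] s.
#' @param flow_amp,effort_amp Sinusoid amplitudes of flow and effort.
#' @param spo2_baseline Baseline saturation, percent.
#' @param events Tibble with columns `kind`, `epoch_index`,
#'   `duration_sec`, `ratio`, `desat_points`, `effort_fraction`; see
#'   [synth_events()].
#' @param artifact_epochs Integer epoch indices to clip at the flow ADC
#'   rail.
#' @param noise_sd Named list of background noise levels per channel
#'   family: `eeg`, `emg`, `flow`, `effort`, `spo2`.
#' @param seed Integer seed; the same spec generates bit-identical output.
#' @return Object of class `psg_synth_spec`.
#' @export
synth_spec <- function(duration_sec = 1800, fs = 200, epoch_sec = 30,
                       hypnogram = NULL, awake_fraction = 0.3,
                       alpha_awake_amp = 3, alpha_sleep_amp = 1,
                       epoch_jitter_sd = 0.1,
                       emg_awake_rms = 3, emg_sleep_rms = 1,
                       breath_period_sec = 4, flow_amp = 1, effort_amp = 1,
                       spo2_baseline = 97,
                       events = NULL, artifact_epochs = integer(0),
                       noise_sd = list(eeg = 1, emg = 0.3, flow = 0.01,
                                       effort = 0.01, spo2 = 0.05),
                       seed = 1L) {
  if (breath_period_sec < 3 || breath_period_sec > 5) {
    abort("breath_period_sec must lie in [3, 5] s (the average respiratory period).")
  }
  n_epochs <- floor(duration_sec / epoch_sec)
  if (n_epochs < 2) abort("Need at least 2 epochs.")
  if (is.null(events)) events <- synth_events()
  need <- c("kind", "epoch_index", "duration_sec", "ratio", "desat_points",
            "effort_fraction")
  if (!all(need %in% names(events))) {
    abort(sprintf("events must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(events) > 0) {
    if (anyDuplicated(events$epoch_index)) {
      abort("Overlapping events: at most one injected event per epoch.")
    }
    if (any(events$epoch_index < 0 | events$epoch_index >= n_epochs)) {
      abort("Event epoch_index out of range.")
    }
    if (any(events$epoch_index == 0)) {
      warn("Event injected in epoch 0 is unscorable (no baseline epoch).")
    }
    bad_kind <- setdiff(events$kind, psg_event_types)
    if (length(bad_kind) > 0) {
      abort(sprintf("Unknown event kind(s): %s", paste(bad_kind, collapse = ", ")))
    }
    ap <- events$kind %in% c("obstructive_apnea", "central_apnea")
    if (any(events$ratio[ap] >= 0.1)) {
      abort("Apnea events must have ratio < 0.1.")
    }
    hy <- events$kind == "hypopnea"
    if (any(events$ratio[hy] <= 0.1 | events$ratio[hy] > 0.7)) {
      abort("Hypopnea events must have ratio in (0.1, 0.7].")
    }
    if (any(events$duration_sec + 5 > epoch_sec - 1)) {
      abort("Event duration + 5 s envelope window must fit inside an epoch with >= 1 s of normal breathing.")
    }
    pred <- events$epoch_index - 1L
    if (any(pred %in% events$epoch_index) || any(pred %in% artifact_epochs)) {
      warn("Some events have an event or artifact in their predecessor epoch; their baselines will be distorted.")
    }
  }
  if (any(artifact_epochs < 0 | artifact_epochs >= n_epochs)) {
    abort("artifact_epochs out of range.")
  }
  structure(
    list(duration_sec = duration_sec, fs = fs, epoch_sec = epoch_sec,
         hypnogram = hypnogram, awake_fraction = awake_fraction,
         alpha_awake_amp = alpha_awake_amp, alpha_sleep_amp = alpha_sleep_amp,
         epoch_jitter_sd = epoch_jitter_sd,
         emg_awake_rms = emg_awake_rms, emg_sleep_rms = emg_sleep_rms,
         breath_period_sec = breath_period_sec, flow_amp = flow_amp,
         effort_amp = effort_amp, spo2_baseline = spo2_baseline,
         events = events, artifact_epochs = as.integer(artifact_epochs),
         noise_sd = noise_sd, seed = as.integer(seed), n_epochs = n_epochs),
    class = "psg_synth_spec"
  )
}

#' Build an event-injection table
#'
#' @param kind Event kinds (`obstructive_apnea`, `central_apnea`,
#'   `hypopnea`).
#' @param epoch_index 0-based scoring epoch of each event.
#' @param duration_sec Nominal event duration.
#' @param ratio Envelope amplitude ratio during the event (apneas < 0.1,
#'   hypopneas in (0.1, 0.7]).
#' @param desat_points SpO2 dip depth in percentage points (0 = no dip).
#' @param effort_fraction Effort amplitude fraction for central apneas.
#' @return Tibble suitable for [synth_spec()]'s `events` argument.
#' @export
synth_events <- function(kind = character(), epoch_index = integer(),
                         duration_sec = numeric(), ratio = numeric(),
                         desat_points = numeric(),
                         effort_fraction = numeric()) {
  n <- length(kind)
  tibble(
    kind = kind,
    epoch_index = as.integer(epoch_index),
    duration_sec = if (length(duration_sec)) duration_sec else rep(12, n),
    ratio = if (length(ratio)) ratio else
      ifelse(kind == "hypopnea", 0.5, 0.05),
    desat_points = if (length(desat_points)) desat_points else
      ifelse(kind == "hypopnea", 4, 0),
    effort_fraction = if (length(effort_fraction)) effort_fraction else
      ifelse(kind == "central_apnea", 0.1, 1)
  )
}

# Unit-RMS noise restricted to a frequency band, by FFT masking.
band_limited_noise <- function(n, fs, band) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)
  mask <- f_fold >= band[1] & f_fold <= band[2]
  y <- Re(fft(W * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Unit-RMS 1/f ("pink") noise by FFT shaping.
pink_noise <- function(n, fs) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmax(pmin(f, fs - f), fs / n)
  y <- Re(fft(W / sqrt(f_fold), inverse = TRUE)) / n
  y / stats::sd(y)
}

# Expand a per-epoch value to sample resolution.
per_epoch_to_samples <- function(v, spe, n) {
  out <- rep(v, each = spe)
  if (length(out) < n) out <- c(out, rep(v[length(v)], n - length(out)))
  out[seq_len(n)]
}

default_synth_hypnogram <- function(n_epochs, awake_fraction) {
  n_aw <- max(1L, min(n_epochs - 1L, round(awake_fraction * n_epochs)))
  first_block <- ceiling(0.6 * n_aw)
  mid_block <- n_aw - first_block
  stages <- rep("N2", n_epochs)
  stages[seq_len(first_block)] <- "W"
  if (mid_block > 0) {
    lo <- first_block + floor((n_epochs - first_block) / 3)
    start <- lo + sample.int(max(1L, n_epochs - mid_block - lo), 1)
    stages[start:(start + mid_block - 1L)] <- "W"
  }
  # give the sleep period some stage texture (binarization is what matters)
  sleep_idx <- which(stages != "W")
  cycle <- rep(c("N1", "N2", "N3", "N2", "REM"), each = 10, length.out = length(sleep_idx))
  stages[sleep_idx] <- cycle
  stages
}

#' Generate a synthetic PSG recording with ground truth
#'
#' @param spec A [synth_spec()].
#' @param self_check Verify, via the package's own envelope, that injected
#'   apnea intervals actually satisfy the <0.1 amplitude-ratio rule against
#'   the previous epoch (skipped for events flagged unscorable).
#' @return List of class `psg_synth`: `recording` (a [psg_recording()]),
#'   `hypnogram`, `events` (ground-truth tibble with `onset_sec`,
#'   `duration_sec`, `type`, `epoch_index`), and `usable` (logical
#'   per-epoch mask, FALSE for injected artifact epochs).
#' @export
generate_psg <- function(spec, self_check = TRUE) {
  stopifnot(inherits(spec, "psg_synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  fs <- spec$fs
  n <- as.integer(round(spec$duration_sec * fs))
  spe <- as.integer(round(spec$epoch_sec * fs))
  n_epochs <- spec$n_epochs
  t <- (0:(n - 1)) / fs

  stages <- if (is.null(spec$hypnogram)) {
    default_synth_hypnogram(n_epochs, spec$awake_fraction)
  } else if (inherits(spec$hypnogram, "psg_hypnogram")) {
    spec$hypnogram$stage
  } else {
    as.character(spec$hypnogram)
  }
  if (length(stages) != n_epochs) {
    abort(sprintf("Hypnogram has %d epochs; record has %d.",
                  length(stages), n_epochs))
  }
  hyp <- hypnogram(stages, spec$epoch_sec)
  awake <- stages == "W"

  # epoch-level amplitude modulation: vigilance-state fluctuation shared by
  # all channels of a family (channel-specific variation enters through each
  # channel's own noise realization)
  jit <- function() exp(rnorm(n_epochs, 0, spec$epoch_jitter_sd))
  alpha_amp <- ifelse(awake, spec$alpha_awake_amp, spec$alpha_sleep_amp) * jit()
  emg_rms <- ifelse(awake, spec$emg_awake_rms, spec$emg_sleep_rms) * jit()

  channels <- list(); roles <- character(); adc <- list()
  eeg_labels <- c(O1 = "eeg_occipital", O2 = "eeg_occipital",
                  F3 = "eeg_frontal", F4 = "eeg_frontal",
                  C3 = "eeg_central", C4 = "eeg_central")
  amp_eeg <- per_epoch_to_samples(alpha_amp, spe, n)
  for (lab in names(eeg_labels)) {
    channels[[lab]] <- spec$noise_sd$eeg * pink_noise(n, fs) +
      amp_eeg * band_limited_noise(n, fs, c(8, 13))
    roles[lab] <- eeg_labels[[lab]]
  }
  amp_emg <- per_epoch_to_samples(emg_rms, spe, n)
  for (lab in c("EMG1", "EMG2")) {
    channels[[lab]] <- spec$noise_sd$emg * pink_noise(n, fs) +
      amp_emg * band_limited_noise(n, fs, c(24, 45))
    roles[lab] <- "emg_chin"
  }

  # respiratory signals: events scale amplitude over duration + one
  # envelope window (5 s), centered in the epoch, so that the detector's
  # qualifying run spans the nominal duration
  ev <- spec$events
  flow_scale <- rep(1, n)
  effort_scale <- rep(1, n)
  spo2 <- rep(spec$spo2_baseline, n)
  truth_events <- empty_events()[, c("onset_sec", "duration_sec", "type", "epoch_index")]
  if (nrow(ev) > 0) {
    rows <- list()
    for (j in seq_len(nrow(ev))) {
      span <- ev$duration_sec[j] + 5
      off <- round(((spec$epoch_sec - span) / 2) * 2) / 2 # align to 0.5-s grid
      t0 <- ev$epoch_index[j] * spec$epoch_sec + off
      idx <- which(t >= t0 & t < t0 + span)
      flow_scale[idx] <- ev$ratio[j]
      if (ev$kind[j] == "central_apnea") {
        effort_scale[idx] <- ev$effort_fraction[j]
      }
      if (ev$desat_points[j] > 0) {
        # trapezoidal dip over 15 s inside the event's epoch
        d0 <- ev$epoch_index[j] * spec$epoch_sec + (spec$epoch_sec - 15) / 2
        tt <- t - d0
        shape <- pmax(0, pmin(1, pmin(tt / 5, (15 - tt) / 5)))
        spo2 <- spo2 - ev$desat_points[j] * shape
      }
      rows[[j]] <- tibble(
        onset_sec = t0, duration_sec = ev$duration_sec[j],
        type = ev$kind[j], epoch_index = ev$epoch_index[j]
      )
    }
    truth_events <- dplyr::bind_rows(rows)
  }

  breath <- sin(2 * pi * t / spec$breath_period_sec)
  channels$RF2 <- spec$flow_amp * flow_scale * breath +
    spec$noise_sd$flow * rnorm(n)
  channels$RE1 <- spec$effort_amp * effort_scale * sin(2 * pi * t / spec$breath_period_sec + 0.2) +
    spec$noise_sd$effort * rnorm(n)
  channels$RE2 <- spec$effort_amp * effort_scale * sin(2 * pi * t / spec$breath_period_sec - 0.2) +
    spec$noise_sd$effort * rnorm(n)
  channels$SO2 <- spo2 + spec$noise_sd$spo2 * rnorm(n)
  roles[c("RF2", "RE1", "RE2", "SO2")] <-
    c("flow_pressure", "effort_thorax", "effort_abdomen", "spo2")

  flow_rail <- 8 * spec$flow_amp
  adc$RF2 <- c(-flow_rail, flow_rail)
  adc$RE1 <- adc$RE2 <- c(-8 * spec$effort_amp, 8 * spec$effort_amp)
  adc$SO2 <- c(0, 100)
  for (ep in spec$artifact_epochs) {
    # 1-s saturation burst in the middle of the epoch, pinned to the rail
    i0 <- ep * spe + spe %/% 2
    channels$RF2[i0:(i0 + fs - 1)] <- flow_rail
  }

  rec <- psg_recording(channels, fs = fs, roles = roles, adc_limits = adc)
  usable <- !(seq_len(n_epochs) - 1L) %in% spec$artifact_epochs

  if (self_check && nrow(ev) > 0) {
    env <- amplitude_envelope(channels$RF2, fs, epoch_sec = spec$epoch_sec)
    for (j in seq_len(nrow(ev))) {
      i <- ev$epoch_index[j]
      if (i == 0 || !usable[i] || !usable[i + 1L] ||
            (i - 1L) %in% ev$epoch_index) next
      base <- mean(env$value[env$epoch_index == i - 1L])
      r <- min(env$value[env$epoch_index == i]) / base
      lim <- if (ev$kind[j] == "hypopnea") 0.7 else 0.1
      if (r >= lim) {
        warn(sprintf("Self-check: event in epoch %d has envelope ratio %.3f >= %.1f.",
                     i, r, lim))
      }
    }
  }

  structure(
    list(recording = rec, hypnogram = hyp, events = truth_events,
         usable = usable, spec = spec),
    class = "psg_synth"
  )
}

#' Generate a reproducible cohort of synthetic recordings
#'
#' Per-record generator parameters are drawn from the supplied ranges;
#' record seeds derive from the cohort seed, so the cohort is fully
#' reproducible.
#'
#' @param n_records Number of records.
#' @param duration_sec Record length (shared).
#' @param ranges Named list of `c(min, max)` ranges sampled per record:
#'   `alpha_contrast` (awake/sleep alpha ratio), `awake_fraction`,
#'   `emg_contrast`, `breath_period_sec`.
#' @param seed Cohort seed.
#' @param ... Further arguments passed to [synth_spec()].
#' @return List of `psg_synth` objects.
#' @export
generate_cohort <- function(n_records, duration_sec = 1800,
                            ranges = list(alpha_contrast = c(2.5, 4),
                                          awake_fraction = c(0.2, 0.4),
                                          emg_contrast = c(2, 4),
                                          breath_period_sec = c(3.2, 4.8)),
                            seed = 1L, ...) {
  stopifnot(n_records >= 1)
  set.seed(seed)
  seeds <- sample.int(1e6, n_records)
  draw <- function(r) runif(n_records, r[1], r[2])
  contrast <- draw(ranges$alpha_contrast)
  awake_f <- draw(ranges$awake_fraction)
  emg_c <- draw(ranges$emg_contrast)
  period <- draw(ranges$breath_period_sec)
  lapply(seq_len(n_records), function(i) {
    generate_psg(synth_spec(
      duration_sec = duration_sec,
      awake_fraction = awake_f[i],
      alpha_awake_amp = contrast[i], alpha_sleep_amp = 1,
      emg_awake_rms = emg_c[i], emg_sleep_rms = 1,
      breath_period_sec = period[i],
      seed = seeds[i], ...
    ))
  })
}

#' Synthetic normalized threshold pairs with a known linear relation
#'
#' Emulates the pooled calibration points of a cohort -- one normalized
#' (ROT, FPT) pair per channel per record -- drawn from an exact linear
#' relation `fpt_norm = slope * rot_norm + intercept` plus Gaussian noise,
#' clipped to [0, 1]. Used to verify that the pooled regression recovers an
#' injected relationship.
#'
#' @param n_records,n_channels Grid size (default 20 records x 6 EEG
#'   channels = 120 points).
#' @param slope,intercept True relation.
#' @param noise_sd Gaussian noise SD on `fpt_norm`.
#' @param rot_range Range of the uniformly drawn `rot_norm` values.
#' @param seed Seed.
#' @return Tibble with columns `record`, `channel`, `rot_norm`, `fpt_norm`.
#' @export
synth_threshold_points <- function(n_records = 20, n_channels = 6,
                                   slope = 0.8, intercept = 0.05,
                                   noise_sd = 0.02, rot_range = c(0.05, 0.6),
                                   seed = 1L) {
  set.seed(seed)
  n <- n_records * n_channels
  rot <- runif(n, rot_range[1], rot_range[2])
  fpt <- slope * rot + intercept + rnorm(n, 0, noise_sd)
  tibble(
    record = rep(seq_len(n_records), each = n_channels),
    channel = rep(seq_len(n_channels), times = n_records),
    rot_norm = pmin(1, pmax(0, rot)),
    fpt_norm = pmin(1, pmax(0, fpt))
  )
}
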