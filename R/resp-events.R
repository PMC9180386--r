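# Respiratory event scoring: sliding amplitude envelopes of flow and
# effort, previous-epoch baselines, apnea/hypopnea detection by amplitude
# ratio, SpO2 desaturation attribution, and central/obstructive
# classification from effort suppression.

#' Sliding-window amplitude envelope
#'
#' Amplitude of the breathing cycle: within each 5-s window (covering one
#' full respiratory period, which lasts 3-5 s) the envelope value is the
#' difference between the window's maximum and minimum. Windows advance in
#' 0.5-s steps, giving 60 points per complete 30-s epoch; windows crossing
#' the record end are dropped.
#'
#' @param x Numeric signal (flow or effort channel).
#' @param fs Sampling rate in Hz; `fs * step_sec` must be integral.
#' @param window_sec Window length in seconds.
#' @param step_sec Step between window starts in seconds.
#' @param epoch_sec Epoch duration used for point-to-epoch attribution.
#' @return Tibble of class `psg_envelope` with columns `time_sec` (window
#'   start), `value` (max - min), and `epoch_index`; `step_sec`,
#'   `window_sec` and `epoch_sec` are carried as attributes.
#' @export
amplitude_envelope <- function(x, fs, window_sec = 5, step_sec = 0.5,
                               epoch_sec = 30) {
  step_n <- fs * step_sec
  if (abs(step_n - round(step_n)) > 1e-9) abort("fs * step_sec must be integral.")
  step_n <- as.integer(round(step_n))
  win_n <- as.integer(round(fs * window_sec))
  if (length(x) < win_n) abort("Signal shorter than one window.")
  n_pts <- (length(x) - win_n) %/% step_n + 1L

  ratio <- window_sec / step_sec
  if (abs(ratio - round(ratio)) < 1e-9 && win_n == round(ratio) * step_n) {
    # window is an exact multiple of the step: compute per-step block
    # extrema once, then take running extrema over `ratio` blocks
    w <- as.integer(round(ratio))
    n_blocks <- length(x) %/% step_n
    bm <- matrix(x[seq_len(n_blocks * step_n)], nrow = step_n)
    bmax <- apply(bm, 2, max)
    bmin <- apply(bm, 2, min)
    vals <- vapply(seq_len(n_pts), function(k) {
      idx <- k:(k + w - 1L)
      max(bmax[idx]) - min(bmin[idx])
    }, numeric(1))
  } else {
    vals <- vapply(seq_len(n_pts), function(k) {
      seg <- x[((k - 1L) * step_n + 1L):((k - 1L) * step_n + win_n)]
      max(seg) - min(seg)
    }, numeric(1))
  }
  times <- (seq_len(n_pts) - 1L) * step_sec
  out <- tibble(
    time_sec = times,
    value = vals,
    epoch_index = as.integer(times %/% epoch_sec)
  )
  class(out) <- c("psg_envelope", class(out))
  attr(out, "step_sec") <- step_sec
  attr(out, "window_sec") <- window_sec
  attr(out, "epoch_sec") <- epoch_sec
  out
}

#' Previous-epoch baseline amplitudes
#'
#' For each epoch i, the baseline is the mean envelope over epoch i-1. The
#' baseline is undefined for epoch 0 (no predecessor) and for epochs whose
#' predecessor is unusable; epochs without a defined baseline are not
#' scored.
#'
#' @param env A `psg_envelope` ([amplitude_envelope()]).
#' @param grid The record's [epoch_grid()].
#' @return Tibble with columns `epoch_index`, `baseline`, `defined`.
#' @export
epoch_baselines <- function(env, grid) {
  stopifnot(inherits(grid, "psg_epoch_grid"))
  n <- grid$n_epochs
  means <- rep(NA_real_, n)
  agg <- tapply(env$value, env$epoch_index, mean)
  idx <- as.integer(names(agg))
  keep <- idx < n
  means[idx[keep] + 1L] <- as.numeric(agg)[keep]
  baseline <- c(NA_real_, means[-n])
  defined <- c(FALSE, grid$usable[-n]) & !is.na(baseline)
  tibble(epoch_index = 0:(n - 1L), baseline = baseline, defined = defined)
}

# Scorable epochs: defined baseline and themselves usable.
scorable_epochs <- function(baselines, grid) {
  which(baselines$defined & grid$usable) - 1L
}

# Maximal runs of TRUE in a logical vector; returns list of (start, end)
# index pairs (1-based, inclusive).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(c, starts[keep], ends[keep])
}

empty_events <- function() {
  tibble(
    onset_sec = numeric(), duration_sec = numeric(), type = character(),
    epoch_index = integer(), min_ratio = numeric(), desat_points = numeric()
  )
}

#' Detect apnea candidates from the flow envelope
#'
#' Within each scorable epoch, the envelope is divided by the epoch's
#' previous-epoch baseline; maximal runs of consecutive points with ratio
#' below `ratio_cut` (default 0.1, a >90% amplitude reduction) lasting at
#' least `min_duration_sec` (>= 20 points at 0.5-s steps) each yield one
#' candidate apnea. Events are confined to their scoring epoch: a reduction
#' crossing an epoch boundary is evaluated on each side against that side's
#' own baseline.
#'
#' @param env Flow `psg_envelope`.
#' @param baselines Output of [epoch_baselines()].
#' @param grid The [epoch_grid()].
#' @param min_duration_sec Minimum event duration in seconds.
#' @param ratio_cut Amplitude-ratio cutoff.
#' @return Tibble of candidates: `onset_sec`, `duration_sec`,
#'   `epoch_index`, `min_ratio` (`type` is assigned by [classify_apnea()]).
#' @export
detect_apneas <- function(env, baselines, grid,
                          min_duration_sec = 10, ratio_cut = 0.1) {
  step <- attr(env, "step_sec") %||% 0.5
  min_pts <- as.integer(ceiling(min_duration_sec / step))
  out <- list()
  for (i in scorable_epochs(baselines, grid)) {
    pts <- env[env$epoch_index == i, ]
    if (nrow(pts) == 0) next
    ratio <- pts$value / baselines$baseline[i + 1L]
    for (run in true_runs(ratio < ratio_cut)) {
      len <- run[2] - run[1] + 1L
      if (len < min_pts) next
      out[[length(out) + 1L]] <- tibble(
        onset_sec = pts$time_sec[run[1]],
        duration_sec = len * step,
        epoch_index = i,
        min_ratio = min(ratio[run[1]:run[2]])
      )
    }
  }
  if (length(out) == 0) {
    return(empty_events()[, c("onset_sec", "duration_sec", "epoch_index", "min_ratio")])
  }
  dplyr::bind_rows(out)
}

#' Classify apnea candidates as central or obstructive
#'
#' An apnea is central when respiratory effort collapses along with the
#' flow: both the thoracic and the abdominal effort envelopes must stay
#' below `effort_frac` (20%) of their own maximum within the event's epoch
#' for a run of at least `min_duration_sec` that overlaps the event.
#' Otherwise -- effort maintained against an occluded airway -- the apnea
#' is obstructive. If either effort channel is unavailable the event is
#' conservatively labelled obstructive with a warning.
#'
#' @param events Candidate tibble from [detect_apneas()].
#' @param env_thorax,env_abdomen Effort `psg_envelope`s (or `NULL`).
#' @param grid The [epoch_grid()].
#' @param effort_frac Suppression threshold as a fraction of the epoch's
#'   envelope maximum.
#' @param min_duration_sec Minimum suppression duration.
#' @return `events` with a `type` column added.
#' @export
classify_apnea <- function(events, env_thorax, env_abdomen, grid,
                           effort_frac = 0.2, min_duration_sec = 10) {
  if (nrow(events) == 0) {
    events$type <- character(0)
    return(events)
  }
  if (is.null(env_thorax) || is.null(env_abdomen)) {
    warn("Effort channel(s) missing; labelling apneas as obstructive.")
    events$type <- "obstructive_apnea"
    return(events)
  }
  step <- attr(env_thorax, "step_sec") %||% 0.5
  min_pts <- as.integer(ceiling(min_duration_sec / step))
  events$type <- vapply(seq_len(nrow(events)), function(j) {
    i <- events$epoch_index[j]
    th <- env_thorax[env_thorax$epoch_index == i, ]
    ab <- env_abdomen[env_abdomen$epoch_index == i, ]
    if (nrow(th) == 0 || nrow(ab) == 0) return("obstructive_apnea")
    m <- min(nrow(th), nrow(ab))
    th <- th[seq_len(m), ]; ab <- ab[seq_len(m), ]
    low <- th$value < effort_frac * max(th$value) &
      ab$value < effort_frac * max(ab$value)
    ev_lo <- events$onset_sec[j]
    ev_hi <- ev_lo + events$duration_sec[j]
    for (run in true_runs(low)) {
      if (run[2] - run[1] + 1L < min_pts) next
      t0 <- th$time_sec[run[1]]
      t1 <- th$time_sec[run[2]] + step
      if (t0 < ev_hi && t1 > ev_lo) return("central_apnea")
    }
    "obstructive_apnea"
  }, character(1))
  events
}

#' Per-epoch SpO2 desaturation depth
#'
#' Maximum minus minimum oxygen saturation within each epoch, in percentage
#' points; `NA` for unusable epochs.
#'
#' @param spo2 SpO2 signal, percent.
#' @param fs Sampling rate in Hz.
#' @param grid The [epoch_grid()].
#' @return Numeric vector of length `n_epochs`.
#' @export
epoch_desaturation <- function(spo2, fs, grid) {
  stopifnot(inherits(grid, "psg_epoch_grid"))
  spe <- as.integer(round(fs * grid$epoch_sec))
  n <- grid$n_epochs
  m <- matrix(spo2[seq_len(n * spe)], nrow = spe)
  d <- apply(m, 2, max) - apply(m, 2, min)
  d[!grid$usable] <- NA_real_
  d
}

#' Detect hypopneas from the flow envelope and SpO2
#'
#' A hypopnea is a partial amplitude reduction -- envelope-to-baseline
#' ratio in (0.1, 0.7], i.e. a 30-90% drop -- sustained for at least
#' `min_duration_sec` within a scorable epoch whose SpO2 desaturation
#' (epoch max - min) reaches at least `desat_min` percentage points.
#' Partial reductions without a qualifying desaturation score nothing.
#'
#' @inheritParams detect_apneas
#' @param spo2 SpO2 signal, percent.
#' @param fs Sampling rate of `spo2` in Hz.
#' @param ratio_low,ratio_high Ratio band: `ratio_low < r <= ratio_high`.
#' @param desat_min Minimum qualifying desaturation, percentage points.
#' @return Tibble of hypopneas: `onset_sec`, `duration_sec`,
#'   `epoch_index`, `min_ratio`, `desat_points`, `type`.
#' @export
detect_hypopneas <- function(env, baselines, spo2, fs, grid,
                             min_duration_sec = 10,
                             ratio_low = 0.1, ratio_high = 0.7,
                             desat_min = 3) {
  step <- attr(env, "step_sec") %||% 0.5
  min_pts <- as.integer(ceiling(min_duration_sec / step))
  desat <- epoch_desaturation(spo2, fs, grid)
  out <- list()
  for (i in scorable_epochs(baselines, grid)) {
    if (is.na(desat[i + 1L]) || desat[i + 1L] < desat_min) next
    pts <- env[env$epoch_index == i, ]
    if (nrow(pts) == 0) next
    ratio <- pts$value / baselines$baseline[i + 1L]
    for (run in true_runs(ratio > ratio_low & ratio <= ratio_high)) {
      len <- run[2] - run[1] + 1L
      if (len < min_pts) next
      out[[length(out) + 1L]] <- tibble(
        onset_sec = pts$time_sec[run[1]],
        duration_sec = len * step,
        epoch_index = i,
        min_ratio = min(ratio[run[1]:run[2]]),
        desat_points = desat[i + 1L],
        type = "hypopnea"
      )
    }
  }
  if (length(out) == 0) {
    return(empty_events()[, c("onset_sec", "duration_sec", "epoch_index",
                              "min_ratio", "desat_points", "type")])
  }
  dplyr::bind_rows(out)
}

#' Score a full record for respiratory events
#'
#' Runs the whole second-part pipeline on a recording: artifact-flags the
#' flow, effort, and SpO2 channels (epochs touching the ADC rails become
#' unusable), builds the 5-s/0.5-s amplitude envelopes, computes
#' previous-epoch baselines, detects and classifies apneas, detects
#' hypopneas, and returns the chronologically sorted event list together
#' with per-epoch binary flags for each event type.
#'
#' @param rec A [psg_recording()] with `flow_pressure` and `spo2` channels
#'   (effort channels optional but needed for central/obstructive
#'   separation).
#' @param calibration Optional `psg_calibration`; with
#'   `gate_sleep = TRUE`, events in epochs the staging pipeline scores
#'   awake are discarded.
#' @param gate_sleep Restrict events to predicted-sleep epochs?
#' @param min_duration_sec,ratio_apnea,ratio_hypopnea_high,desat_min,effort_frac
#'   Scoring rule parameters (defaults: 10 s, 0.1, 0.7, 3 points, 0.2).
#' @param window_sec,step_sec Envelope construction parameters.
#' @return List of class `psg_scoring`: `events` (tibble with `onset_sec`,
#'   `duration_sec`, `type`, `epoch_index`, `min_ratio`, `desat_points`),
#'   `epoch_flags` (tibble with `epoch_index`, `usable`,
#'   `obstructive_apnea`, `central_apnea`, `hypopnea`), and `grid`.
#' @export
score_record <- function(rec, calibration = NULL, gate_sleep = FALSE,
                         min_duration_sec = 10, ratio_apnea = 0.1,
                         ratio_hypopnea_high = 0.7, desat_min = 3,
                         effort_frac = 0.2, window_sec = 5, step_sec = 0.5) {
  stopifnot(inherits(rec, "psg_recording"))
  flow_lab <- role_channel(rec, "flow_pressure")
  spo2_lab <- role_channel(rec, "spo2")
  if (is.null(flow_lab)) abort("Recording is missing a channel with mandatory role 'flow_pressure'.")
  if (is.null(spo2_lab)) abort("Recording is missing a channel with mandatory role 'spo2'.")
  thor_lab <- role_channel(rec, "effort_thorax")
  abdo_lab <- role_channel(rec, "effort_abdomen")

  fs <- rec$fs
  flow <- rec$channels[[flow_lab]]
  grid <- split_epochs(flow, fs)$grid
  for (lab in c(flow_lab, thor_lab, abdo_lab, spo2_lab)) {
    grid <- flag_artifact_epochs(rec$channels[[lab]], grid,
                                 adc_limits = rec$adc_limits[[lab]])
  }

  env_flow <- amplitude_envelope(flow, fs, window_sec, step_sec, grid$epoch_sec)
  env_thor <- if (!is.null(thor_lab)) {
    amplitude_envelope(rec$channels[[thor_lab]], fs, window_sec, step_sec, grid$epoch_sec)
  }
  env_abdo <- if (!is.null(abdo_lab)) {
    amplitude_envelope(rec$channels[[abdo_lab]], fs, window_sec, step_sec, grid$epoch_sec)
  }
  baselines <- epoch_baselines(env_flow, grid)

  apneas <- detect_apneas(env_flow, baselines, grid, min_duration_sec, ratio_apnea)
  apneas <- classify_apnea(apneas, env_thor, env_abdo, grid,
                           effort_frac, min_duration_sec)
  if (nrow(apneas) > 0) apneas$desat_points <- NA_real_
  hypopneas <- detect_hypopneas(env_flow, baselines, rec$channels[[spo2_lab]],
                                fs, grid, min_duration_sec,
                                ratio_apnea, ratio_hypopnea_high, desat_min)
  events <- dplyr::bind_rows(apneas, hypopneas)
  if (nrow(events) > 0) {
    events <- events[order(events$onset_sec), ]
    events <- events[, c("onset_sec", "duration_sec", "type", "epoch_index",
                         "min_ratio", "desat_points")]
  } else {
    events <- empty_events()[, c("onset_sec", "duration_sec", "type",
                                 "epoch_index", "min_ratio", "desat_points")]
  }

  if (gate_sleep && !is.null(calibration)) {
    staging <- stage_record(rec, calibration)
    sleep_epochs <- staging$epoch_index[staging$sleep == 1]
    events <- events[events$epoch_index %in% sleep_epochs, , drop = FALSE]
  }

  n <- grid$n_epochs
  flags <- tibble(
    epoch_index = 0:(n - 1L),
    usable = grid$usable,
    obstructive_apnea = as.integer(0:(n - 1L) %in%
                                     events$epoch_index[events$type == "obstructive_apnea"]),
    central_apnea = as.integer(0:(n - 1L) %in%
                                 events$epoch_index[events$type == "central_apnea"]),
    hypopnea = as.integer(0:(n - 1L) %in%
                            events$epoch_index[events$type == "hypopnea"])
  )
  structure(
    list(events = as_tibble(events), epoch_flags = flags, grid = grid),
    class = "psg_scoring"
  )
}

#' @export
print.psg_scoring <- function(x, ...) {
  cat(sprintf(
    "<psg_scoring> %d event(s) over %d epochs (%d usable): %d obstructive, %d central, %d hypopnea\n",
    nrow(x$events), x$grid$n_epochs, sum(x$grid$usable),
    sum(x$events$type == "obstructive_apnea"),
    sum(x$events$type == "central_apnea"),
    sum(x$events$type == "hypopnea")))
  invisible(x)
}
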