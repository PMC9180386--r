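# Awake/sleep staging: per-epoch accumulated band power, threshold
# classification, ROC-based threshold calibration (ROT + false-positive-
# capped FPT), the pooled FPT-vs-ROT regression, and the nine OR-combination
# channel search.

#' Accumulated in-band FFT magnitude of one epoch
#'
#' Computes the FFT of a 30-s epoch block and sums the spectral magnitude
#' over the frequency bins falling inside `band` (inclusive, positive
#' frequencies). The signal is expected to be band-pass filtered already;
#' the in-band sum then accumulates essentially all of its spectral content.
#'
#' @param block Numeric vector of exactly `fs * epoch_sec` samples.
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz.
#' @param epoch_sec Epoch duration in seconds.
#' @return Non-negative scalar, in arbitrary amplitude units.
#' @export
epoch_band_power <- function(block, fs, band, epoch_sec = 30) {
  n_expect <- as.integer(round(fs * epoch_sec))
  if (length(block) != n_expect) {
    abort(sprintf("Epoch block must have fs * epoch_sec = %d samples, got %d.",
                  n_expect, length(block)))
  }
  N <- length(block)
  freqs <- (0:(N - 1)) * fs / N
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  sum(Mod(fft(block))[keep])
}

#' Per-epoch band-power series for one channel
#'
#' Splits the (already filtered) signal into epochs and accumulates the
#' in-band FFT magnitude of each.
#'
#' @param x Filtered channel signal.
#' @inheritParams epoch_band_power
#' @return Tibble with columns `epoch_index` (0-based) and `power`.
#' @export
band_power_series <- function(x, fs, band, epoch_sec = 30) {
  sp <- split_epochs(x, fs, epoch_sec)
  mags <- Mod(stats::mvfft(sp$blocks))
  N <- nrow(sp$blocks)
  freqs <- (0:(N - 1)) * fs / N
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  tibble(
    epoch_index = seq_len(ncol(mags)) - 1L,
    power = colSums(mags[keep, , drop = FALSE])
  )
}

#' Classify epochs as awake/sleep by power threshold
#'
#' An epoch is scored sleep (1) when its accumulated band power is strictly
#' below the threshold, awake (0) otherwise: alpha-band EEG activity and
#' chin-EMG tone both drop at sleep onset. Equality counts as awake, which
#' makes the sleep region shrink monotonically as the threshold falls -- the
#' property the FPT ("largest threshold under the false-positive cap")
#' definition relies on.
#'
#' @param powers Numeric vector of per-epoch powers, or a tibble with a
#'   `power` column.
#' @param threshold Finite scalar threshold in power units.
#' @return Integer vector, 1 = sleep, 0 = awake.
#' @export
threshold_classify <- function(powers, threshold) {
  if (is.data.frame(powers)) powers <- powers$power
  if (!is.finite(threshold)) abort("threshold must be finite.")
  as.integer(powers < threshold)
}

#' ROC scan over a grid of power thresholds
#'
#' Evaluates `n_thresholds` equally spaced thresholds between the minimum
#' and maximum observed power. For each, a confusion matrix against the
#' expert awake/sleep labels is computed with sleep as the positive class,
#' and the ROC-optimal threshold (ROT) is the one maximizing Youden's
#' J = sensitivity + specificity - 1, ties broken toward the smallest
#' threshold. AUC is the trapezoidal area over the scanned
#' (1 - specificity, sensitivity) points augmented with (0,0) and (1,1).
#'
#' @param powers Per-epoch power vector (or tibble with `power`).
#' @param expert Integer expert labels, 1 = sleep, 0 = awake; both classes
#'   must be present.
#' @param n_thresholds Number of scanned thresholds.
#' @param usable Optional logical mask; epochs outside it are ignored.
#' @return List of class `psg_roc`: `roc` (tibble with threshold, tp, fp,
#'   tn, fn, sensitivity, specificity, youden), `rot`, `auc`, `power_max`,
#'   `power_min`.
#' @export
roc_scan <- function(powers, expert, n_thresholds = 100, usable = NULL) {
  if (is.data.frame(powers)) powers <- powers$power
  expert <- as.integer(expert)
  if (length(powers) != length(expert)) abort("powers and expert differ in length.")
  if (!is.null(usable)) {
    powers <- powers[usable]; expert <- expert[usable]
  }
  if (all(expert == 1)) abort("Expert labels contain no awake epochs.")
  if (all(expert == 0)) abort("Expert labels contain no sleep epochs.")

  thresholds <- seq(min(powers), max(powers), length.out = n_thresholds)
  pred <- outer(powers, thresholds, `<`) # TRUE = sleep
  is_sleep <- expert == 1
  tp <- colSums(pred[is_sleep, , drop = FALSE])
  fn <- sum(is_sleep) - tp
  fp <- colSums(pred[!is_sleep, , drop = FALSE])
  tn <- sum(!is_sleep) - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  youden <- sens + spec - 1
  rot <- thresholds[which.max(youden)]
  fpr <- c(0, sort(1 - spec), 1)
  tpr <- c(0, sort(sens), 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(
      roc = tibble(threshold = thresholds, tp = tp, fp = fp, tn = tn, fn = fn,
                   sensitivity = sens, specificity = spec, youden = youden),
      rot = rot, auc = auc,
      power_max = max(powers), power_min = min(powers)
    ),
    class = "psg_roc"
  )
}

#' @export
print.psg_roc <- function(x, ...) {
  cat(sprintf("<psg_roc> %d thresholds on [%.4g, %.4g]; ROT = %.4g, AUC = %.3f\n",
              nrow(x$roc), x$power_min, x$power_max, x$rot, x$auc))
  invisible(x)
}

#' Select the false-positive-capped threshold (FPT)
#'
#' Scans the same equally spaced threshold grid as [roc_scan()] and returns
#' the largest threshold whose false-positive count (expert-awake epochs
#' classified sleep) is strictly below `fp_rate` times the number of
#' expert-awake epochs. If no threshold satisfies the cap, the minimum
#' scanned threshold is returned with a warning.
#'
#' @inheritParams roc_scan
#' @param fp_rate False-positive cap as a fraction of expert-awake epochs.
#' @return List with `fpt`, `fp` (false positives at the FPT), `cap`
#'   (the strict upper bound on FP counts), and `n_awake`.
#' @export
select_fpt <- function(powers, expert, fp_rate = 0.10, n_thresholds = 100,
                       usable = NULL) {
  if (is.data.frame(powers)) powers <- powers$power
  expert <- as.integer(expert)
  if (!is.null(usable)) {
    powers <- powers[usable]; expert <- expert[usable]
  }
  n_awake <- sum(expert == 0)
  if (n_awake == 0) abort("Expert labels contain no awake epochs.")
  thresholds <- seq(min(powers), max(powers), length.out = n_thresholds)
  fp <- colSums(outer(powers[expert == 0], thresholds, `<`))
  cap <- fp_rate * n_awake
  ok <- fp < cap
  if (!any(ok)) {
    warn("No scanned threshold keeps false positives below the cap; returning the minimum threshold.")
    i <- 1L
  } else {
    i <- max(which(ok))
  }
  list(fpt = thresholds[i], fp = unname(fp[i]), cap = cap, n_awake = n_awake)
}

#' Fit the pooled FPT-vs-ROT linear regression
#'
#' Ordinary least squares of normalized FPT on normalized ROT, pooled
#' across channels and records. Both coordinates must already be normalized
#' to [0, 1] by each channel-record's maximum scanned power. For EEG
#' channels, points with `rot_norm` above the cutoff are excluded before
#' fitting (high normalized ROTs come from low-AUC series and degrade the
#' relationship); no cutoff is applied for EMG.
#'
#' @param points Tibble (or data frame) with columns `rot_norm` and
#'   `fpt_norm`, both in [0, 1].
#' @param channel_type `"eeg"` or `"emg"`.
#' @param rot_norm_cutoff Exclusion cutoff for EEG points.
#' @return List of class `psg_fpt_regression`: `slope`, `intercept`, `r2`,
#'   `channel_type`, `n_used`, `n_total`, `frac_retained`, and (for EEG)
#'   `rot_norm_cutoff`.
#' @export
fit_fpt_regression <- function(points, channel_type = c("eeg", "emg"),
                               rot_norm_cutoff = 0.6) {
  channel_type <- match.arg(channel_type)
  stopifnot(all(c("rot_norm", "fpt_norm") %in% names(points)))
  if (any(points$rot_norm < 0 | points$rot_norm > 1 |
            points$fpt_norm < 0 | points$fpt_norm > 1)) {
    abort("All rot_norm and fpt_norm values must lie in [0, 1].")
  }
  n_total <- nrow(points)
  fit_pts <- points
  if (channel_type == "eeg") {
    fit_pts <- points[points$rot_norm <= rot_norm_cutoff, , drop = FALSE]
  }
  if (nrow(fit_pts) < 3) {
    abort(sprintf("Need at least 3 points to fit (have %d after filtering).",
                  nrow(fit_pts)))
  }
  fit <- lm(fpt_norm ~ rot_norm, data = fit_pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((fit_pts$fpt_norm - mean(fit_pts$fpt_norm))^2)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    channel_type = channel_type,
    n_used = nrow(fit_pts),
    n_total = n_total,
    frac_retained = nrow(fit_pts) / n_total
  )
  if (channel_type == "eeg") out$rot_norm_cutoff <- rot_norm_cutoff
  structure(out, class = "psg_fpt_regression")
}

#' @export
print.psg_fpt_regression <- function(x, ...) {
  cat(sprintf(
    "<psg_fpt_regression> %s: fpt_norm = %.3f * rot_norm + %.3f (R2 = %.3f, %d/%d points)\n",
    x$channel_type, x$slope, x$intercept, x$r2, x$n_used, x$n_total))
  invisible(x)
}

#' Predict a record's FPT from its ROT via the pooled regression
#'
#' Transfers the cohort calibration to a new record: the record's ROT is
#' normalized by its maximum scanned power, run through the regression, and
#' de-normalized, clipping the result to `[0, power_max]`.
#'
#' @param rot ROC-optimal threshold, in the record's power units.
#' @param power_max The record-channel's maximum scanned power (> 0).
#' @param regression A `psg_fpt_regression` (or any list with `slope` and
#'   `intercept`).
#' @return Predicted FPT in power units.
#' @export
predict_fpt <- function(rot, power_max, regression) {
  if (power_max <= 0) abort("power_max must be > 0.")
  fpt_norm <- regression$slope * (rot / power_max) + regression$intercept
  min(max(fpt_norm * power_max, 0), power_max)
}

#' Combine binary stage series with OR
#'
#' An epoch is scored sleep when any of the input series scores it sleep.
#'
#' @param series List of equal-length 0/1 integer vectors.
#' @return Integer 0/1 vector.
#' @export
combine_or <- function(series) {
  if (!is.list(series) || length(series) == 0) {
    abort("combine_or needs a non-empty list of series.")
  }
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) > 1) abort("Series must have equal lengths.")
  as.integer(Reduce(`|`, lapply(series, as.logical)))
}

#' The nine staging channel combinations
#'
#' Enumerates, in fixed order, the nine channel sets whose OR-combined
#' stage series are compared: (i) all EEG, (ii) EMG, (iii) EEG + EMG,
#' (iv) occipital EEG + EMG, (v) frontal EEG + EMG, (vi) central EEG + EMG,
#' (vii) occipital + frontal EEG + EMG, (viii) occipital + central EEG +
#' EMG, (ix) frontal + central EEG + EMG.
#'
#' @param roles Named character vector label -> role covering the six EEG
#'   and two EMG channels.
#' @return Named list (names `"i"` ... `"ix"`) of character vectors of
#'   channel labels.
#' @export
staging_combinations <- function(roles) {
  occ <- names(roles)[roles == "eeg_occipital"]
  fro <- names(roles)[roles == "eeg_frontal"]
  cen <- names(roles)[roles == "eeg_central"]
  emg <- names(roles)[roles == "emg_chin"]
  eeg <- c(occ, fro, cen)
  list(
    i = eeg,
    ii = emg,
    iii = c(eeg, emg),
    iv = c(occ, emg),
    v = c(fro, emg),
    vi = c(cen, emg),
    vii = c(occ, fro, emg),
    viii = c(occ, cen, emg),
    ix = c(fro, cen, emg)
  )
}

#' Search the nine OR-combinations for the best staging channel set
#'
#' Each combination's channels are OR-combined and scored against the
#' expert labels by success rate, (TP + TN) / number of evaluated epochs.
#' Ties break toward the earlier combination in the (i)-(ix) order.
#'
#' @param per_channel Named list of per-channel 0/1 stage series covering
#'   all eight channels.
#' @param expert Expert 0/1 series (1 = sleep).
#' @param roles Named character vector label -> role for the 8 channels.
#' @param usable Optional logical mask restricting evaluated epochs.
#' @return List: `combination_id`, `success_rate`, and `scores`, a tibble
#'   of all nine combinations.
#' @export
best_combination <- function(per_channel, expert, roles, usable = NULL) {
  combos <- staging_combinations(roles)
  missing <- setdiff(unique(unlist(combos)), names(per_channel))
  if (length(missing) > 0) {
    abort(sprintf("per_channel is missing channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  rates <- vapply(combos, function(labs) {
    pred <- combine_or(per_channel[labs])
    success_rate(confusion(pred, expert, usable = usable, positive_class = "sleep"))
  }, numeric(1))
  best <- which.max(rates) # first maximum = earliest combination
  list(
    combination_id = names(combos)[best],
    success_rate = unname(rates[best]),
    scores = tibble(combination_id = names(combos), success_rate = unname(rates))
  )
}

# ---- record-level calibration and staging ---------------------------------

# Filtered per-channel band-power series for the 8 staging channels.
staging_band_powers <- function(rec, eeg_band = c(8, 13), emg_band = c(24, 45),
                                epoch_sec = 30) {
  eeg_labs <- channels_with_role(rec, c("eeg_occipital", "eeg_frontal", "eeg_central"))
  emg_labs <- channels_with_role(rec, "emg_chin")
  if (length(eeg_labs) == 0) abort("Recording has no EEG channels.")
  eeg_ref <- average_reference(rec$channels[eeg_labs])
  b_eeg <- design_bandpass(eeg_band, rec$fs)
  b_emg <- design_bandpass(emg_band, rec$fs)
  powers <- list()
  for (lab in eeg_labs) {
    powers[[lab]] <- band_power_series(apply_filter(eeg_ref[[lab]], b_eeg),
                                       rec$fs, eeg_band, epoch_sec)$power
  }
  for (lab in emg_labs) {
    powers[[lab]] <- band_power_series(apply_filter(rec$channels[[lab]], b_emg),
                                       rec$fs, emg_band, epoch_sec)$power
  }
  powers
}

#' Calibrate staging thresholds for one record
#'
#' Runs the full first-part pipeline against an expert hypnogram:
#' average-references the EEG, band-pass filters EEG (8-13 Hz) and chin EMG
#' (24-45 Hz), accumulates per-epoch FFT magnitude, scans 100 thresholds
#' per channel for the ROC-optimal threshold (ROT) and the largest
#' threshold keeping false positives under the 10% cap (FPT), classifies
#' each channel at its working threshold, and searches the nine
#' OR-combinations for the best channel set. When a pooled regression is
#' supplied, each channel's working FPT is predicted from its ROT through
#' the regression instead of selected directly (the transfer path used for
#' new patients).
#'
#' @param rec A [psg_recording()] with the 6 EEG and 2 EMG channels.
#' @param hyp Expert hypnogram ([hypnogram()] tibble). If shorter than the
#'   recording, the recording's trailing epochs are dropped with a warning.
#' @param eeg_band,emg_band Pass bands in Hz.
#' @param fp_rate False-positive cap.
#' @param n_thresholds Thresholds in the ROC scan.
#' @param epoch_sec Epoch duration.
#' @param regression Optional named list
#'   `list(eeg = <psg_fpt_regression>, emg = <psg_fpt_regression>)`.
#' @return A `psg_calibration`: per-channel thresholds tibble (`channel`,
#'   `role`, `rot`, `fpt`, `power_max`, `auc`, `fp_at_fpt`), the winning
#'   `combination_id` and its success rate, any regressions used, and the
#'   run parameters.
#' @export
calibrate_record <- function(rec, hyp,
                             eeg_band = c(8, 13), emg_band = c(24, 45),
                             fp_rate = 0.10, n_thresholds = 100,
                             epoch_sec = 30, regression = NULL) {
  powers <- staging_band_powers(rec, eeg_band, emg_band, epoch_sec)
  n_rec_epochs <- length(powers[[1]])
  expert <- binarize_stages(hyp)
  if (length(expert) < n_rec_epochs) {
    warn(sprintf(
      "Hypnogram (%d epochs) shorter than recording (%d); truncating recording.",
      length(expert), n_rec_epochs))
    powers <- lapply(powers, function(p) p[seq_along(expert)])
  } else if (length(expert) > n_rec_epochs) {
    expert <- expert[seq_len(n_rec_epochs)]
  }
  eeg_labs <- channels_with_role(rec, c("eeg_occipital", "eeg_frontal", "eeg_central"))

  rows <- list(); series <- list()
  for (lab in names(powers)) {
    p <- powers[[lab]]
    scan <- roc_scan(p, expert, n_thresholds)
    is_eeg <- lab %in% eeg_labs
    reg <- if (is_eeg) regression$eeg else regression$emg
    if (is.null(reg)) {
      sel <- select_fpt(p, expert, fp_rate, n_thresholds)
      fpt <- sel$fpt; fp_at <- sel$fp
    } else {
      fpt <- predict_fpt(scan$rot, scan$power_max, reg)
      fp_at <- sum(p[expert == 0] < fpt)
    }
    rows[[lab]] <- tibble(
      channel = lab, role = unname(rec$roles[[lab]]),
      rot = scan$rot, fpt = fpt, power_max = scan$power_max,
      auc = scan$auc, fp_at_fpt = fp_at
    )
    series[[lab]] <- threshold_classify(p, fpt)
  }
  comb <- best_combination(series, expert, rec$roles[names(powers)])
  structure(
    list(
      thresholds = dplyr::bind_rows(rows),
      regression_eeg = regression$eeg,
      regression_emg = regression$emg,
      combination_id = comb$combination_id,
      combination_success = comb$success_rate,
      combination_scores = comb$scores,
      fp_rate = fp_rate, n_thresholds = as.integer(n_thresholds),
      eeg_band = eeg_band, emg_band = emg_band,
      epoch_sec = epoch_sec, fs = rec$fs
    ),
    class = "psg_calibration"
  )
}

#' @export
print.psg_calibration <- function(x, ...) {
  cat(sprintf(
    "<psg_calibration> %d channels, combination (%s) success %.3f, FP cap %.0f%%\n",
    nrow(x$thresholds), x$combination_id %||% "?",
    x$combination_success %||% NA_real_, 100 * x$fp_rate))
  print(x$thresholds)
  invisible(x)
}

#' @rdname calibrate_record
#' @param x A `psg_calibration`.
#' @param ... Unused.
#' @method tidy psg_calibration
#' @export
tidy.psg_calibration <- function(x, ...) {
  x$thresholds
}

#' @rdname calibrate_record
#' @method glance psg_calibration
#' @export
glance.psg_calibration <- function(x, ...) {
  tibble(
    n_channels = nrow(x$thresholds),
    combination_id = x$combination_id %||% NA_character_,
    combination_success = x$combination_success %||% NA_real_,
    mean_auc = mean(x$thresholds$auc),
    fp_rate = x$fp_rate,
    eeg_r2 = if (is.null(x$regression_eeg)) NA_real_ else x$regression_eeg$r2,
    emg_r2 = if (is.null(x$regression_emg)) NA_real_ else x$regression_emg$r2
  )
}

#' Stage a record with a calibration model
#'
#' Recomputes per-channel band powers, classifies each channel at its
#' calibrated working threshold (FPT), and OR-combines the channels of the
#' calibration's winning combination (or an override).
#'
#' @param rec A [psg_recording()].
#' @param calibration A `psg_calibration`.
#' @param combination Optional combination id `"i"`..`"ix"` overriding the
#'   calibrated winner.
#' @return Tibble with columns `epoch_index` and `sleep` (1 = sleep).
#' @export
stage_record <- function(rec, calibration, combination = NULL) {
  stopifnot(inherits(calibration, "psg_calibration"))
  powers <- staging_band_powers(rec, calibration$eeg_band, calibration$emg_band,
                                calibration$epoch_sec)
  th <- calibration$thresholds
  missing <- setdiff(th$channel, names(powers))
  if (length(missing) > 0) {
    abort(sprintf("Recording lacks calibrated channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  series <- lapply(seq_len(nrow(th)), function(i) {
    threshold_classify(powers[[th$channel[i]]], th$fpt[i])
  })
  names(series) <- th$channel
  combo_id <- combination %||% calibration$combination_id %||% "iii"
  combos <- staging_combinations(stats::setNames(th$role, th$channel))
  labs <- combos[[combo_id]]
  if (is.null(labs)) abort(sprintf("Unknown combination id '%s'.", combo_id))
  tibble(
    epoch_index = seq_along(series[[1]]) - 1L,
    sleep = combine_or(series[labs])
  )
}

#' Calibrate a cohort and fit the pooled threshold regressions
#'
#' Calibrates each record independently, pools the normalized (ROT, FPT)
#' pairs across records -- EEG channels into one set, EMG channels into
#' another -- and fits the two transfer regressions.
#'
#' @param records List of [psg_recording()]s.
#' @param hyps List of matching hypnograms.
#' @param ... Passed to [calibrate_record()].
#' @return List of class `psg_cohort_calibration`: `models` (per-record
#'   calibrations), `regression_eeg`, `regression_emg`, and `points`, the
#'   pooled normalized threshold tibble.
#' @export
calibrate_cohort <- function(records, hyps, ...) {
  stopifnot(length(records) == length(hyps), length(records) >= 1)
  models <- purrr::map2(records, hyps, calibrate_record, ...)
  points <- purrr::imap_dfr(models, function(m, i) {
    th <- m$thresholds
    tibble(
      record = i, channel = th$channel,
      channel_type = ifelse(grepl("^eeg", th$role), "eeg", "emg"),
      rot_norm = pmin(1, pmax(0, th$rot / th$power_max)),
      fpt_norm = pmin(1, pmax(0, th$fpt / th$power_max))
    )
  })
  eeg_pts <- points[points$channel_type == "eeg", ]
  emg_pts <- points[points$channel_type == "emg", ]
  structure(
    list(
      models = models,
      regression_eeg = if (nrow(eeg_pts) >= 3) fit_fpt_regression(eeg_pts, "eeg") else NULL,
      regression_emg = if (nrow(emg_pts) >= 3) fit_fpt_regression(emg_pts, "emg") else NULL,
      points = points
    ),
    class = "psg_cohort_calibration"
  )
}
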