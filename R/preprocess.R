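# Signal conditioning: average reference, equiripple band-pass filtering,
# 30-s epoch segmentation, and ADC-saturation artifact flagging.

#' Re-reference EEG channels to their instantaneous average
#'
#' Subtracts, at every sample, the mean across the supplied EEG channels
#' from each channel. After referencing the across-channel mean is zero
#' everywhere.
#'
#' @param eeg Named list (or plain list) of equal-length numeric vectors.
#' @return List of the same shape with the average removed.
#' @examples
#' average_reference(list(a = c(1, 1), b = c(2, 2), c = c(3, 3)))
#' @export
average_reference <- function(eeg) {
  if (!is.list(eeg) || length(eeg) < 2) {
    abort("Average referencing needs at least 2 channels.")
  }
  lens <- vapply(eeg, length, integer(1))
  if (length(unique(lens)) > 1) abort("Channels must have equal lengths.")
  m <- Reduce(`+`, eeg) / length(eeg)
  lapply(eeg, function(x) x - m)
}

#' Design an equiripple FIR band-pass filter
#'
#' Parks-McClellan (equiripple) design via [signal::remez()], with the
#' filter order estimated from the attenuation/transition-width formula and
#' then grown until the measured frequency response meets the passband
#' ripple and stopband attenuation specs. The defaults are the pipeline's
#' two bands: alpha EEG 8-13 Hz and chin EMG 24-45 Hz at 200 Hz sampling,
#' with 0.5 Hz transition bands, at most 1 dB passband ripple and 40 dB
#' stopband attenuation.
#'
#' @param band Numeric `c(low, high)` passband edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param transition_hz Width of each transition band in Hz.
#' @param passband_ripple_db Maximum allowed passband deviation (dB).
#' @param stopband_atten_db Minimum required stopband attenuation (dB).
#' @param max_order Order cap; an infeasible spec errors, reporting the
#'   ripple actually achieved.
#' @return Numeric coefficient vector of class `psg_fir`, carrying the
#'   design parameters and achieved ripple/attenuation as attributes.
#' @export
design_bandpass <- function(band, fs,
                            transition_hz = 0.5,
                            passband_ripple_db = 1,
                            stopband_atten_db = 40,
                            max_order = 3000) {
  low <- band[1]; high <- band[2]
  if (!(low > 0 && high > low && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < fs/2 (no all-pass designs).")
  }
  if (transition_hz <= 0) abort("transition_hz must be > 0.")
  if (low - transition_hz <= 0 || high + transition_hz >= fs / 2) {
    abort("Transition bands must fit inside (0, fs/2).")
  }
  nyq <- fs / 2
  delta_s <- 10^(-stopband_atten_db / 20)
  # design to half the allowed ripple so that two-pass (zero-phase)
  # application still sits inside the single-pass spec
  delta_p <- (10^(passband_ripple_db / 20) - 1) / 2
  w_stop <- max(1, delta_p / delta_s)
  dw <- 2 * pi * transition_hz / fs
  n <- ceiling((stopband_atten_db - 7.95) / (2.285 * dw))
  n <- n + n %% 2 # even order -> odd length, type-I linear phase

  edges <- c(0, low - transition_hz, low, high, high + transition_hz, nyq) / nyq
  probe_pass <- seq(low, high, length.out = 64)
  probe_stop <- c(seq(0, low - transition_hz, length.out = 32),
                  seq(high + transition_hz, nyq * 0.999, length.out = 32))
  achieved <- NULL
  while (n <= max_order) {
    b <- as.numeric(signal::remez(n, edges, c(0, 0, 1, 1, 0, 0),
                                  w = c(w_stop, 1, w_stop)))
    hp <- filter_response(b, probe_pass, fs)
    hs <- filter_response(b, probe_stop, fs)
    ripple <- max(abs(20 * log10(hp)))
    atten <- -max(20 * log10(pmax(hs, 1e-12)))
    achieved <- c(ripple = ripple, atten = atten)
    if (ripple <= passband_ripple_db && atten >= stopband_atten_db) {
      attr(b, "spec") <- list(
        band = band, fs = fs, transition_hz = transition_hz,
        passband_ripple_db = passband_ripple_db,
        stopband_atten_db = stopband_atten_db,
        achieved_ripple_db = ripple, achieved_atten_db = atten,
        kind = "equiripple FIR"
      )
      class(b) <- c("psg_fir", "numeric")
      return(b)
    }
    n <- ceiling(n * 1.25)
    n <- n + n %% 2
  }
  abort(sprintf(
    "Filter spec infeasible within order cap %d (achieved ripple %.3f dB, attenuation %.1f dB).",
    max_order, achieved[["ripple"]], achieved[["atten"]]
  ))
}

#' Magnitude frequency response of an FIR filter
#'
#' Direct evaluation of |H(f)| = |sum_k b_k exp(-2 pi i f k / fs)|.
#'
#' @param coef FIR coefficients.
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of magnitudes (linear scale).
#' @export
filter_response <- function(coef, freq_hz, fs) {
  k <- 0:(length(coef) - 1)
  vapply(freq_hz, function(f) {
    Mod(sum(as.numeric(coef) * exp(-2i * pi * f / fs * k)))
  }, numeric(1))
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application, implemented exactly as one FFT convolution
#' with the symmetric kernel `conv(b, rev(b))` and the group delay removed,
#' so no epoch boundary is phase-shifted and band power stays attributed to
#' the epoch it occurred in. Output has the input's length.
#'
#' @param x Numeric signal, longer than the filter.
#' @param coef FIR coefficients from [design_bandpass()].
#' @return Filtered signal, same length as `x`.
#' @export
apply_filter <- function(x, coef) {
  b <- as.numeric(coef)
  n <- length(x); m <- length(b)
  if (n <= m) abort("Signal must be longer than the filter.")
  g <- stats::convolve(b, b, type = "open") # conv(b, rev(b)), zero-phase kernel
  L <- n + length(g) - 1
  nfft <- stats::nextn(L, c(2, 3, 5))
  X <- fft(c(x, numeric(nfft - n)))
  G <- fft(c(g, numeric(nfft - length(g))))
  y_full <- Re(fft(X * G, inverse = TRUE)) / nfft
  y_full[m:(m + n - 1)]
}

# ---- epoch grid ------------------------------------------------------------

#' Epoch grid
#'
#' Describes the 30-s AASM epoch segmentation of a record: epoch count,
#' epoch duration, sampling rate, and the per-epoch usable mask that
#' artifact flagging updates.
#'
#' @param n_epochs Number of complete epochs.
#' @param fs Sampling rate in Hz.
#' @param epoch_sec Epoch duration in seconds.
#' @param usable Logical per-epoch mask.
#' @return An object of class `psg_epoch_grid`.
#' @export
epoch_grid <- function(n_epochs, fs, epoch_sec = 30,
                       usable = rep(TRUE, n_epochs)) {
  stopifnot(n_epochs >= 1, length(usable) == n_epochs)
  structure(
    list(n_epochs = as.integer(n_epochs), epoch_sec = epoch_sec,
         fs = fs, usable = usable),
    class = "psg_epoch_grid"
  )
}

#' @export
print.psg_epoch_grid <- function(x, ...) {
  cat(sprintf("<psg_epoch_grid> %d x %gs epochs, %d usable\n",
              x$n_epochs, x$epoch_sec, sum(x$usable)))
  invisible(x)
}

#' Split a signal into scoring epochs
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; `fs * epoch_sec` must be integral.
#' @param epoch_sec Epoch duration (30 s for AASM scoring).
#' @return List with `blocks`, a `(fs*epoch_sec) x n_epochs` matrix (any
#'   trailing partial epoch is discarded), and `grid`, the matching
#'   [epoch_grid()].
#' @export
split_epochs <- function(x, fs, epoch_sec = 30) {
  spe <- fs * epoch_sec
  if (abs(spe - round(spe)) > 1e-9) abort("fs * epoch_sec must be integral.")
  spe <- as.integer(round(spe))
  n_epochs <- length(x) %/% spe
  if (n_epochs < 1) abort("Signal shorter than one epoch.")
  blocks <- matrix(x[seq_len(n_epochs * spe)], nrow = spe)
  list(blocks = blocks, grid = epoch_grid(n_epochs, fs, epoch_sec))
}

#' Flag ADC-saturation artifact epochs
#'
#' Computes the channel's full-record amplitude range R = max - min and
#' marks any sample in the top or bottom 1% band of that range (above
#' `max - 0.01 R` or below `min + 0.01 R`) as an artifact; an epoch
#' containing at least one such sample is flagged unusable in its entirety.
#' When the channel's ADC limits are known, a band is only active if the
#' corresponding extreme actually touches the ADC rail -- the artifacts
#' this rule targets are saturation events, and a channel that never
#' saturates should not lose its extremes. Intended for the flow, effort,
#' and SpO2 channels.
#'
#' @param x Numeric channel signal.
#' @param grid An [epoch_grid()] for this record; its `usable` mask is
#'   intersected with the new flags (so the operation is idempotent and
#'   composable across channels).
#' @param adc_limits Optional `c(min, max)` representable amplitude.
#' @return The grid with its `usable` mask updated.
#' @export
flag_artifact_epochs <- function(x, grid, adc_limits = NULL) {
  stopifnot(inherits(grid, "psg_epoch_grid"))
  lo <- min(x); hi <- max(x)
  R <- hi - lo
  if (R == 0) {
    warn("Constant signal: amplitude range is zero, no artifact epochs flagged.")
    return(grid)
  }
  tol <- 1e-9 * max(1, abs(hi), abs(lo))
  upper_active <- is.null(adc_limits) || hi >= adc_limits[2] - tol
  lower_active <- is.null(adc_limits) || lo <= adc_limits[1] + tol
  bad <- logical(length(x))
  if (upper_active) bad <- bad | (x > hi - 0.01 * R)
  if (lower_active) bad <- bad | (x < lo + 0.01 * R)
  spe <- as.integer(round(grid$fs * grid$epoch_sec))
  ep <- (seq_along(x) - 1L) %/% spe
  keep <- ep < grid$n_epochs
  flagged <- unique(ep[keep][bad[keep]])
  grid$usable[flagged + 1L] <- FALSE
  grid
}
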