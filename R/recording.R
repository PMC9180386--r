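#' Multichannel PSG recording
#'
#' A `psg_recording` bundles the raw signals of one polysomnography exam:
#' a named list of equal-length sample vectors, one shared sampling rate,
#' a role tag per channel (which physiological signal it carries), and
#' optionally the representable amplitude range of the acquisition ADC per
#' channel. All downstream operations (filtering, band power, envelopes,
#' event scoring) consume this container.
#'
#' @param channels Named list of numeric vectors, one per channel. All must
#'   have the same length.
#' @param fs Sampling rate in Hz, shared by every channel.
#' @param roles Named character vector mapping channel labels to role tags.
#'   Valid tags: `eeg_occipital`, `eeg_frontal`, `eeg_central`, `emg_chin`,
#'   `flow_pressure`, `effort_thorax`, `effort_abdomen`, `spo2`.
#' @param adc_limits Optional named list mapping channel labels to
#'   `c(min, max)` representable amplitudes. Used by artifact flagging.
#'
#' @return An object of class `psg_recording`.
#' @examples
#' rec <- psg_recording(
#'   channels = list(O1 = sin(seq(0, 2 * pi, length.out = 400))),
#'   fs = 200, roles = c(O1 = "eeg_occipital")
#' )
#' n_samples(rec)
#' @export
psg_recording <- function(channels, fs, roles, adc_limits = NULL) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a named list of sample vectors.")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    abort(sprintf(
      "All channels must have the same length (got %s).",
      paste(unique(lens), collapse = ", ")
    ))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  roles <- validate_roles(roles, names(channels))
  if (!is.null(adc_limits)) {
    stopifnot(is.list(adc_limits))
    bad <- setdiff(names(adc_limits), names(channels))
    if (length(bad) > 0) {
      abort(sprintf("adc_limits given for unknown channel(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      channels = lapply(channels, as.numeric),
      fs = as.numeric(fs),
      roles = roles,
      adc_limits = adc_limits
    ),
    class = "psg_recording"
  )
}

validate_roles <- function(roles, labels) {
  if (is.null(names(roles)) || any(names(roles) == "")) {
    abort("`roles` must be a named character vector (label -> role).")
  }
  bad_role <- setdiff(unname(roles), psg_role_levels)
  if (length(bad_role) > 0) {
    abort(sprintf("Unknown role tag(s): %s. Valid: %s",
                  paste(unique(bad_role), collapse = ", "),
                  paste(psg_role_levels, collapse = ", ")))
  }
  missing_lab <- setdiff(names(roles), labels)
  if (length(missing_lab) > 0) {
    abort(sprintf("Role map names channel(s) not present: %s",
                  paste(missing_lab, collapse = ", ")))
  }
  roles
}

#' @export
print.psg_recording <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf(
    "<psg_recording> %d channel(s), %d samples @ %g Hz (%.1f min)\n",
    length(x$channels), n, x$fs, n / x$fs / 60
  ))
  for (lab in names(x$channels)) {
    cat(sprintf("  %-8s %s\n", lab, x$roles[[lab]] %||% "?"))
  }
  invisible(x)
}

#' Number of samples per channel of a recording
#' @param rec A `psg_recording`.
#' @return Integer sample count (identical across channels).
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "psg_recording"))
  if (length(rec$channels) == 0) return(0L)
  length(rec$channels[[1]])
}

#' Channel labels carrying a given role
#'
#' @param rec A `psg_recording`.
#' @param role One or more role tags.
#' @return Character vector of channel labels (possibly empty).
#' @export
channels_with_role <- function(rec, role) {
  stopifnot(inherits(rec, "psg_recording"))
  names(rec$roles)[rec$roles %in% role]
}

#' Check that mandatory channel roles are present
#'
#' Errors, naming the first missing role, if the recording lacks a channel
#' for any of the requested roles. The default set is what the full
#' staging + event-scoring pipeline needs: the six EEG derivations
#' (occipital, frontal, central), nasal-pressure flow, and SpO2.
#'
#' @param rec A `psg_recording`.
#' @param required Character vector of role tags that must each map to at
#'   least one channel.
#' @return `rec`, invisibly, for piping.
#' @export
require_roles <- function(rec, required = psg_mandatory_roles) {
  for (role in required) {
    if (length(channels_with_role(rec, role)) == 0) {
      abort(sprintf("Recording is missing a channel with mandatory role '%s'.", role))
    }
  }
  invisible(rec)
}

# First channel with a role, or NULL.
role_channel <- function(rec, role) {
  labs <- channels_with_role(rec, role)
  if (length(labs) == 0) return(NULL)
  labs[[1]]
}
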