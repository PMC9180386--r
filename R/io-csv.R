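# Plain-text PSG dialect: one CSV per channel inside a directory.
#
# Each channel file has a two-line metadata block followed by a value column:
#   label,fs,role,adc_min,adc_max
#   O1,200,eeg_occipital,NA,NA
#   value
#   0.1234
#   ...
# This keeps fixtures human-readable and exactly round-trippable.

#' Write a recording as per-channel CSV files
#'
#' @param rec A [psg_recording()].
#' @param dir Output directory (created if absent); one `<label>.csv` per
#'   channel.
#' @return `dir`, invisibly.
#' @export
write_psg_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "psg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (lab in names(rec$channels)) {
    lim <- rec$adc_limits[[lab]]
    meta <- c(
      "label,fs,role,adc_min,adc_max",
      sprintf("%s,%s,%s,%s,%s", lab, format(rec$fs, digits = 17),
              rec$roles[[lab]],
              if (is.null(lim)) "NA" else format(lim[1], digits = 17),
              if (is.null(lim)) "NA" else format(lim[2], digits = 17)),
      "value",
      format(rec$channels[[lab]], digits = 17, trim = TRUE, scientific = FALSE)
    )
    writeLines(meta, file.path(dir, paste0(lab, ".csv")))
  }
  invisible(dir)
}

#' Read a per-channel CSV directory into a recording
#'
#' @param dir Directory holding `<label>.csv` channel files as written by
#'   [write_psg_csv()].
#' @param role_map Optional named character vector label -> role overriding
#'   the roles stored in the files; unmapped channels are dropped when a map
#'   is given.
#' @param required Roles that must be present; `character()` disables the
#'   check.
#' @return A [psg_recording()].
#' @export
read_psg_csv <- function(dir, role_map = NULL, required = psg_mandatory_roles) {
  if (!dir.exists(dir)) abort(sprintf("No such directory: %s", dir))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  if (length(files) == 0) abort(sprintf("No channel CSV files in %s", dir))
  channels <- list(); roles <- character(); fs <- numeric(); adc <- list()
  for (f in files) {
    lines <- readLines(f, n = 2)
    meta <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    lab <- meta[1]
    fs <- c(fs, as.numeric(meta[2]))
    roles[lab] <- meta[3]
    if (meta[4] != "NA") adc[[lab]] <- c(as.numeric(meta[4]), as.numeric(meta[5]))
    channels[[lab]] <- scan(f, what = numeric(), skip = 3, quiet = TRUE)
  }
  if (length(unique(fs)) != 1) {
    abort(sprintf("Channel files disagree on fs: %s", paste(unique(fs), collapse = ", ")))
  }
  if (!is.null(role_map)) {
    keep <- intersect(names(role_map), names(channels))
    if (length(keep) == 0) abort("role_map matches no channel file.")
    channels <- channels[keep]
    roles <- role_map[keep]
    adc <- adc[intersect(names(adc), keep)]
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    abort("Channel files have unequal sample counts.")
  }
  rec <- psg_recording(channels, fs = fs[1], roles = roles,
                       adc_limits = if (length(adc)) adc else NULL)
  require_roles(rec, required)
  rec
}

#' Read a PSG recording (EDF file or CSV directory)
#'
#' Dispatches on `path`: a directory is read with [read_psg_csv()], a file
#' with [read_psg_edf()].
#'
#' @inheritParams read_psg_edf
#' @return A [psg_recording()].
#' @export
read_recording <- function(path, role_map = NULL, required = psg_mandatory_roles) {
  if (dir.exists(path)) {
    read_psg_csv(path, role_map, required)
  } else {
    if (is.null(role_map)) abort("Reading EDF requires a role_map.")
    read_psg_edf(path, role_map, required)
  }
}

# ---- hypnogram -------------------------------------------------------------

psg_stage_levels <- c("W", "N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is a tibble with one row per 30-s scoring epoch and columns
#' `epoch_index` (0-based, contiguous) and `stage` (one of W, N1, N2, N3,
#' REM). The awake/sleep binarization collapses every non-W stage to sleep.
#'
#' @param stages Character vector of stage tokens.
#' @param epoch_sec Epoch duration in seconds.
#' @return A tibble of class `psg_hypnogram`.
#' @export
hypnogram <- function(stages, epoch_sec = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), psg_stage_levels)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage token(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble(epoch_index = seq_along(stages) - 1L, stage = stages)
  class(out) <- c("psg_hypnogram", class(out))
  attr(out, "epoch_sec") <- epoch_sec
  out
}

#' Binarize a hypnogram to awake (0) / sleep (1)
#'
#' Stages N1, N2, N3 and REM are combined into a single sleep state.
#'
#' @param hyp A `psg_hypnogram` (or anything with a `stage` column).
#' @return Integer vector, 0 = awake, 1 = sleep, one entry per epoch.
#' @export
binarize_stages <- function(hyp) {
  as.integer(hyp$stage != "W")
}

#' Read a hypnogram CSV
#'
#' Expects columns `epoch_index` (0-based, contiguous) and `stage`.
#' Gaps, duplicates, or unknown stage tokens are errors.
#'
#' @param path CSV path.
#' @return A `psg_hypnogram` tibble.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    abort("Hypnogram CSV must have columns epoch_index, stage.")
  }
  idx <- as.integer(df$epoch_index)
  expected <- seq_len(nrow(df)) - 1L
  if (!identical(idx, expected)) {
    abort("epoch_index must be contiguous and 0-based (gap or duplicate found).")
  }
  hypnogram(df$stage)
}

#' Write a hypnogram CSV
#' @param hyp A `psg_hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  write.csv(as.data.frame(hyp[, c("epoch_index", "stage")]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- event lists -----------------------------------------------------------

psg_event_types <- c("obstructive_apnea", "central_apnea", "hypopnea")

#' Write a respiratory event list to CSV
#'
#' Columns written: `onset_sec`, `duration_sec`, `type`, `epoch_index`,
#' sorted by onset. Re-reading with [read_events()] reproduces the list.
#'
#' @param events Tibble with at least those four columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  need <- c("onset_sec", "duration_sec", "type", "epoch_index")
  if (!all(need %in% names(events))) {
    abort(sprintf("Event list must have columns: %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(events$type), psg_event_types)
  if (length(bad) > 0) {
    abort(sprintf("Unknown event type(s): %s", paste(bad, collapse = ", ")))
  }
  ev <- events[order(events$onset_sec), need, drop = FALSE]
  lines <- c(
    paste(need, collapse = ","),
    if (nrow(ev) > 0) {
      sprintf("%s,%s,%s,%d",
              format(ev$onset_sec, digits = 17, trim = TRUE, scientific = FALSE),
              format(ev$duration_sec, digits = 17, trim = TRUE, scientific = FALSE),
              ev$type, as.integer(ev$epoch_index))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a respiratory event list from CSV
#' @param path CSV path as written by [write_events()].
#' @return Tibble with columns onset_sec, duration_sec, type, epoch_index.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(onset_sec = "numeric", duration_sec = "numeric",
                                type = "character", epoch_index = "integer"))
  bad <- setdiff(unique(df$type), psg_event_types)
  if (length(bad) > 0) {
    abort(sprintf("Unknown event type(s): %s", paste(bad, collapse = ", ")))
  }
  as_tibble(df)
}
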