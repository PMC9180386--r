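# Calibration files: versioned key/value text, losslessly round-trippable.

calibration_schema_version <- 1L

fmt17 <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)

#' Write a calibration model to a structured text file
#'
#' Serializes every per-channel threshold (ROT, FPT, power maximum, AUC),
#' the pooled FPT-vs-ROT regressions, and the winning channel combination
#' with full floating-point precision, so [read_calibration()] reproduces
#' the model exactly.
#'
#' @param model A `psg_calibration` (see [calibrate_record()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "psg_calibration"))
  th <- model$thresholds
  reg_line <- function(r, extra = character()) {
    if (is.null(r)) return("none")
    paste(c(fmt17(r$slope), fmt17(r$intercept), fmt17(r$r2), extra), collapse = " ")
  }
  lines <- c(
    sprintf("schema_version: %d", calibration_schema_version),
    sprintf("fs: %s", fmt17(model$fs)),
    sprintf("epoch_sec: %s", fmt17(model$epoch_sec)),
    sprintf("eeg_band: %s %s", fmt17(model$eeg_band[1]), fmt17(model$eeg_band[2])),
    sprintf("emg_band: %s %s", fmt17(model$emg_band[1]), fmt17(model$emg_band[2])),
    sprintf("fp_rate: %s", fmt17(model$fp_rate)),
    sprintf("n_thresholds: %d", model$n_thresholds),
    sprintf("combination_id: %s", model$combination_id %||% "none"),
    sprintf("combination_success: %s",
            if (is.null(model$combination_success)) "none" else fmt17(model$combination_success)),
    sprintf("n_channels: %d", nrow(th)),
    sprintf("channel: %s %s %s %s %s %s",
            th$channel, th$role, fmt17(th$rot), fmt17(th$fpt),
            fmt17(th$power_max), fmt17(th$auc)),
    sprintf("regression_eeg: %s",
            reg_line(model$regression_eeg,
                     if (!is.null(model$regression_eeg))
                       fmt17(model$regression_eeg$rot_norm_cutoff %||% 0.6))),
    sprintf("regression_emg: %s", reg_line(model$regression_emg))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration model from file
#'
#' @param path Path written by [write_calibration()].
#' @return A `psg_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  get1 <- function(key, required = TRUE) {
    i <- which(keys == key)
    if (length(i) == 0) {
      if (required) abort(sprintf("Calibration file missing '%s' block.", key))
      return(NULL)
    }
    vals[i[1]]
  }
  ver <- suppressWarnings(as.integer(get1("schema_version")))
  if (is.na(ver) || ver != calibration_schema_version) {
    abort(sprintf("Calibration schema version mismatch: file has '%s', expected %d.",
                  get1("schema_version"), calibration_schema_version))
  }
  nums <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  ch_lines <- vals[keys == "channel"]
  n_ch <- as.integer(get1("n_channels"))
  if (length(ch_lines) != n_ch) {
    abort(sprintf("Calibration file declares %d channels but lists %d.",
                  n_ch, length(ch_lines)))
  }
  parts <- strsplit(ch_lines, " ", fixed = TRUE)
  th <- tibble(
    channel = vapply(parts, `[`, "", 1),
    role = vapply(parts, `[`, "", 2),
    rot = as.numeric(vapply(parts, `[`, "", 3)),
    fpt = as.numeric(vapply(parts, `[`, "", 4)),
    power_max = as.numeric(vapply(parts, `[`, "", 5)),
    auc = as.numeric(vapply(parts, `[`, "", 6))
  )
  parse_reg <- function(key, eeg = FALSE) {
    s <- get1(key) # required: absence is a schema error
    if (s == "none") return(NULL)
    v <- nums(s)
    out <- list(slope = v[1], intercept = v[2], r2 = v[3])
    if (eeg) out$rot_norm_cutoff <- v[4]
    out
  }
  comb <- get1("combination_id")
  comb_succ <- get1("combination_success")
  structure(
    list(
      thresholds = th,
      regression_eeg = parse_reg("regression_eeg", eeg = TRUE),
      regression_emg = parse_reg("regression_emg"),
      combination_id = if (comb == "none") NULL else comb,
      combination_success = if (comb_succ == "none") NULL else as.numeric(comb_succ),
      fp_rate = as.numeric(get1("fp_rate")),
      n_thresholds = as.integer(get1("n_thresholds")),
      eeg_band = nums(get1("eeg_band")),
      emg_band = nums(get1("emg_band")),
      epoch_sec = as.numeric(get1("epoch_sec")),
      fs = as.numeric(get1("fs"))
    ),
    class = "psg_calibration"
  )
}
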