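# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a fixed 256-byte ASCII header, one 256-byte ASCII header per
# signal, then interleaved data records of 16-bit little-endian integers.
# Physical values are recovered by the linear map
#   phys = phys_min + (dig - dig_min) * (phys_max - phys_min)/(dig_max - dig_min).
# When samples are integral and fit the 16-bit range we write an identity
# digital/physical map, so integer-valued recordings round-trip exactly;
# arbitrary floats round-trip to within one 16-bit quantization step of the
# channel's physical range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  # densest representation that fits the fixed-width ASCII field
  for (d in 10:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  edf_pad(substr(s, 1, width), width)
}

#' Write a recording to an EDF file
#'
#' @param rec A [psg_recording()].
#' @param path Output file path.
#' @param record_duration_sec Length of one EDF data record; the recording is
#'   truncated to a whole number of records.
#' @return `path`, invisibly.
#' @export
write_psg_edf <- function(rec, path, record_duration_sec = 1) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  spr <- fs * record_duration_sec
  if (abs(spr - round(spr)) > 1e-9) {
    abort("fs * record_duration_sec must be an integer number of samples.")
  }
  spr <- as.integer(round(spr))
  ns <- length(rec$channels)
  n <- n_samples(rec)
  n_rec <- n %/% spr
  if (n_rec < 1) abort("Recording shorter than one EDF data record.")

  # per-channel scaling
  scale <- lapply(names(rec$channels), function(lab) {
    x <- rec$channels[[lab]][seq_len(n_rec * spr)]
    lim <- rec$adc_limits[[lab]]
    integral <- all(abs(x - round(x)) < 1e-9)
    if (integral && min(x) >= -32768 && max(x) <= 32767) {
      list(pmin = -32768, pmax = 32767, identity = TRUE)
    } else {
      pmin <- if (!is.null(lim)) lim[1] else min(x)
      pmax <- if (!is.null(lim)) lim[2] else max(x)
      if (pmax <= pmin) pmax <- pmin + 1
      # quantize against the values the 8-char header fields actually store,
      # so the reader reconstructs with the writer's scaling
      pmin <- as.numeric(trimws(edf_num(pmin, 8)))
      pmax <- as.numeric(trimws(edf_num(pmax, 8)))
      list(pmin = pmin, pmax = pmax, identity = FALSE)
    }
  })
  names(scale) <- names(rec$channels)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(record_duration_sec, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(names(rec$channels), edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(scale, function(s) edf_num(s$pmin, 8), ""),
    vapply(scale, function(s) edf_num(s$pmax, 8), ""),
    rep(edf_pad(-32768, 8), ns),
    rep(edf_pad(32767, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste(unlist(fields), collapse = ""), con, eos = NULL)

  dig <- matrix(0L, nrow = spr * ns, ncol = n_rec)
  for (j in seq_len(ns)) {
    s <- scale[[j]]
    x <- rec$channels[[j]][seq_len(n_rec * spr)]
    d <- if (s$identity) {
      as.integer(round(x))
    } else {
      g <- (s$pmax - s$pmin) / 65535
      as.integer(pmin(32767, pmax(-32768, round((x - s$pmin) / g) - 32768)))
    }
    dig[(j - 1) * spr + seq_len(spr), ] <- matrix(d, nrow = spr)
  }
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path Path to an EDF file.
#' @param role_map Named character vector mapping channel labels (as stored
#'   in the EDF signal headers) to role tags; unmapped channels are ignored.
#' @param required Roles that must be present after mapping; defaults to the
#'   full pipeline's mandatory set. Use `character()` to skip the check.
#' @return A [psg_recording()].
#' @export
read_psg_edf <- function(path, role_map, required = psg_mandatory_roles) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  fs_all <- spr / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2, endian = "little")
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  channels <- list()
  for (j in seq_len(ns)) {
    idx <- as.vector(outer(offs[j] + seq_len(spr[j]), (seq_len(n_rec) - 1L) * per_rec, "+"))
    d <- raw[idx]
    g <- (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    channels[[labels[j]]] <- pmin[j] + (d - dmin[j]) * g
  }
  keep <- intersect(names(role_map), labels)
  if (length(keep) == 0) abort("role_map matches no channel in the EDF file.")
  fs <- unique(fs_all[match(keep, labels)])
  if (length(fs) != 1) {
    abort(sprintf("Mapped channels have unequal sampling rates: %s",
                  paste(fs, collapse = ", ")))
  }
  rec <- psg_recording(channels[keep], fs = fs, roles = role_map[keep])
  require_roles(rec, required)
  rec
}
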