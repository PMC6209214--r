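# Minimal European Data Format (EDF) support: enough to round-trip the
# package's own multichannel records (continuous recording, identical
# sampling rate on every channel, 1-second data records, 16-bit samples).
# No R EDF package is available in the supported dependency set, so the
# fixed-layout header and int16 payload are handled directly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

# fixed physical scaling: +/- 3276.8 uV mapped onto the int16 range, i.e.
# 0.1 uV quantization, comfortably finer than the 0.5 uV round-trip budget
EDF_PHYS_MAX <- 3276.7
EDF_PHYS_MIN <- -3276.8

#' Write an EEG record as EDF
#'
#' Writes a continuous European Data Format file with one 1-second data
#' record per second of signal, all channels at the record's sampling rate,
#' physical units microvolts, and a fixed +/-3276.8 uV physical range
#' (0.1 uV quantization). The record is truncated to a whole number of
#' seconds, values outside the physical range are clipped.
#'
#' @param eeg An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_record"))
  fs <- as.integer(round(eeg$fs))
  ns <- nrow(eeg$samples)
  n_rec <- floor(ncol(eeg$samples) / fs)
  if (n_rec < 1) abort("Record shorter than one EDF data record (1 s).")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  field <- function(vals, width) {
    paste(vapply(vals, edf_pad, character(1), width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(eeg$labels, 16),
    field(rep("", ns), 80),                 # transducer
    field(rep("uV", ns), 8),                # physical dimension
    field(rep(format(EDF_PHYS_MIN), ns), 8),
    field(rep(format(EDF_PHYS_MAX), ns), 8),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),                 # prefiltering
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (32767 - (-32768)) / (EDF_PHYS_MAX - EDF_PHYS_MIN)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- t(eeg$samples[, idx, drop = FALSE]) # samples x channels
    dig <- round((clip(block, EDF_PHYS_MIN, EDF_PHYS_MAX) - EDF_PHYS_MIN) *
                   scale) - 32768
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' Supports the continuous-recording subset written by [write_edf()]:
#' equal sampling rates across channels and an integer number of samples per
#' data record. Annotations channels are not supported.
#'
#' @param path EDF file path.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(spr)) != 1) {
    abort("Only EDF files with a single sampling rate across channels are supported.")
  }
  fs <- spr[1] / rec_dur
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      samples[ch, idx] <- (dig - dig_min[ch]) * gain[ch] + phys_min[ch]
    }
  }
  eeg_record(samples, fs, labels = labels)
}
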