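#' Standard 10-20 scalp electrode labels
#'
#' The nineteen-electrode montage of the international 10-20 system, in the
#' order conventionally used for clinical recordings.
#'
#' @return Character vector of length 19.
#' @export
ten_twenty_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Multichannel EEG record
#'
#' Lightweight container for multichannel sampled voltage. Channels are rows
#' of `samples`; values are in microvolts. Sampling rates other than the
#' clinical 256 / 512 Hz are accepted with a warning.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (10-20 names for clinical data). Defaults to
#'   the first `nrow(samples)` labels of [ten_twenty_labels()].
#' @param start_time Record start, seconds. All package time axes are seconds
#'   from record start.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, labels = NULL, start_time = 0) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  if (is.null(labels)) {
    labels <- if (nrow(samples) <= 19) {
      ten_twenty_labels()[seq_len(nrow(samples))]
    } else {
      paste0("CH", seq_len(nrow(samples)))
    }
  }
  if (length(labels) != nrow(samples)) {
    abort("`labels` must have one entry per channel.")
  }
  if (!fs %in% c(256, 512)) {
    warn(sprintf("Sampling rate %g Hz is outside the clinical 256/512 Hz convention.", fs))
  }
  structure(
    list(samples = samples, fs = fs, labels = as.character(labels),
         start_time = start_time),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of an EEG record in seconds
#' @param eeg An [eeg_record()].
#' @return Duration in seconds.
#' @export
eeg_duration <- function(eeg) ncol(eeg$samples) / eeg$fs

#' Global binary suppression signal
#'
#' Per-sample indicator of the EEG state (1 = suppression, 0 = burst)
#' together with a per-epoch validity mask from artifact rejection. Values in
#' masked (invalid) epochs carry no information.
#'
#' @param values Integer/logical vector, one element per sample; 1 marks
#'   suppression, 0 marks burst.
#' @param fs Sampling rate in Hz.
#' @param mask Logical per-epoch validity mask (TRUE = valid). Defaults to
#'   all-valid.
#' @param epoch_len Epoch length in seconds (half-open epochs
#'   `[k*epoch_len, (k+1)*epoch_len)`).
#' @return An object of class `binary_signal`.
#' @export
binary_signal <- function(values, fs, mask = NULL, epoch_len = 1) {
  values <- as.integer(values)
  if (any(!values %in% c(0L, 1L))) {
    abort("`values` must contain only 0 (burst) and 1 (suppression).")
  }
  n_epochs <- n_epochs_for(length(values), fs, epoch_len)
  if (is.null(mask)) mask <- rep(TRUE, n_epochs)
  if (length(mask) != n_epochs) {
    abort(sprintf("`mask` must have one entry per epoch (%d expected).", n_epochs))
  }
  structure(
    list(values = values, fs = fs, mask = as.logical(mask),
         epoch_len = epoch_len),
    class = "binary_signal"
  )
}

#' @export
print.binary_signal <- function(x, ...) {
  cat(sprintf("<binary_signal> %d samples @ %g Hz, %d/%d epochs valid, %.1f%% suppressed\n",
              length(x$values), x$fs, sum(x$mask), length(x$mask),
              100 * mean(x$values)))
  invisible(x)
}

# number of (possibly partial) epochs covering n samples
n_epochs_for <- function(n_samples, fs, epoch_len) {
  as.integer(ceiling(n_samples / (fs * epoch_len)))
}

# 0-based epoch index of each sample (half-open convention)
sample_epoch_index <- function(n_samples, fs, epoch_len) {
  as.integer(floor((seq_len(n_samples) - 1) / (fs * epoch_len)))
}
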