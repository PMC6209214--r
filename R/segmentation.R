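# Zero-phase FFT band-pass with raised-cosine transitions. Mirror padding
# (5 s or record length, whichever is shorter) limits edge transients; the
# padded mean is removed first so a constant input maps exactly to zero.
fft_bandpass_vec <- function(x, fs, lo, hi, trans_lo = NULL, trans_hi = NULL) {
  n <- length(x)
  if (n == 0) return(x)
  trans_lo <- trans_lo %||% (lo / 2)
  trans_hi <- trans_hi %||% min(5, (fs / 2 - hi) / 2)
  pad <- min(n, as.integer(round(5 * fs)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  mu <- mean(xp)
  xp <- xp - mu
  nfft <- nextn(length(xp))
  xp <- c(xp, rep(0, nfft - length(xp)))
  f <- (seq_len(nfft) - 1) / nfft * fs
  f <- pmin(f, fs - f) # two-sided spectrum, symmetric response
  H <- rep(1, nfft)
  lo0 <- max(lo - trans_lo, 0)
  H[f <= lo0] <- 0
  rl <- f > lo0 & f < lo
  H[rl] <- 0.5 * (1 - cos(pi * (f[rl] - lo0) / (lo - lo0)))
  hi1 <- hi + trans_hi
  H[f >= hi1] <- 0
  rh <- f > hi & f < hi1
  H[rh] <- 0.5 * (1 + cos(pi * (f[rh] - hi) / trans_hi))
  y <- Re(fft(fft(xp) * H, inverse = TRUE)) / nfft
  y[(pad + 1):(pad + n)]
}

#' Re-reference an EEG record to the average montage
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the result is zero. Idempotent. A single
#' channel is rejected: the average reference is undefined.
#'
#' @param eeg An [eeg_record()] with at least two channels.
#' @return The re-referenced [eeg_record()].
#' @export
apply_average_montage <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (nrow(eeg$samples) < 2) {
    abort("Average montage needs at least 2 channels.")
  }
  eeg$samples <- sweep(eeg$samples, 2, colMeans(eeg$samples))
  eeg
}

#' Band-pass filter an EEG record
#'
#' Zero-phase frequency-domain band-pass (default 0.5-55 Hz, the clinical
#' preprocessing band). The passband gain is unity; stopband energy,
#' including any DC offset, is removed.
#'
#' @param eeg An [eeg_record()].
#' @param lo,hi Band edges in Hz; `hi` must be below Nyquist.
#' @return The filtered [eeg_record()].
#' @export
eeg_bandpass <- function(eeg, lo = 0.5, hi = 55) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (hi >= eeg$fs / 2) {
    abort(sprintf("Upper edge %g Hz is not below Nyquist (%g Hz).",
                  hi, eeg$fs / 2))
  }
  if (lo <= 0 || lo >= hi) abort("Need 0 < lo < hi.")
  for (ch in seq_len(nrow(eeg$samples))) {
    eeg$samples[ch, ] <- fft_bandpass_vec(eeg$samples[ch, ], eeg$fs, lo, hi)
  }
  eeg
}

#' Reject high-amplitude epochs
#'
#' Marks an epoch invalid when any sample on any channel exceeds the
#' amplitude threshold in absolute value within the half-open epoch
#' `[k * epoch_len, (k + 1) * epoch_len)`.
#'
#' @param eeg An [eeg_record()].
#' @param thresh Rejection threshold in microvolts (default 500).
#' @param epoch_len Epoch length in seconds.
#' @return Logical vector, one entry per epoch; TRUE = valid.
#' @export
reject_artifacts <- function(eeg, thresh = 500, epoch_len = 1) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (thresh <= 0) abort("`thresh` must be positive.")
  n <- ncol(eeg$samples)
  n_ep <- n_epochs_for(n, eeg$fs, epoch_len)
  if (n == 0) return(logical(0))
  exceed <- colSums(abs(eeg$samples) > thresh) > 0
  idx <- sample_epoch_index(n, eeg$fs, epoch_len)
  mask <- rep(TRUE, n_ep)
  mask[unique(idx[exceed]) + 1L] <- FALSE
  mask
}

#' Binarize one preprocessed EEG channel into burst/suppression
#'
#' A rectified-amplitude envelope `e_t = beta * e_{t-1} + (1 - beta) * |v_t|`
#' (exponential moving average with time constant `tau_s`) is thresholded
#' with hysteresis: the channel enters suppression when the envelope falls
#' below `theta * (1 - hysteresis)` and returns to burst when it rises above
#' `theta * (1 + hysteresis)`. Runs of either state shorter than `min_dur`
#' are merged into their neighbours (except at the record edges).
#'
#' @param x Numeric vector: one channel, already montaged and band-passed,
#'   in microvolts.
#' @param fs Sampling rate, Hz.
#' @param theta Suppression amplitude threshold in microvolts.
#' @param tau_s Envelope time constant in seconds. The default 0.2 s tracks
#'   transitions to within half the minimum state duration; see the methods
#'   vignette for why a multi-second constant is too sluggish for
#'   second-scale bursts.
#' @param min_dur Minimum state duration in seconds.
#' @param hysteresis Relative half-width of the hysteresis band around
#'   `theta`.
#' @return Integer vector of per-sample states (1 = suppression, 0 = burst).
#' @export
binarize_channel <- function(x, fs, theta = 5, tau_s = 0.2, min_dur = 0.5,
                             hysteresis = 0.2) {
  if (theta <= 0) abort("`theta` must be positive.")
  n <- length(x)
  if (n == 0) return(integer(0))
  beta <- exp(-1 / (fs * tau_s))
  e <- as.numeric(stats::filter((1 - beta) * abs(x), beta,
                                method = "recursive", init = abs(x[1])))
  lo <- theta * (1 - hysteresis)
  hi <- theta * (1 + hysteresis)

  # hysteresis state machine, vectorized by carrying the last crossing forward
  s <- rep(NA_integer_, n)
  s[e < lo] <- 1L
  s[e > hi] <- 0L
  if (is.na(s[1])) s[1] <- if (e[1] < theta) 1L else 0L
  known <- which(!is.na(s))
  s <- s[known][findInterval(seq_len(n), known)]

  enforce_min_duration(s, min_samples = as.integer(round(min_dur * fs)))
}

# merge runs shorter than min_samples into their neighbours (shortest
# first); edge runs are left alone, a record may begin or end mid-state.
# Works on the run-length representation so long signals stay cheap.
enforce_min_duration <- function(s, min_samples) {
  if (min_samples <= 1) return(s)
  r <- rle(s)
  len <- r$lengths
  val <- r$values
  repeat {
    k <- length(len)
    if (k <= 2) break
    interior <- 2:(k - 1)
    short <- interior[len[interior] < min_samples]
    if (length(short) == 0) break
    i <- short[which.min(len[short])]
    # flipping run i makes it equal to both neighbours: merge the three
    merged <- len[i - 1] + len[i] + len[i + 1]
    keep_pre <- seq_len(i - 2)
    keep_post <- if (i + 2 <= k) (i + 2):k else integer(0)
    len <- c(len[keep_pre], merged, len[keep_post])
    val <- c(val[keep_pre], val[i - 1], val[keep_post])
  }
  inverse.rle(list(lengths = len, values = val))
}

#' Combine per-channel binary signals by majority vote
#'
#' A sample of the global signal is marked suppression if and only if
#' strictly more than half of the contributing channels mark it suppression
#' (ties go to burst, conservative toward detecting cerebral activity).
#' Channels may abstain at individual samples with `NA`.
#'
#' @param signals Matrix (channels x samples) of per-channel 0/1 states, or
#'   a list of equal-length vectors.
#' @param fs Sampling rate, Hz.
#' @param mask Optional per-epoch validity mask from [reject_artifacts()].
#' @param epoch_len Epoch length in seconds.
#' @return A [binary_signal()].
#' @export
vote <- function(signals, fs, mask = NULL, epoch_len = 1) {
  if (is.list(signals)) signals <- do.call(rbind, signals)
  if (!is.matrix(signals) || nrow(signals) == 0) {
    abort("`signals` must contain at least one channel.")
  }
  votes <- colSums(signals == 1L, na.rm = TRUE)
  contributing <- colSums(!is.na(signals))
  values <- as.integer(2 * votes > contributing)
  binary_signal(values, fs, mask = mask, epoch_len = epoch_len)
}

#' Full burst/suppression segmentation chain
#'
#' Applies the preprocessing and segmentation pipeline to a multichannel EEG
#' record: amplitude-based epoch rejection (>`artifact_thresh` uV on any
#' channel), band-pass filtering, average montage, per-channel binarization,
#' and cross-channel majority voting into a single global binary signal.
#'
#' @param eeg An [eeg_record()].
#' @param lo,hi Band-pass edges, Hz.
#' @param artifact_thresh Epoch rejection threshold, uV.
#' @param epoch_len Epoch length, seconds.
#' @param theta,tau_s,min_dur,hysteresis Binarization parameters, see
#'   [binarize_channel()].
#' @return A [binary_signal()] with the artifact mask attached.
#' @export
segment_eeg <- function(eeg, lo = 0.5, hi = 55, artifact_thresh = 500,
                        epoch_len = 1, theta = 5, tau_s = 0.2,
                        min_dur = 0.5, hysteresis = 0.2) {
  stopifnot(inherits(eeg, "eeg_record"))
  mask <- reject_artifacts(eeg, thresh = artifact_thresh,
                           epoch_len = epoch_len)
  pre <- eeg_bandpass(eeg, lo = lo, hi = hi)
  pre <- apply_average_montage(pre)
  per_ch <- lapply(seq_len(nrow(pre$samples)), function(ch) {
    binarize_channel(pre$samples[ch, ], pre$fs, theta = theta, tau_s = tau_s,
                     min_dur = min_dur, hysteresis = hysteresis)
  })
  vote(per_ch, fs = eeg$fs, mask = mask, epoch_len = epoch_len)
}
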