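# All on-disk tables are tab-separated with a header row; times are seconds
# from record start, intervals half-open.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE))
}

#' Read / write medication records
#'
#' Medication records are delimited text with header
#' `subject_id, drug, time_s, event, value`: `event = "rate"` rows start a
#' piecewise-constant infusion-rate step (mg/kg/hr, holding until the next
#' rate row of the same drug), `event = "bolus"` rows record bolus doses
#' (mg/kg). Reading validates the format: unknown events and
#' per-drug time disorder are rejected with the offending line.
#'
#' @param path File path.
#' @return `read_med_records()`: a tibble of events, grouped-by-nothing but
#'   ordered as on disk; use `dplyr::filter(subject_id == ...)` per subject.
#' @export
read_med_records <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("subject_id", "drug", "time_s", "event", "value")
  if (!all(need %in% names(df))) {
    abort(paste0("Medication record must have columns: ",
                 paste(need, collapse = ", ")))
  }
  bad <- !df$event %in% c("rate", "bolus")
  if (any(bad)) {
    abort(sprintf("Unknown event '%s' at line %d of %s.",
                  df$event[which(bad)[1]], which(bad)[1] + 1, path))
  }
  for (sid in unique(df$subject_id)) {
    for (d in unique(df$drug[df$subject_id == sid])) {
      rows <- which(df$subject_id == sid & df$drug == d & df$event == "rate")
      if (is.unsorted(df$time_s[rows])) {
        first_bad <- rows[which(diff(df$time_s[rows]) < 0)[1] + 1]
        abort(sprintf("Unordered rate times for %s/%s at line %d of %s.",
                      sid, d, first_bad + 1, path))
      }
    }
  }
  validate_regimen(df)
  df
}

#' @rdname read_med_records
#' @param meds Medication tibble (columns as above).
#' @export
write_med_records <- function(meds, path) {
  stopifnot(all(c("subject_id", "drug", "time_s", "event", "value") %in%
                  names(meds)))
  write_tsv_plain(meds, path)
}

#' Read / write intent-period interval lists
#'
#' Intent periods — intervals with documented intent to maintain burst
#' suppression — are delimited text with header
#' `subject_id, start_s, end_s` (half-open intervals in seconds).
#'
#' @param path File path.
#' @export
read_intent_periods <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("subject_id", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    abort("Intent periods must have columns subject_id, start_s, end_s.")
  }
  if (any(df$end_s <= df$start_s)) abort("Intent intervals must have end_s > start_s.")
  df
}

#' @rdname read_intent_periods
#' @param intent Intent tibble.
#' @export
write_intent_periods <- function(intent, path) {
  stopifnot(all(c("subject_id", "start_s", "end_s") %in% names(intent)))
  write_tsv_plain(intent, path)
}

#' Read / write per-epoch suppression counts
#'
#' The epoch-count interchange format between segmentation and BSP
#' estimation: `epoch_index, n_suppressed_samples, n_valid_samples`, one row
#' per epoch (0-based, 1-second epochs unless stated otherwise in the
#' consuming configuration).
#'
#' @param path File path.
#' @param epoch_len Epoch length in seconds (annotated on the returned
#'   tibble).
#' @export
read_epoch_counts <- function(path, epoch_len = 1) {
  df <- read_tsv_plain(path)
  need <- c("epoch_index", "n_suppressed_samples", "n_valid_samples")
  if (!all(need %in% names(df))) {
    abort("Epoch counts must have columns epoch_index, n_suppressed_samples, n_valid_samples.")
  }
  out <- tibble(epoch = as.integer(df$epoch_index),
                t_start = as.numeric(df$epoch_index) * epoch_len,
                n = as.integer(df$n_suppressed_samples),
                N = as.integer(df$n_valid_samples))
  attr(out, "epoch_len") <- epoch_len
  out
}

#' @rdname read_epoch_counts
#' @param counts Epoch-count tibble from [epoch_counts()].
#' @export
write_epoch_counts <- function(counts, path) {
  write_tsv_plain(
    tibble(epoch_index = counts$epoch, n_suppressed_samples = counts$n,
           n_valid_samples = counts$N),
    path)
}

#' Read / write BSP trajectories
#'
#' Trajectory interchange format: `epoch, bsp, ci_lo, ci_hi, n, N` (plus the
#' latent state and variance so the trajectory can be reloaded losslessly).
#'
#' @param path File path.
#' @param epoch_len Epoch length in seconds.
#' @export
read_trajectory <- function(path, epoch_len = 1) {
  df <- read_tsv_plain(path)
  need <- c("epoch", "bsp", "ci_lo", "ci_hi", "n", "N")
  if (!all(need %in% names(df))) {
    abort("Trajectory file must have columns epoch, bsp, ci_lo, ci_hi, n, N.")
  }
  out <- tibble(epoch = as.integer(df$epoch),
                t_start = as.numeric(df$epoch) * epoch_len,
                n = as.integer(df$n), N = as.integer(df$N),
                x = if ("x" %in% names(df)) df$x else logit(clip(df$bsp, 1e-6, 1 - 1e-6)),
                var = if ("var" %in% names(df)) df$var else NA_real_,
                bsp = df$bsp, ci_lo = df$ci_lo, ci_hi = df$ci_hi)
  attr(out, "epoch_len") <- epoch_len
  class(out) <- c("bsp_traj", class(tibble()))
  out
}

#' @rdname read_trajectory
#' @param traj A `bsp_traj`.
#' @export
write_trajectory <- function(traj, path) {
  df <- tibble(epoch = traj$epoch,
               bsp = format_full(traj$bsp), ci_lo = format_full(traj$ci_lo),
               ci_hi = format_full(traj$ci_hi), n = traj$n, N = traj$N,
               x = format_full(traj$x), var = format_full(traj$var))
  write_tsv_plain(df, path)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Pipeline configuration
#'
#' All tunable parameters of the analysis chain in one flat list; the
#' key-value serialization ([write_pipeline_config()] /
#' [read_pipeline_config()]) round-trips losslessly. See the methods
#' vignette for the rationale behind each default.
#'
#' @param epoch_len Epoch length, seconds.
#' @param filter_lo,filter_hi Band-pass edges, Hz.
#' @param artifact_thresh Amplitude rejection threshold, uV.
#' @param theta,tau_s,min_dur,hysteresis Binarization parameters.
#' @param sigma_v2 Process-noise variance (logit scale) per epoch.
#' @param use_em Estimate `sigma_v2` by EM when enough valid epochs exist?
#' @param band_target,band_tol Reference band.
#' @param control_frac Time-aggregation threshold for accurate/reliable.
#' @param min_raw_h,guard_min,min_median_bsp Constant-dose segment rules.
#' @param n_draws Monte Carlo draws for group comparison.
#' @param seed Global seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_len = 1, filter_lo = 0.5, filter_hi = 55,
                            artifact_thresh = 500, theta = 5, tau_s = 0.2,
                            min_dur = 0.5, hysteresis = 0.2,
                            sigma_v2 = 0.005, use_em = FALSE,
                            band_target = 0.8, band_tol = 0.15,
                            control_frac = 0.5, min_raw_h = 2,
                            guard_min = 30, min_median_bsp = 0.05,
                            n_draws = 100000, seed = 1) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(unlist(cfg[num]) <= 0 & !names(cfg[num]) %in% "seed")) {
    abort("All numeric configuration values must be positive.")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the flat key=value serialization.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vs <- if (is.logical(v)) as.character(v) else format_full(v)
    paste0(k, "=", vs)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    if (v %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(pipeline_config, vals)
}

# md5 of the serialized configuration, embedded in report headers
config_hash <- function(config) {
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}
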