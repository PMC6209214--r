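#' Per-epoch suppression counts from a global binary signal
#'
#' Aggregates the per-sample global binary signal into per-epoch binomial
#' observations: `n` suppressed samples out of `N` valid samples. Epochs
#' masked by artifact rejection have `N = 0` and are treated as missing by
#' the state-space model.
#'
#' @param signal A [binary_signal()].
#' @param epoch_len Epoch length in seconds; defaults to the signal's own.
#' @return A tibble (`epoch` 0-based, `t_start` seconds, `n`, `N`) with
#'   attribute `epoch_len`.
#' @export
epoch_counts <- function(signal, epoch_len = NULL) {
  stopifnot(inherits(signal, "binary_signal"))
  epoch_len <- epoch_len %||% signal$epoch_len
  if (epoch_len <= 0) abort("`epoch_len` must be positive.")
  ns <- length(signal$values)
  idx <- sample_epoch_index(ns, signal$fs, epoch_len)
  n_ep <- n_epochs_for(ns, signal$fs, epoch_len)
  n_t <- integer(n_ep)
  N_t <- integer(n_ep)
  tab_n <- rowsum(signal$values, idx)
  tab_N <- rowsum(rep(1L, ns), idx)
  rows <- as.integer(rownames(tab_n)) + 1L
  n_t[rows] <- tab_n[, 1]
  N_t[rows] <- tab_N[, 1]

  # the mask is defined on the signal's native epoch grid
  mask_ep <- signal$epoch_len
  sec_start <- (seq_len(n_ep) - 1) * epoch_len
  mask_idx <- clip(floor(sec_start / mask_ep) + 1, 1, length(signal$mask))
  invalid <- !signal$mask[mask_idx]
  n_t[invalid] <- 0L
  N_t[invalid] <- 0L

  out <- tibble(epoch = seq_len(n_ep) - 1L, t_start = sec_start,
                n = n_t, N = N_t)
  attr(out, "epoch_len") <- epoch_len
  attr(out, "fs") <- signal$fs
  attr(out, "ess_per_epoch") <- estimate_epoch_ess(signal, epoch_len)
  out
}

#' Effective number of independent observations per epoch
#'
#' Samples of the binary signal are strongly serially correlated: bursts and
#' suppressions last on the order of seconds, so the hundreds of samples in
#' a one-second epoch carry far fewer than `N` independent Bernoulli
#' observations. For a two-state alternating process with mean burst / mean
#' suppression durations `mu_b` / `mu_s` the integrated correlation time is
#' `tau = mu_b * mu_s / (mu_b + mu_s)` and the variance of a T-second
#' average is `p(1-p) * 2 tau / T`, i.e. `T / (2 tau)` effective
#' observations per T seconds. The durations are estimated from the run
#' lengths of the signal itself (interior runs only).
#'
#' @param signal A [binary_signal()].
#' @param epoch_len Epoch length in seconds.
#' @return Effective observations per epoch (scalar >= 1/epoch; `NA` when
#'   the signal never alternates, in which case no correction is applied).
#' @export
estimate_epoch_ess <- function(signal, epoch_len = NULL) {
  stopifnot(inherits(signal, "binary_signal"))
  epoch_len <- epoch_len %||% signal$epoch_len
  r <- rle(signal$values)
  if (length(r$lengths) < 4) return(NA_real_)
  # drop edge runs: censored durations
  lens <- r$lengths[-c(1, length(r$lengths))] / signal$fs
  vals <- r$values[-c(1, length(r$values))]
  if (!any(vals == 1L) || !any(vals == 0L)) return(NA_real_)
  mu_s <- mean(lens[vals == 1L])
  mu_b <- mean(lens[vals == 0L])
  tau <- mu_b * mu_s / (mu_b + mu_s)
  max(epoch_len / (2 * tau), 1e-3)
}

#' Forward filter of the burst suppression probability
#'
#' State-space model of the BSP: a Gaussian random walk on the logit scale,
#' `x_t = x_{t-1} + v_t`, `v_t ~ N(0, sigma_v2)`, observed through binomial
#' epoch counts `n_t ~ Binomial(N_t, logistic(x_t))`. The forward pass
#' computes the posterior mode of `x_t` given data up to `t` by Newton
#' iteration on the log-posterior, with the variance from the negative
#' inverse Hessian at the mode. Missing epochs (`N_t = 0`) propagate the
#' prediction: the mean is carried forward and the variance grows by
#' `sigma_v2` per epoch, so gaps widen the credible interval.
#'
#' @param counts Epoch-count tibble from [epoch_counts()] (columns `n`, `N`).
#' @param sigma_v2 Process-noise variance per epoch on the logit scale.
#'   Default 0.005; see [estimate_sigma_v2()] for data-driven estimation.
#' @param x0 Initial latent state. Default: logit of the first valid epoch's
#'   empirical rate, clipped to `[0.01, 0.99]`.
#' @param var0 Initial state variance (weakly informative default 1).
#' @param ess Effective independent observations per epoch, correcting the
#'   binomial likelihood for serial correlation of the underlying binary
#'   signal (see [estimate_epoch_ess()]). Defaults to the value annotated on
#'   `counts` by [epoch_counts()]; `NA` disables the correction (raw counts,
#'   appropriate when epochs hold independent observations). Valid epochs
#'   are down-weighted by `min(1, ess / N_t)`; the reported `n`, `N` stay
#'   raw.
#' @return A `bsp_traj` tibble (`epoch`, `t_start`, `n`, `N`, `x`, `var`,
#'   `bsp`, `ci_lo`, `ci_hi`) with the 95% credible bounds obtained by
#'   transforming `x +/- 1.96 sd` through the logistic.
#' @export
bsp_filter <- function(counts, sigma_v2 = 0.005, x0 = NULL, var0 = 1,
                       ess = NULL) {
  stopifnot(all(c("n", "N") %in% names(counts)))
  if (sigma_v2 < 1e-8) abort("`sigma_v2` must be >= 1e-8.")
  ess <- ess %||% attr(counts, "ess_per_epoch") %||% NA_real_
  n_t <- counts$n
  N_t <- counts$N
  if (!is.na(ess)) {
    w <- ifelse(N_t > 0, pmin(1, ess / N_t), 1)
    n_t <- n_t * w
    N_t <- N_t * w
  }
  Tn <- length(n_t)
  if (Tn == 0) abort("`counts` is empty.")
  if (any(n_t > N_t) || any(n_t < 0)) abort("Need 0 <= n <= N per epoch.")
  if (is.null(x0)) {
    fv <- which(N_t > 0)[1]
    x0 <- if (is.na(fv)) 0 else logit(clip(n_t[fv] / N_t[fv], 0.01, 0.99))
  }
  x <- numeric(Tn)
  v <- numeric(Tn)
  x_prev <- x0
  v_prev <- var0
  for (t in seq_len(Tn)) {
    x_pred <- x_prev
    v_pred <- v_prev + sigma_v2
    if (N_t[t] == 0) {
      x[t] <- x_pred
      v[t] <- v_pred
    } else {
      xt <- x_pred
      ok <- FALSE
      for (it in 1:50) {
        p <- logistic(xt)
        g <- -(xt - x_pred) / v_pred + n_t[t] - N_t[t] * p
        h <- -1 / v_pred - N_t[t] * p * (1 - p)
        # damped step: the log-posterior is strictly concave, but a full
        # Newton step can overshoot where the likelihood saturates
        dx <- clip(g / h, -4, 4)
        xt <- xt - dx
        if (abs(dx) < 1e-8) { ok <- TRUE; break }
      }
      if (!ok) abort(sprintf("Newton update failed to converge at epoch %d.",
                             counts$epoch[t] %||% (t - 1)))
      p <- logistic(xt)
      x[t] <- xt
      v[t] <- 1 / (1 / v_pred + N_t[t] * p * (1 - p))
    }
    x_prev <- x[t]
    v_prev <- v[t]
  }
  new_bsp_traj(counts, x, v, sigma_v2 = sigma_v2, x0 = x0, var0 = var0,
               type = "filtered")
}

new_bsp_traj <- function(counts, x, v, sigma_v2, x0, var0, type) {
  sdv <- sqrt(v)
  out <- tibble(
    epoch = counts$epoch %||% (seq_along(x) - 1L),
    t_start = counts$t_start %||% (seq_along(x) - 1),
    n = counts$n, N = counts$N,
    x = x, var = v,
    bsp = logistic(x),
    ci_lo = logistic(x - 1.96 * sdv),
    ci_hi = logistic(x + 1.96 * sdv)
  )
  attr(out, "sigma_v2") <- sigma_v2
  attr(out, "x0") <- x0
  attr(out, "var0") <- var0
  attr(out, "epoch_len") <- attr(counts, "epoch_len") %||% 1
  attr(out, "type") <- type
  class(out) <- c("bsp_traj", class(tibble()))
  out
}

#' Fixed-interval smoother of the BSP trajectory
#'
#' Rauch-Tung-Striebel backward pass over the filtered trajectory. The
#' smoothed state uses all data, so its variance never exceeds the filtered
#' variance, and the two coincide at the final epoch.
#'
#' @param filtered A filtered `bsp_traj` from [bsp_filter()].
#' @return A smoothed `bsp_traj` with the same columns; the smoother gains
#'   are kept in attribute `gain` (used by the EM step).
#' @export
bsp_smoother <- function(filtered) {
  stopifnot(inherits(filtered, "bsp_traj"))
  if (identical(attr(filtered, "type"), "smoothed")) {
    abort("`filtered` is already smoothed.")
  }
  sigma_v2 <- attr(filtered, "sigma_v2")
  xf <- filtered$x
  vf <- filtered$var
  Tn <- length(xf)
  xs <- xf
  vs <- vf
  gain <- numeric(Tn)
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      v_pred <- vf[t] + sigma_v2
      C <- vf[t] / v_pred
      gain[t] <- C
      xs[t] <- xf[t] + C * (xs[t + 1] - xf[t])
      vs[t] <- vf[t] + C^2 * (vs[t + 1] - v_pred)
    }
  }
  out <- new_bsp_traj(filtered, xs, vs,
                      sigma_v2 = sigma_v2, x0 = attr(filtered, "x0"),
                      var0 = attr(filtered, "var0"), type = "smoothed")
  attr(out, "gain") <- gain
  out
}

#' Estimate the BSP trajectory from epoch counts
#'
#' Convenience wrapper: optionally estimates the process-noise variance by
#' EM, then runs the forward filter and the fixed-interval smoother.
#'
#' @inheritParams bsp_filter
#' @param use_em Estimate `sigma_v2` from the data by EM (requires >= 100
#'   valid epochs)? When FALSE the supplied `sigma_v2` is used as-is.
#' @param ... Passed to [estimate_sigma_v2()] when `use_em = TRUE`.
#' @return A smoothed `bsp_traj`.
#' @export
bsp_estimate <- function(counts, sigma_v2 = 0.005, x0 = NULL, var0 = 1,
                         use_em = FALSE, ess = NULL, ...) {
  if (use_em) {
    sigma_v2 <- tryCatch(
      estimate_sigma_v2(counts, sigma0 = sigma_v2, ess = ess, ...),
      error = function(e) {
        warn(paste0("EM estimation unavailable (", conditionMessage(e),
                    "); using sigma_v2 = ", sigma_v2, "."))
        sigma_v2
      })
  }
  bsp_smoother(bsp_filter(counts, sigma_v2 = sigma_v2, x0 = x0, var0 = var0,
                          ess = ess))
}

#' EM estimation of the process-noise variance
#'
#' Iterates between the Gaussian-approximation forward filter / backward
#' smoother (E-step) and the closed-form update of the random-walk variance
#' `sigma_v2 = mean of E[(x_t - x_{t-1})^2]` (M-step), using the smoothed
#' means, variances and lag-one covariances. Deterministic given the data.
#'
#' @param counts Epoch-count tibble; at least 100 valid epochs required.
#' @param sigma0 Starting value.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative change of `sigma_v2`.
#' @param floor Lower bound (numerical floor) on the estimate.
#' @param ess Effective observations per epoch, see [bsp_filter()].
#' @return The estimated `sigma_v2` (scalar, >= `floor`).
#' @export
estimate_sigma_v2 <- function(counts, sigma0 = 0.005, max_iter = 100,
                              tol = 1e-3, floor = 1e-8, ess = NULL) {
  if (sum(counts$N > 0) < 100) {
    abort("EM needs at least 100 valid epochs; use the configured default instead.")
  }
  s <- sigma0
  for (it in seq_len(max_iter)) {
    filt <- bsp_filter(counts, sigma_v2 = s, ess = ess)
    sm <- bsp_smoother(filt)
    xs <- sm$x
    vs <- sm$var
    gain <- attr(sm, "gain")
    Tn <- length(xs)
    # lag-one smoothed covariance: cov(x_t, x_{t-1} | all data) = C_{t-1} * vs_t
    dx2 <- (xs[-1] - xs[-Tn])^2 + vs[-1] + vs[-Tn] -
      2 * gain[-Tn] * vs[-1]
    s_new <- max(mean(dx2), floor)
    if (abs(s_new - s) / max(s, floor) < tol) {
      return(s_new)
    }
    s <- s_new
  }
  s
}

#' Windowed burst suppression ratio
#'
#' The traditional BSR: the fraction of suppressed time among valid samples
#' in a centered moving window. At steady state the BSR and the model-based
#' BSP agree; the BSP is preferable for dynamic data.
#'
#' @param signal A [binary_signal()].
#' @param window Window length in seconds.
#' @return A tibble (`time_s`, `bsr`); `bsr` is `NA` where the window
#'   contains no valid samples.
#' @export
windowed_bsr <- function(signal, window = 60) {
  stopifnot(inherits(signal, "binary_signal"))
  if (window <= 0) abort("`window` must be positive.")
  ns <- length(signal$values)
  idx <- sample_epoch_index(ns, signal$fs, signal$epoch_len)
  valid <- signal$mask[idx + 1]
  vals <- as.numeric(signal$values) * valid
  cs_v <- c(0, cumsum(vals))
  cs_n <- c(0, cumsum(as.numeric(valid)))
  half <- round(window * signal$fs / 2)
  i <- seq_len(ns)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half - 1, ns) # exactly window * fs samples interior
  nsupp <- cs_v[hi + 1] - cs_v[lo]
  nval <- cs_n[hi + 1] - cs_n[lo]
  tibble(time_s = (i - 1) / signal$fs,
         bsr = ifelse(nval > 0, nsupp / nval, NA_real_))
}
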