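# Independent oracles used across tests.

# P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2) by numerical quadrature
beta_gt_oracle <- function(a1, b1, a2, b2) {
  stats::integrate(function(y) {
    stats::dbeta(y, a2, b2) * stats::pbeta(y, a1, b1, lower.tail = FALSE)
  }, 0, 1, rel.tol = 1e-10)$value
}

# brute-force exceedance probability over all ordered pairs
exceedance_brute <- function(x, y) {
  cmp <- outer(x, y, FUN = "<")
  ties <- outer(x, y, FUN = "==")
  (sum(cmp) + 0.5 * sum(ties)) / (length(x) * length(y))
}

# hand-built BSP trajectory tibble with the columns the compliance module needs
make_traj <- function(bsp, x = NULL, var = NULL, ci_lo = NULL, ci_hi = NULL,
                      N = 1L, epoch_len = 1) {
  m <- length(bsp)
  x <- x %||% log(bsp / (1 - bsp))
  var <- var %||% rep(0.01, m)
  sdv <- sqrt(var)
  out <- tibble::tibble(
    epoch = seq_len(m) - 1L, t_start = (seq_len(m) - 1) * epoch_len,
    n = 0L, N = rep_len(as.integer(N), m),
    x = x, var = var, bsp = bsp,
    ci_lo = ci_lo %||% plogis(x - 1.96 * sdv),
    ci_hi = ci_hi %||% plogis(x + 1.96 * sdv))
  attr(out, "epoch_len") <- epoch_len
  class(out) <- c("bsp_traj", class(tibble::tibble()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# epoch-count tibble from raw vectors (no ESS annotation: epochs independent)
make_counts <- function(n, N) {
  tibble::tibble(epoch = seq_along(n) - 1L, t_start = seq_along(n) - 1,
                 n = n, N = rep_len(N, length(n)))
}

# single-drug constant-rate medication record
const_meds <- function(rate = 2, subject = "S1", drug = "propofol") {
  tibble::tibble(subject_id = subject, drug = drug, time_s = 0,
                 event = "rate", value = rate)
}
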