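#' Tidy a BSP trajectory
#'
#' @param x A `bsp_traj`.
#' @param ... Unused.
#' @return A plain tibble (`epoch`, `t_start`, `bsp`, `ci_lo`, `ci_hi`,
#'   `n`, `N`).
#' @export
tidy.bsp_traj <- function(x, ...) {
  as_tibble(x)[, c("epoch", "t_start", "bsp", "ci_lo", "ci_hi", "n", "N")]
}

#' One-row summary of a BSP trajectory
#'
#' @param x A `bsp_traj`.
#' @param ... Unused.
#' @return A one-row tibble: epoch count, valid-epoch count, mean and median
#'   BSP over valid epochs, process-noise variance and trajectory type.
#' @export
glance.bsp_traj <- function(x, ...) {
  valid <- x$N > 0
  tibble(n_epochs = nrow(x), n_valid = sum(valid),
         mean_bsp = mean(x$bsp[valid]), median_bsp = median(x$bsp[valid]),
         sigma_v2 = attr(x, "sigma_v2") %||% NA_real_,
         type = attr(x, "type") %||% NA_character_)
}

#' Tidy a group-level Beta posterior
#'
#' @param x A [beta_posterior()] object.
#' @param ... Unused.
#' @return A one-row tibble (`k`, `n`, `alpha`, `beta`, `map`, `bci_lo`,
#'   `bci_hi`).
#' @export
tidy.group_posterior <- function(x, ...) {
  tibble(k = x$k, n = x$n, alpha = x$alpha, beta = x$beta, map = x$map,
         bci_lo = x$bci_lo, bci_hi = x$bci_hi)
}

#' Plot a BSP trajectory against the reference band
#'
#' Ribbon of the 95% credible interval around the BSP estimate, with the
#' reference band drawn as horizontal guides (target solid, band edges
#' dashed), in the style of clinical burst-suppression monitoring plots.
#'
#' @param object A `bsp_traj`.
#' @param band A [reference_band()] or NULL to omit the guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsp_traj <- function(object, band = reference_band(), ...) {
  df <- tidy(object)
  df$hours <- df$t_start / 3600
  p <- ggplot2::ggplot(df[df$N > 0, ], ggplot2::aes(x = .data$hours)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bsp), linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (h)", y = "Burst suppression probability")
  if (!is.null(band)) {
    p <- p +
      ggplot2::geom_hline(yintercept = band$target, colour = "forestgreen") +
      ggplot2::geom_hline(yintercept = c(band$lo, band$hi),
                          colour = "forestgreen", linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked per-subject compliance bars
#'
#' Mirrors the per-patient view of time above (red), within (green) and
#' below (blue) the reference band: one stacked bar per subject, ordered by
#' group then subject id.
#'
#' @param summary Subject summary tibble with `subject_id`, `pt_a`, `pt_i`,
#'   `pt_b` (percent), e.g. `run_pipeline(...)$summary`.
#' @return A ggplot object.
#' @export
plot_compliance <- function(summary) {
  stopifnot(all(c("subject_id", "pt_a", "pt_i", "pt_b") %in% names(summary)))
  long <- tidyr::pivot_longer(
    summary[, c("subject_id", "pt_a", "pt_i", "pt_b")],
    cols = c("pt_a", "pt_i", "pt_b"),
    names_to = "where", values_to = "percent")
  long$where <- factor(long$where, levels = c("pt_a", "pt_i", "pt_b"),
                       labels = c("above", "within", "below"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject_id,
                                     y = .data$percent,
                                     fill = .data$where)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(above = "firebrick",
                                          within = "forestgreen",
                                          below = "steelblue")) +
    ggplot2::labs(x = NULL, y = "% of intent-period time", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
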