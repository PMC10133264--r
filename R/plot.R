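#' Plot a GC trace
#'
#' Time course of the Granger statistic (or one of its normalized variants)
#' per direction, with the onset and the medium/strong thresholds marked when
#' a z variant is shown.
#'
#' @param object a `gc_trace` tibble.
#' @param value column to plot (`"F"`, `"z_surr"` or `"z_base"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gc_trace <- function(object, value = "F", ...) {
  stopifnot(value %in% names(object))
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$window_center_ms, y = .data[[value]],
    colour = paste(.data$source, "→", .data$target))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~ns_factor, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time from static onset (ms)", y = value,
                  colour = "direction") +
    ggplot2::theme_minimal()
  if (value %in% c("z_surr", "z_base")) {
    p <- p + ggplot2::geom_hline(yintercept = c(3, 5), linetype = "dashed",
                                 linewidth = 0.3)
  }
  p
}

#' @export
plot.gc_trace <- function(x, ...) print(autoplot.gc_trace(x, ...))

#' Plot baseline-z gamma power time courses
#'
#' @param z tibble from [zscore_vs_baseline()].
#' @param leads optional subset of lead ids.
#' @return a ggplot object.
#' @export
plot_power_z <- function(z, leads = NULL) {
  if (!is.null(leads)) z <- z[z$lead_id %in% leads, ]
  ggplot2::ggplot(z, ggplot2::aes(x = .data$time_ms, y = .data$z,
                                  colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~lead_id) +
    ggplot2::labs(x = "time from static onset (ms)",
                  y = "gamma power (baseline z)") +
    ggplot2::theme_minimal()
}

#' Plot a rejection mask
#'
#' Lead-by-trial heat map of the combined rejection mask.
#'
#' @param mask a `rejection_mask` from [combine_rejections()].
#' @return a ggplot object.
#' @export
plot_rejection_mask <- function(mask) {
  m <- mask$combined
  d <- expand.grid(lead = seq_len(nrow(m)), trial = seq_len(ncol(m)))
  d$rejected <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$lead,
                                  fill = .data$rejected)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "trial", y = "lead") +
    ggplot2::theme_minimal()
}

#' Plot the two-delay strength plane with connection types
#'
#' Scatter of NS4 against NS1 strength, coloured by type, with the strong
#' threshold marked — the plane on which the disappear / maintain / appear /
#' negative taxonomy lives.
#'
#' @param connections tibble with `C_ns1`, `C_ns4`, `type` (e.g. from
#'   [connection_summary()]).
#' @param strong_z threshold drawn (default 5).
#' @return a ggplot object.
#' @export
plot_connection_types <- function(connections, strong_z = 5) {
  ggplot2::ggplot(connections, ggplot2::aes(x = .data$C_ns1, y = .data$C_ns4,
                                            colour = .data$type)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-strong_z, strong_z),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-strong_z, strong_z),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "strength C (NS1, max 4 ms)",
                  y = "strength C (NS4, max 16 ms)") +
    ggplot2::theme_minimal()
}
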