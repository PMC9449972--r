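#' Peak-migration trajectories in shift space
#'
#' Plots each residue's cross-peak path through (1H, 15N) ppm space over the
#' melt, colored by temperature, with both axes reversed as in a spectrum.
#'
#' @param series A `melt_series`.
#' @param residues Residues to show (default: all; more than ~20 gets busy).
#' @return A ggplot.
#' @export
plot_trajectories <- function(series, residues = NULL) {
  tbl <- as_tibble(series)
  if (!is.null(residues)) tbl <- filter(tbl, .data$residue_index %in% residues)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$delta_h, .data$delta_n,
                                    color = .data$temperature,
                                    group = .data$residue_index)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_viridis_c(name = "T (K)") +
    ggplot2::labs(x = expression(delta ~ ""^1 * H ~ "(ppm)"),
                  y = expression(delta ~ ""^15 * N ~ "(ppm)")) +
    ggplot2::theme_minimal()
}

#' Cumulative shift-distance curves
#'
#' One line per residue of cumulative shift distance against temperature,
#' with flagged residues (if a flag table is given) emphasized.
#'
#' @param cum_tbl Output of [cumulative_shift()].
#' @param flags Optional [flag_sum_delta()] table; flagged residues are
#'   colored.
#' @return A ggplot.
#' @export
plot_sum_delta <- function(cum_tbl, flags = NULL) {
  flagged <- if (is.null(flags)) integer(0) else unique(flags$residue_index)
  cum_tbl <- mutate(cum_tbl, flagged = .data$residue_index %in% flagged)
  ggplot2::ggplot(cum_tbl, ggplot2::aes(.data$temperature, .data$cum_delta,
                                        group = .data$residue_index,
                                        color = .data$flagged)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                name = "flagged") +
    ggplot2::labs(x = "temperature (K)",
                  y = expression(sum(Delta * delta) ~ "(" * Delta * "ppm)")) +
    ggplot2::theme_minimal()
}

#' Peak-intensity profiles with quadratic trends
#'
#' @param series A `melt_series`.
#' @param residues Residues to show (default: all).
#' @return A ggplot with observed intensities and per-residue quadratic fits.
#' @export
plot_pi_profiles <- function(series, residues = NULL) {
  tbl <- as_tibble(series)
  if (!is.null(residues)) tbl <- filter(tbl, .data$residue_index %in% residues)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$temperature, .data$intensity,
                                    group = .data$residue_index)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ poly(x, 2),
                         se = FALSE, linewidth = 0.4, color = "steelblue") +
    ggplot2::labs(x = "temperature (K)", y = "peak intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Heat map of a cross-correlation matrix
#'
#' Gated cells (when the matrix has been through [gate_matrix()]) render
#' white, mirroring the usual noise-gated coloring.
#'
#' @param object A `melt_ccm`.
#' @param gated Plot the gated matrix when available (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.melt_ccm <- function(object, gated = TRUE, ...) {
  m <- if (gated && !is.null(object$gate)) object$rho_gated else object$rho
  long <- tibble(
    residue_i = rep(object$residues, times = length(object$residues)),
    residue_j = rep(object$residues, each = length(object$residues)),
    rho = as.vector(m)
  )
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$residue_i),
                                     factor(.data$residue_j),
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1), na.value = "white",
                                  name = expression(rho)) +
    ggplot2::labs(x = "residue", y = "residue",
                  title = paste0(object$observable, " cross-correlation")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
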