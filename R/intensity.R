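#' Quadratic peak-intensity trend
#'
#' Ordinary least-squares fit of a second-order polynomial to a residue's
#' peak-intensity series, PI(T) = a2*T'^2 + a1*T' + a0, with temperature
#' centered at the midpoint of its observed range before fitting (T' = T -
#' mid). The centered basis keeps the normal equations well conditioned on
#' kelvin-scale grids and makes `a0` the fitted mid-melt intensity. The fit is
#' descriptive — no residue is excluded for fitting poorly — so R-squared is
#' returned alongside the coefficients.
#'
#' @param temperature Observed temperatures (kelvin), at least 3.
#' @param intensity Peak intensities at those temperatures.
#' @return One-row tibble: `a2`, `a1`, `a0` (centered basis), `t_center`,
#'   `r_squared`.
#' @export
fit_pi_trend <- function(temperature, intensity) {
  stopifnot(length(temperature) == length(intensity))
  if (length(temperature) < 3L) abort("fit_pi_trend needs at least 3 points")
  t_center <- (min(temperature) + max(temperature)) / 2
  tc <- temperature - t_center
  fit <- lm(intensity ~ tc + I(tc^2))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  tibble(
    a2 = unname(coef(fit)[3L]),
    a1 = unname(coef(fit)[2L]),
    a0 = unname(coef(fit)[1L]),
    t_center = t_center,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  )
}

#' Percentage change in peak intensity
#'
#' Change from the intensity at the start of the melt to the maximum along the
#' melt, as a percentage of the start value:
#' \deqn{\%\Delta PI = \frac{PI_{max} - PI_{start}}{PI_{start}} \times 100}
#' Dimensionless, so invariant under any common rescaling of intensities.
#'
#' @param start_pi Intensity at the first observed temperature; must be > 0.
#' @param max_pi Maximum intensity over the melt.
#' @return Percentage (vectorized).
#' @export
#' @examples
#' percent_change(100, 397) # 297
percent_change <- function(start_pi, max_pi) {
  if (any(start_pi <= 0)) abort("percent_change undefined for start_pi <= 0")
  (max_pi - start_pi) / start_pi * 100
}

#' Per-residue peak-intensity summaries
#'
#' For every residue observed at three or more temperatures: the start-of-melt
#' intensity (at the residue's first observed temperature), the maximum
#' intensity and the temperature at which it occurs, the percentage change
#' between the two, and the quadratic trend fit of [fit_pi_trend()].
#'
#' @param series A `melt_series`.
#' @return Tibble, one row per residue: `residue_index`, `start_temperature`,
#'   `start_pi`, `max_pi`, `max_pi_temperature`, `percent_change`, `a2`, `a1`,
#'   `a0`, `t_center`, `r_squared`.
#' @export
pi_summary <- function(series) {
  arrange(as_tibble(series), .data$residue_index, .data$temperature) %>%
    group_by(.data$residue_index) %>%
    filter(dplyr::n() >= 3L) %>%
    summarise(
      start_temperature = first(.data$temperature),
      start_pi = first(.data$intensity),
      max_pi = max(.data$intensity),
      max_pi_temperature = .data$temperature[which.max(.data$intensity)],
      percent_change = percent_change(first(.data$intensity), max(.data$intensity)),
      fit_pi_trend(.data$temperature, .data$intensity),
      .groups = "drop"
    )
}
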