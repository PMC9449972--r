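#' Combined 1H/15N chemical-shift distance
#'
#' Euclidean distance between two amide cross-peak positions in weighted ppm
#' space, the per-step CSP statistic:
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w\,\Delta\delta_N)^2}}
#' where `w` down-weights the 15N axis for its wider ppm range. The
#' community-standard weight 0.14 is the default; `nitrogen_weight = 1` gives
#' the raw ppm distance.
#'
#' @param h1,n1 1H and 15N shifts (ppm) of the first position (vectorized).
#' @param h2,n2 Shifts of the second position.
#' @param nitrogen_weight Positive scaling of the 15N axis (default 0.14).
#' @return Numeric vector of shift distances (delta-ppm), symmetric in the
#'   two positions.
#' @export
#' @examples
#' delta_shift(8.12, 119.4, 8.15, 119.6) # one step
delta_shift <- function(h1, n1, h2, n2, nitrogen_weight = 0.14) {
  stopifnot(nitrogen_weight > 0)
  sqrt((h2 - h1)^2 + (nitrogen_weight * (n2 - n1))^2)
}

#' Per-step and cumulative shift distances along the melt
#'
#' For each residue, computes the shift distance of every step between
#' consecutive observed temperatures and its running sum. The cumulative
#' distance at a residue's first observed temperature is 0 by definition;
#' at temperature T it is the total distance the cross-peak has traveled from
#' its first observed position, accumulated step-by-step (e.g. the cumulative
#' value at 301 K is the 295->297, 297->299 and 299->301 K steps summed).
#' A gap in observation is bridged by a single step between the flanking
#' observed positions, assigned to the later temperature — no positions are
#' interpolated.
#'
#' @param series A `melt_series`.
#' @param residues Residue indices to compute (default: all residues with at
#'   least two observations; residues below that are skipped with a message
#'   when selected implicitly, and are an error when requested explicitly).
#' @param nitrogen_weight Passed to [delta_shift()].
#' @return Tibble with `residue_index`, `temperature`, `step_delta` (NA at the
#'   first observed temperature), `cum_delta`.
#' @export
cumulative_shift <- function(series, residues = NULL, nitrogen_weight = 0.14) {
  tbl <- arrange(as_tibble(series), .data$residue_index, .data$temperature)
  obs <- table(tbl$residue_index)
  if (is.null(residues)) {
    thin <- names(obs)[obs < 2L]
    if (length(thin) > 0L) {
      inform(paste0("cumulative_shift: skipping residue(s) with < 2 observations: ",
                    paste(thin, collapse = ", ")))
    }
    residues <- as.integer(names(obs)[obs >= 2L])
  } else {
    bad <- setdiff(as.character(residues), names(obs))
    if (length(bad) > 0L) abort(paste0("residue(s) not in series: ", paste(bad, collapse = ", ")))
    thin <- residues[obs[as.character(residues)] < 2L]
    if (length(thin) > 0L) {
      abort(paste0("insufficient points (< 2 observations) for residue(s): ",
                   paste(thin, collapse = ", ")))
    }
  }
  tbl %>%
    filter(.data$residue_index %in% residues) %>%
    group_by(.data$residue_index) %>%
    mutate(
      step_delta = delta_shift(lag(.data$delta_h), lag(.data$delta_n),
                               .data$delta_h, .data$delta_n,
                               nitrogen_weight = nitrogen_weight),
      cum_delta = cumsum(dplyr::coalesce(.data$step_delta, 0))
    ) %>%
    ungroup() %>%
    select("residue_index", "temperature", "step_delta", "cum_delta")
}

#' Trajectory linearity score
#'
#' How far a peak's migration path bends away from a straight line. The score
#' is the RMS perpendicular deviation of the intermediate positions from the
#' first-to-last chord, in weighted ppm space, divided by the total path
#' length — a dimensionless quantity in \[0, ~0.5\] that is invariant under
#' rotation, translation and uniform scaling of the trajectory. A perfectly
#' straight path scores 0; a right-angle dog-leg of equal legs scores
#' 1/(2*sqrt(2)) ~ 0.354.
#'
#' @param delta_h,delta_n Ordered peak positions (ppm) along the melt; at
#'   least 3 points.
#' @param nitrogen_weight Passed to the weighted-space embedding.
#' @param threshold Score above which the trajectory is called `"nonlinear"`
#'   (default 0.15).
#' @return One-row tibble: `linearity_score`, `trajectory_class`.
#' @export
classify_trajectory <- function(delta_h, delta_n, nitrogen_weight = 0.14,
                                threshold = 0.15) {
  stopifnot(length(delta_h) == length(delta_n))
  if (length(delta_h) < 3L) abort("classify_trajectory needs at least 3 positions")
  x <- delta_h
  y <- nitrogen_weight * delta_n
  n <- length(x)
  path_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path_len == 0) {
    score <- 0
  } else {
    cx <- x[n] - x[1L]
    cy <- y[n] - y[1L]
    chord <- sqrt(cx^2 + cy^2)
    xi <- x[2:(n - 1L)] - x[1L]
    yi <- y[2:(n - 1L)] - y[1L]
    d <- if (chord == 0) sqrt(xi^2 + yi^2) else abs(cx * yi - cy * xi) / chord
    score <- sqrt(mean(d^2)) / path_len
  }
  tibble(linearity_score = score,
         trajectory_class = if (score > threshold) "nonlinear" else "linear")
}

#' Per-residue trajectory classification for a whole series
#'
#' Applies [classify_trajectory()] to every residue with at least three
#' observed temperatures.
#'
#' @inheritParams cumulative_shift
#' @inheritParams classify_trajectory
#' @return Tibble: `residue_index`, `n_points`, `linearity_score`,
#'   `trajectory_class`.
#' @export
trajectory_classes <- function(series, nitrogen_weight = 0.14, threshold = 0.15) {
  arrange(as_tibble(series), .data$residue_index, .data$temperature) %>%
    group_by(.data$residue_index) %>%
    filter(dplyr::n() >= 3L) %>%
    summarise(
      n_points = dplyr::n(),
      classify_trajectory(.data$delta_h, .data$delta_n,
                          nitrogen_weight = nitrogen_weight,
                          threshold = threshold),
      .groups = "drop"
    )
}
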