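#' Upper-tail threshold of a fitted normal distribution
#'
#' Fits a normal distribution to the values (sample mean, sample standard
#' deviation with denominator n-1) and returns the upper-tail quantile at the
#' requested percentile level: `threshold = mean + qnorm(level/100) * sd`.
#' Values strictly above the threshold are "in the level-th percentile" of the
#' fitted distribution. A degenerate sample (all values identical) yields
#' `threshold = mean` with a warning.
#'
#' @param values Numeric vector, length >= 2.
#' @param level Percentile level in (0, 100), e.g. 90 or 95.
#' @param warn_degenerate Emit the zero-variance warning (default `TRUE`).
#' @return One-row tibble: `mean`, `sd`, `level`, `threshold`, `n`.
#' @export
#' @examples
#' normal_threshold(rnorm(1000, 10, 2), 95)
normal_threshold <- function(values, level, warn_degenerate = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort("normal_threshold needs at least 2 finite values")
  if (level <= 0 || level >= 100) abort("level must be in (0, 100)")
  mu <- mean(values)
  s <- stats::sd(values)
  if (s == 0 && warn_degenerate) {
    warn("degenerate distribution (zero variance); threshold equals the mean")
  }
  tibble(mean = mu, sd = s, level = level,
         threshold = mu + qnorm(level / 100) * s, n = length(values))
}

#' Percentile flags for cumulative shift distance, per temperature
#'
#' At each grid temperature, a normal distribution is fitted to that
#' temperature's cumulative shift distances across residues, and residues
#' strictly above the fitted upper-tail threshold are flagged, for each
#' requested level. By construction the 95th-percentile set at a temperature
#' is nested inside the 90th-percentile set.
#'
#' @param cum_tbl Output of [cumulative_shift()] (columns `residue_index`,
#'   `temperature`, `cum_delta`).
#' @param levels Percentile levels (default `c(90, 95)`).
#' @return Tibble of flagged (temperature, level, residue_index, cum_delta)
#'   rows, with the per-temperature fitted thresholds in the `thresholds`
#'   attribute (see [flag_thresholds()]). Temperatures where all values are
#'   identical flag nobody.
#' @export
flag_sum_delta <- function(cum_tbl, levels = c(90, 95)) {
  stopifnot(all(levels > 0 & levels < 100))
  temps <- sort(unique(cum_tbl$temperature))
  thr <- purrr::map_dfr(temps, function(tt) {
    v <- cum_tbl$cum_delta[cum_tbl$temperature == tt]
    purrr::map_dfr(levels, function(lv) {
      mutate(normal_threshold(v, lv, warn_degenerate = FALSE), temperature = tt)
    })
  })
  flags <- cum_tbl %>%
    select("residue_index", "temperature", "cum_delta") %>%
    left_join(select(thr, "temperature", "level", "threshold", "sd"),
              by = "temperature", relationship = "many-to-many") %>%
    filter(.data$sd > 0, .data$cum_delta > .data$threshold) %>%
    select("temperature", "level", "residue_index", "cum_delta") %>%
    arrange(.data$temperature, .data$level, .data$residue_index)
  attr(flags, "thresholds") <- select(thr, "temperature", "level", "mean", "sd",
                                      "threshold", "n")
  attr(flags, "observable") <- "sum_delta"
  flags
}

#' Accessor for the fitted thresholds behind a flag table
#' @param flags Output of [flag_sum_delta()] or [flag_pi()].
#' @return Tibble of fitted normal parameters and thresholds.
#' @export
flag_thresholds <- function(flags) attr(flags, "thresholds")

#' Percentile flags for peak intensity, pooled over the melt
#'
#' A single normal distribution is fitted to the pooled set of every
#' residue-temperature intensity observation across the whole melt (each
#' observation used once; missing points contribute nothing), and a residue is
#' flagged when its maximum intensity exceeds the pooled upper-tail threshold.
#'
#' @param series A `melt_series`.
#' @param level Percentile level (default 90).
#' @param profiles Optional precomputed [pi_summary()] table (recomputed from
#'   `series` when absent).
#' @return Tibble of flagged residues (`residue_index`, `max_pi`,
#'   `max_pi_temperature`, `level`), with the pooled fit in the `thresholds`
#'   attribute.
#' @export
flag_pi <- function(series, level = 90, profiles = NULL) {
  if (is.null(profiles)) profiles <- pi_summary(series)
  thr <- normal_threshold(as_tibble(series)$intensity, level,
                          warn_degenerate = FALSE)
  flags <- profiles %>%
    filter(thr$sd > 0, .data$max_pi > thr$threshold) %>%
    mutate(level = level) %>%
    select("residue_index", "max_pi", "max_pi_temperature", "level") %>%
    arrange(.data$residue_index)
  attr(flags, "thresholds") <- thr
  attr(flags, "observable") <- "pi"
  flags
}

#' Top residues by percentage intensity change
#'
#' Ranks residues by [percent_change()] descending; ties are broken by
#' residue index ascending so the ranking is deterministic.
#'
#' @param profiles A [pi_summary()] table.
#' @param k Number of residues to keep (default 15; the whole cohort when
#'   smaller than `k`).
#' @return Tibble `residue_index`, `percent_change`, `rank`.
#' @export
top_percent_change <- function(profiles, k = 15) {
  stopifnot(k >= 1)
  profiles %>%
    arrange(dplyr::desc(.data$percent_change), .data$residue_index) %>%
    head(k) %>%
    mutate(rank = dplyr::row_number()) %>%
    select("residue_index", "percent_change", "rank")
}
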