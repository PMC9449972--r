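#' Assemble peak records into a temperature series
#'
#' Builds a validated temperature series from a pile of peak records: the
#' temperature grid is the sorted set of distinct temperatures seen, and a
#' residue missing at a grid temperature is simply absent (missingness is
#' bookkept, not imputed). Exact duplicate records are collapsed with a
#' warning; records that share (residue, temperature) but disagree on any
#' field are an error.
#'
#' @param records Peak-record tibble (see [read_peak_table()]); several files'
#'   worth can be row-bound first.
#' @return A `melt_series` tibble (rows = observed records, ordered by residue
#'   then temperature) with attributes `temperatures` (the grid) and
#'   `reference_offsets` if present on the input.
#' @export
assemble_series <- function(records) {
  stopifnot(nrow(records) > 0)
  key <- paste(records$residue_index, records$temperature, sep = "@")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    full <- paste(records$residue_index, records$temperature,
                  records$residue_type, records$delta_h, records$delta_n,
                  records$intensity)
    conflicting <- vapply(dup_keys, function(k) {
      length(unique(full[key == k])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      abort(paste0("conflicting duplicate records for (residue@temperature): ",
                   paste(dup_keys[conflicting], collapse = ", ")))
    }
    warn(paste0("dropping ", sum(duplicated(key)), " exact duplicate record(s)"))
    records <- records[!duplicated(key), ]
  }
  out <- arrange(as_tibble(records), .data$residue_index, .data$temperature)
  attr(out, "temperatures") <- sort(unique(out$temperature))
  attr(out, "reference_offsets") <- attr(records, "reference_offsets")
  class(out) <- c("melt_series", class(out))
  out
}

#' @export
print.melt_series <- function(x, ...) {
  temps <- series_temperatures(x)
  cat(sprintf("<melt_series> %d residues x %d temperatures (%g-%g K), %d records\n",
              length(unique(x$residue_index)), length(temps),
              min(temps), max(temps), nrow(x)))
  NextMethod()
}

#' Temperature grid of a series
#' @param series A `melt_series`.
#' @return Sorted numeric vector of grid temperatures (kelvin).
#' @export
series_temperatures <- function(series) {
  t <- attr(series, "temperatures")
  if (is.null(t)) sort(unique(series$temperature)) else t
}

#' Missing-point bookkeeping
#'
#' Number of grid temperatures at which each residue was not observed.
#'
#' @param series A `melt_series`.
#' @return Tibble with `residue_index`, `n_observed`, `n_missing`.
#' @export
missing_counts <- function(series) {
  n_grid <- length(series_temperatures(series))
  series %>%
    as_tibble() %>%
    group_by(.data$residue_index) %>%
    summarise(n_observed = dplyr::n(), .groups = "drop") %>%
    mutate(n_missing = n_grid - .data$n_observed)
}

#' Drop residues with too many missing temperature points
#'
#' Residues missing more than `max_missing` grid temperatures are excluded
#' from further analysis (default 3, so a residue observed at 12 of 15 points
#' survives and one observed at 11 does not). The removed residues are
#' recorded in the `dropped_residues` attribute and reported.
#'
#' @param series A `melt_series`.
#' @param max_missing Maximum tolerated number of missing grid points
#'   (default 3).
#' @return The filtered `melt_series`; the grid attribute is kept as-is so
#'   missingness stays defined against the full grid.
#' @export
filter_missing <- function(series, max_missing = 3) {
  stopifnot(max_missing >= 0)
  mc <- missing_counts(series)
  drop <- mc$residue_index[mc$n_missing > max_missing]
  prior <- attr(series, "dropped_residues")
  if (length(drop) > 0L) {
    inform(paste0("filter_missing: dropping ", length(drop), " residue(s) with > ",
                  max_missing, " missing point(s): ", paste(drop, collapse = ", ")))
  }
  out <- series[!series$residue_index %in% drop, ]
  attr(out, "temperatures") <- series_temperatures(series)
  attr(out, "reference_offsets") <- attr(series, "reference_offsets")
  attr(out, "dropped_residues") <- union(prior, drop)
  class(out) <- unique(c("melt_series", class(out)))
  out
}
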