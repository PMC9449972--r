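#' Read an assigned peak table
#'
#' Reads per-temperature assigned cross-peak lists into a tidy record table
#' with one row per (residue, temperature) observation. Two dialects are
#' supported: the package's native tab-separated table and Sparky-style
#' `.list` files (assignment string followed by w1/w2 positions and a height,
#' with the temperature supplied out-of-band since Sparky lists carry none).
#'
#' The native TSV header is
#' `residue_index residue_type temperature_K delta_H_ppm delta_N_ppm intensity`
#' (tab-separated); lines starting with `#` are comments. Sparky assignment
#' strings such as `"Q134N-H"` are parsed into the one-letter residue type and
#' residue index; columns are `w1` (ppm, 15N), `w2` (ppm, 1H), then an
#' intensity/height column.
#'
#' @param file Path to a file, or a character vector of lines (useful for
#'   literal text; anything containing a newline or of length > 1 is treated
#'   as lines, not a path).
#' @param dialect `"tsv"` (native table) or `"sparky"`.
#' @param temperature Temperature in kelvin for every record; required for the
#'   sparky dialect, ignored for tsv. For files named `*_<kelvin>K.list` the
#'   temperature is recovered from the filename when not given.
#' @param offset Integer added to every residue index on read, so that files
#'   in a foreign numbering scheme land in the pipeline's canonical
#'   (mature-sequence) numbering.
#' @param validate If `TRUE` (default), range-check fields: temperature in
#'   \[200, 400\] K, intensity >= 0, delta_h in \[-2, 15\] ppm, delta_n in
#'   \[90, 140\] ppm. Offending rows are reported with their line numbers.
#'
#' @return A tibble with columns `residue_index`, `residue_type`,
#'   `temperature`, `delta_h`, `delta_n`, `intensity`.
#' @export
#' @examples
#' txt <- c(
#'   "# demo peak table",
#'   "residue_index\tresidue_type\ttemperature_K\tdelta_H_ppm\tdelta_N_ppm\tintensity",
#'   "134\tQ\t303\t8.12\t119.4\t1.0e6"
#' )
#' read_peak_table(txt)
read_peak_table <- function(file,
                            dialect = c("tsv", "sparky"),
                            temperature = NULL,
                            offset = 0L,
                            validate = TRUE) {
  dialect <- match.arg(dialect)
  one_liner <- length(file) == 1L && !grepl("\n", file, fixed = TRUE)
  is_path <- one_liner && file.exists(file)
  if (one_liner && !is_path && !grepl("[\t ]", file)) {
    abort(paste0("file not found: ", file))
  }
  lines <- if (is_path) readLines(file, warn = FALSE) else unlist(strsplit(file, "\n", fixed = TRUE))
  if (dialect == "sparky" && is.null(temperature) && is_path) {
    temperature <- temperature_from_filename(file)
  }
  recs <- switch(dialect,
    tsv    = parse_tsv_peaks(lines),
    sparky = parse_sparky_peaks(lines, temperature)
  )
  recs$residue_index <- recs$residue_index + as.integer(offset)
  if (validate) validate_peak_records(recs)
  recs[setdiff(names(recs), ".line")]
}

temperature_from_filename <- function(path) {
  m <- regmatches(basename(path), regexpr("_([0-9]+(\\.[0-9]+)?)K\\.list$", basename(path)))
  if (length(m) == 0L) {
    abort("sparky dialect needs `temperature`, and none could be read from the filename")
  }
  as.numeric(sub("^_", "", sub("K\\.list$", "", m)))
}

tsv_header <- c("residue_index", "residue_type", "temperature_K",
                "delta_H_ppm", "delta_N_ppm", "intensity")

parse_tsv_peaks <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort("peak table has no header line")
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(tsv_header, trimws(header))
  if (length(missing_cols) > 0L) {
    abort(paste0("malformed peak-table header: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  col <- match(tsv_header, trimws(header))
  data_idx <- idx[-1L]
  if (length(data_idx) == 0L) return(empty_peak_tbl())
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < length(header))
  if (length(bad) > 0L) {
    abort(paste0("row(s) with too few fields at line(s) ",
                 paste(data_idx[bad], collapse = ", ")))
  }
  m <- do.call(rbind, fields)
  tibble(
    residue_index = as.integer(m[, col[1L]]),
    residue_type  = trimws(m[, col[2L]]),
    temperature   = as.numeric(m[, col[3L]]),
    delta_h       = as.numeric(m[, col[4L]]),
    delta_n       = as.numeric(m[, col[5L]]),
    intensity     = as.numeric(m[, col[6L]]),
    .line         = data_idx
  )
}

parse_sparky_peaks <- function(lines, temperature) {
  if (is.null(temperature)) abort("sparky dialect requires `temperature` (kelvin)")
  keep <- which(!grepl("^\\s*(#|$)", lines) & !grepl("^\\s*Assignment", lines))
  if (length(keep) == 0L) return(empty_peak_tbl())
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L) {
    abort(paste0("sparky row(s) with fewer than 4 fields at line(s) ",
                 paste(keep[bad], collapse = ", ")))
  }
  asg <- vapply(fields, `[[`, "", 1L)
  m <- regmatches(asg, regexec("^([A-Za-z])([0-9]+)N-?H$", asg))
  bad <- which(lengths(m) == 0L)
  if (length(bad) > 0L) {
    abort(paste0("unparsable assignment string(s) at line(s) ",
                 paste(keep[bad], collapse = ", "), ": ",
                 paste(asg[bad], collapse = ", ")))
  }
  tibble(
    residue_index = as.integer(vapply(m, `[[`, "", 3L)),
    residue_type  = toupper(vapply(m, `[[`, "", 2L)),
    temperature   = as.numeric(temperature),
    delta_h       = as.numeric(vapply(fields, `[[`, "", 3L)),
    delta_n       = as.numeric(vapply(fields, `[[`, "", 2L)),
    intensity     = as.numeric(vapply(fields, `[[`, "", 4L)),
    .line         = keep
  )
}

empty_peak_tbl <- function() {
  tibble(residue_index = integer(), residue_type = character(),
         temperature = double(), delta_h = double(), delta_n = double(),
         intensity = double(), .line = integer())
}

validate_peak_records <- function(recs) {
  checks <- list(
    "temperature outside [200, 400] K" =
      recs$temperature < 200 | recs$temperature > 400,
    "negative intensity" = recs$intensity < 0,
    "delta_h outside [-2, 15] ppm" = recs$delta_h < -2 | recs$delta_h > 15,
    "delta_n outside [90, 140] ppm" = recs$delta_n < 90 | recs$delta_n > 140,
    "non-finite numeric field" =
      !is.finite(recs$temperature) | !is.finite(recs$delta_h) |
      !is.finite(recs$delta_n) | !is.finite(recs$intensity)
  )
  msgs <- character()
  for (what in names(checks)) {
    bad <- which(checks[[what]])
    if (length(bad) > 0L) {
      ln <- if (".line" %in% names(recs)) recs$.line[bad] else bad
      msgs <- c(msgs, paste0(what, " at line(s) ", paste(ln, collapse = ", ")))
    }
  }
  if (length(msgs) > 0L) abort(paste(c("invalid peak record(s):", msgs), collapse = "\n"))
  invisible(recs)
}

#' Write a peak table
#'
#' Inverse of [read_peak_table()]: writes records in either dialect, so that a
#' write/read round trip reproduces the record fields exactly. The sparky
#' dialect holds one temperature per file, so mixed-temperature input is an
#' error there.
#'
#' @param records Tibble as returned by [read_peak_table()].
#' @param file Output path.
#' @inheritParams read_peak_table
#' @param offset Integer subtracted from residue indices on write (the inverse
#'   of the read-side offset).
#' @return `file`, invisibly.
#' @export
write_peak_table <- function(records, file, dialect = c("tsv", "sparky"),
                             offset = 0L) {
  dialect <- match.arg(dialect)
  records$residue_index <- records$residue_index - as.integer(offset)
  if (dialect == "tsv") {
    lines <- c(
      paste(tsv_header, collapse = "\t"),
      sprintf("%d\t%s\t%s\t%s\t%s\t%s",
              records$residue_index, records$residue_type,
              format(records$temperature, trim = TRUE, digits = 15),
              format(records$delta_h, trim = TRUE, digits = 15),
              format(records$delta_n, trim = TRUE, digits = 15),
              format(records$intensity, trim = TRUE, digits = 15))
    )
  } else {
    if (length(unique(records$temperature)) > 1L) {
      abort("sparky dialect holds a single temperature per file")
    }
    lines <- c(
      sprintf("%10s %8s %8s %12s", "Assignment", "w1", "w2", "Height"),
      sprintf("%10s %8s %8s %12s",
              paste0(records$residue_type, records$residue_index, "N-H"),
              format(records$delta_n, trim = TRUE, digits = 15),
              format(records$delta_h, trim = TRUE, digits = 15),
              format(records$intensity, trim = TRUE, digits = 15))
    )
  }
  writeLines(lines, file)
  invisible(file)
}

#' Re-reference shifts to the TSP signal
#'
#' Zeroes the proton axis to the observed TSP (3-(trimethylsilyl)propionate)
#' resonance at each temperature by subtracting its apparent 1H shift. When
#' `indirect_nitrogen = TRUE` the 15N axis is re-anchored indirectly through
#' the IUPAC 15N/1H frequency ratio; because chemical shift is a fractional
#' (ppm) quantity, moving the 1H zero by `s` ppm moves the ratio-derived 15N
#' zero by the same `s` ppm, so the correction applied to `delta_n` equals the
#' proton correction (the ratio itself cancels). Per-temperature offsets are
#' recorded in the `reference_offsets` attribute. Either way the correction is
#' a per-temperature constant, so per-step shift distances are unaffected.
#'
#' @param records Peak-record tibble.
#' @param tsp_shift_h Apparent 1H shift of TSP in ppm: a single number applied
#'   to all records, or a data frame with columns `temperature` and
#'   `tsp_shift_h` for per-temperature referencing.
#' @param indirect_nitrogen Also correct the 15N axis (default `TRUE`).
#' @param nitrogen_ratio IUPAC frequency ratio Xi(15N)/Xi(1H) used for the
#'   indirect re-anchoring (default 0.101329118, the standard value; it enters
#'   the zero-frequency mapping and cancels in ppm, and is exposed for
#'   documentation and non-standard referencing schemes).
#' @return The records with corrected shifts and a `reference_offsets`
#'   attribute (tibble: temperature, offset_h, offset_n).
#' @export
reference_to_tsp <- function(records, tsp_shift_h, indirect_nitrogen = TRUE,
                             nitrogen_ratio = 0.101329118) {
  stopifnot(nitrogen_ratio > 0)
  temps <- sort(unique(records$temperature))
  if (is.data.frame(tsp_shift_h)) {
    off <- tsp_shift_h$tsp_shift_h[match(records$temperature, tsp_shift_h$temperature)]
    if (anyNA(off)) abort("tsp_shift_h table lacks entries for some temperatures")
    off_tbl <- tsp_shift_h$tsp_shift_h[match(temps, tsp_shift_h$temperature)]
  } else {
    if (!is.finite(tsp_shift_h)) abort("tsp_shift_h must be finite")
    off <- rep(tsp_shift_h, nrow(records))
    off_tbl <- rep(tsp_shift_h, length(temps))
  }
  records$delta_h <- records$delta_h - off
  off_n <- if (indirect_nitrogen) off_tbl else rep(0, length(temps))
  if (indirect_nitrogen) records$delta_n <- records$delta_n - off
  attr(records, "reference_offsets") <-
    tibble(temperature = temps, offset_h = off_tbl, offset_n = off_n)
  records
}
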