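#' End-to-end analysis of a temperature series
#'
#' Runs the full residue-level workflow on an assembled series: missingness
#' filtering, per-step and cumulative shift distances, trajectory
#' classification, intensity summaries, percentile flagging of both
#' observables, top percentage-change ranking, and gated cross-correlation
#' matrices for the flagged residues.
#'
#' @param series A `melt_series`.
#' @param nitrogen_weight 15N weighting of the combined shift distance
#'   (default 0.14).
#' @param levels Percentile levels for cumulative-shift flags (default
#'   `c(90, 95)`).
#' @param pi_level Percentile level for the pooled intensity flags (default
#'   90).
#' @param linearity_threshold Trajectory nonlinearity threshold (default
#'   0.15).
#' @param max_missing Missing-point filter (default 3).
#' @param delta_gate,pi_gate Gate bounds for the two matrices (`NULL` =
#'   observable defaults, see [gate_matrix()]).
#' @param top_k Size of the percentage-change ranking (default 15).
#' @param ccm_residues `"percentile"` (default: correlate the residues
#'   flagged at the lowest requested level, as the matrices are meant to
#'   explain the flagged set) or `"all"`.
#' @param delta_kind Vector kind for the shift-distance matrix (default
#'   `"step"`).
#' @return A `melt_analysis` list: `series` (filtered), `dropped_residues`,
#'   `shift` (per-residue/temperature step and cumulative distances),
#'   `trajectories`, `profiles`, `sum_delta_flags`, `pi_flags`,
#'   `top_percent_change`, `ccm_delta`, `ccm_pi` (gated `melt_ccm`s or
#'   `NULL`), `params`.
#' @export
analyze_series <- function(series, nitrogen_weight = 0.14, levels = c(90, 95),
                           pi_level = 90, linearity_threshold = 0.15,
                           max_missing = 3, delta_gate = NULL, pi_gate = NULL,
                           top_k = 15, ccm_residues = c("percentile", "all"),
                           delta_kind = c("step", "cumulative")) {
  ccm_residues <- match.arg(ccm_residues)
  delta_kind <- match.arg(delta_kind)
  filtered <- filter_missing(series, max_missing)
  cum <- cumulative_shift(filtered, nitrogen_weight = nitrogen_weight)
  traj <- trajectory_classes(filtered, nitrogen_weight, linearity_threshold)
  profiles <- pi_summary(filtered)
  sd_flags <- flag_sum_delta(cum, levels)
  p_flags <- flag_pi(filtered, pi_level, profiles = profiles)
  topk <- top_percent_change(profiles, top_k)

  pick <- function(flagged, fallback) {
    r <- sort(unique(flagged))
    if (ccm_residues == "all" || length(r) < 2L) fallback else r
  }
  all_res <- sort(unique(as_tibble(filtered)$residue_index))
  delta_res <- pick(sd_flags$residue_index[sd_flags$level == min(levels)], all_res)
  pi_res <- pick(p_flags$residue_index, all_res)
  ccm_d <- if (length(all_res) >= 2L) {
    gate_matrix(build_ccm(filtered, "delta", residues = delta_res,
                          nitrogen_weight = nitrogen_weight,
                          delta_kind = delta_kind),
                low = delta_gate[1L], high = delta_gate[2L])
  }
  ccm_p <- if (length(all_res) >= 2L) {
    gate_matrix(build_ccm(filtered, "pi", residues = pi_res),
                low = pi_gate[1L], high = pi_gate[2L])
  }
  structure(
    list(series = filtered,
         dropped_residues = attr(filtered, "dropped_residues") %||% integer(0),
         shift = cum, trajectories = traj, profiles = profiles,
         sum_delta_flags = sd_flags, pi_flags = p_flags,
         top_percent_change = topk, ccm_delta = ccm_d, ccm_pi = ccm_p,
         params = list(nitrogen_weight = nitrogen_weight, levels = levels,
                       pi_level = pi_level,
                       linearity_threshold = linearity_threshold,
                       max_missing = max_missing, top_k = top_k,
                       delta_kind = delta_kind)),
    class = "melt_analysis"
  )
}

#' @export
print.melt_analysis <- function(x, ...) {
  cat("<melt_analysis>\n")
  print(glance(x))
  invisible(x)
}

#' @describeIn analyze_series One-row summary of an analysis: residue and
#'   temperature counts, dropped residues, flag counts, nonlinear-trajectory
#'   count.
#' @param x A `melt_analysis`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.melt_analysis <- function(x, ...) {
  tibble(
    n_residues = length(unique(as_tibble(x$series)$residue_index)),
    n_temperatures = length(series_temperatures(x$series)),
    n_dropped = length(x$dropped_residues),
    n_flagged_sum_delta = length(unique(x$sum_delta_flags$residue_index)),
    n_flagged_pi = nrow(x$pi_flags),
    n_nonlinear = sum(x$trajectories$trajectory_class == "nonlinear")
  )
}

#' @describeIn analyze_series Per-residue tidy summary: final cumulative
#'   shift distance, intensity statistics, trajectory class and flag
#'   memberships.
#' @exportS3Method generics::tidy
tidy.melt_analysis <- function(x, ...) {
  final_cum <- x$shift %>%
    group_by(.data$residue_index) %>%
    summarise(final_cum_delta = dplyr::last(.data$cum_delta), .groups = "drop")
  flagged90 <- unique(x$sum_delta_flags$residue_index[
    x$sum_delta_flags$level == min(x$params$levels)])
  flagged95 <- unique(x$sum_delta_flags$residue_index[
    x$sum_delta_flags$level == max(x$params$levels)])
  final_cum %>%
    left_join(x$profiles, by = "residue_index") %>%
    left_join(select(x$trajectories, "residue_index", "linearity_score",
                     "trajectory_class"),
              by = "residue_index") %>%
    mutate(flag_sum_delta_90 = .data$residue_index %in% flagged90,
           flag_sum_delta_95 = .data$residue_index %in% flagged95,
           flag_pi = .data$residue_index %in% x$pi_flags$residue_index)
}

default_config <- function() {
  list(
    dialect = "tsv", temperatures = NULL, offset = 0L,
    nitrogen_weight = 0.14, levels = c(90, 95), pi_level = 90,
    linearity_threshold = 0.15, max_missing = 3,
    delta_gate = c(-0.6, 0.6), pi_gate = c(-0.95, 0.95), top_k = 15,
    structure = NULL, structure_offset = 0L, probe_radius = 0.14,
    cluster_cutoff = 6.0, seed = 1L,
    n_residues = 100, n_transitioning = 5, n_high_dynamics = 5,
    group_size = 4, out_dir = "shiftmelt-out"
  )
}

#' Read a run configuration file
#'
#' YAML key-value file whose entries override the built-in defaults;
#' explicit arguments to [run_analyze()] / [run_simulate()] override the
#' file in turn.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  cfg
}

write_tsv_report <- function(df, path, title) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# shiftmelt: ", title), con)
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), "")
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

write_matrix_report <- function(m, path, title) {
  df <- as.data.frame(m)
  df <- cbind(residue = rownames(m), df)
  write_tsv_report(df, path, title)
}

#' Simulate a cohort and write peak lists plus ground truth
#'
#' Generates the default synthetic cohort under the configured seed and
#' writes a native-TSV peak table, the ground-truth scenario table, and a
#' JSON manifest into `out_dir`.
#'
#' @param config Named list overriding [read_config()] defaults (notable
#'   keys: `seed`, `n_residues`, `n_transitioning`, `n_high_dynamics`,
#'   `group_size`, `out_dir`).
#' @return Invisibly, a list with the written paths and the series.
#' @export
run_simulate <- function(config = list()) {
  cfg <- modifyList(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- default_cohort(n_residues = cfg$n_residues,
                         n_transitioning = cfg$n_transitioning,
                         n_high_dynamics = cfg$n_high_dynamics,
                         group_size = cfg$group_size, seed = cfg$seed)
  temps <- cfg$temperatures %||% seq(295, 323, by = 2)
  series <- generate_series(scen, temperatures = temps, seed = cfg$seed)
  peaks_path <- file.path(cfg$out_dir, "peaks.tsv")
  write_peak_table(as_tibble(series), peaks_path)
  truth_path <- file.path(cfg$out_dir, "ground_truth.tsv")
  write_tsv_report(scen, truth_path, "ground-truth scenarios")
  manifest <- list(tool = "shiftmelt", version = pkg_version(),
                   command = "simulate", config = cfg[order(names(cfg))],
                   files = list(peaks = peaks_path, ground_truth = truth_path))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(peaks = peaks_path, ground_truth = truth_path,
                 manifest = manifest_path, series = series))
}

pkg_version <- function() {
  as.character(utils::packageVersion("shiftmelt"))
}

#' Analyze peak lists end-to-end and write a report bundle
#'
#' Reads the configured peak tables, assembles and analyzes the series, and
#' writes: per-residue metrics, per-temperature percentile tables and
#' thresholds, full and gated cross-correlation matrices, and — when a
#' structure is configured — spatial clusters of the flagged residues plus a
#' PDB with the final cumulative shift distance in the B-factor column. A
#' JSON manifest records the configuration, package version, input checksums
#' and every filter decision.
#'
#' @param inputs Character vector of peak-table paths (native TSV, or Sparky
#'   `.list` files named `*_<kelvin>K.list`).
#' @param config Named list overriding [read_config()] defaults.
#' @return Invisibly, the `melt_analysis` with a `paths` attribute.
#' @export
run_analyze <- function(inputs, config = list()) {
  cfg <- modifyList(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- purrr::map_dfr(inputs, function(p) {
    if (grepl("\\.list$", p)) {
      read_peak_table(p, dialect = "sparky", offset = cfg$offset)
    } else {
      read_peak_table(p, dialect = cfg$dialect, offset = cfg$offset)
    }
  })
  series <- assemble_series(recs)
  an <- analyze_series(series,
                       nitrogen_weight = cfg$nitrogen_weight,
                       levels = cfg$levels, pi_level = cfg$pi_level,
                       linearity_threshold = cfg$linearity_threshold,
                       max_missing = cfg$max_missing,
                       delta_gate = cfg$delta_gate, pi_gate = cfg$pi_gate,
                       top_k = cfg$top_k)
  out <- cfg$out_dir
  paths <- list(
    residue_metrics = file.path(out, "residue_metrics.tsv"),
    shift_long = file.path(out, "cumulative_shift.tsv"),
    sum_delta_flags = file.path(out, "sum_delta_percentiles.tsv"),
    sum_delta_thresholds = file.path(out, "sum_delta_thresholds.tsv"),
    pi_flags = file.path(out, "pi_percentiles.tsv"),
    top_percent_change = file.path(out, "top_percent_change.tsv"),
    manifest = file.path(out, "manifest.json")
  )
  write_tsv_report(tidy(an), paths$residue_metrics, "per-residue metrics")
  write_tsv_report(an$shift, paths$shift_long, "per-step and cumulative shift distances")
  write_tsv_report(an$sum_delta_flags, paths$sum_delta_flags,
                   "cumulative-shift percentile flags")
  write_tsv_report(flag_thresholds(an$sum_delta_flags), paths$sum_delta_thresholds,
                   "cumulative-shift fitted thresholds")
  write_tsv_report(an$pi_flags, paths$pi_flags, "intensity percentile flags")
  write_tsv_report(an$top_percent_change, paths$top_percent_change,
                   "top residues by percent intensity change")
  for (tag in c("delta", "pi")) {
    ccm <- an[[paste0("ccm_", tag)]]
    if (is.null(ccm)) next
    paths[[paste0("ccm_", tag)]] <- file.path(out, paste0("ccm_", tag, ".tsv"))
    paths[[paste0("ccm_", tag, "_gated")]] <- file.path(out, paste0("ccm_", tag, "_gated.tsv"))
    write_matrix_report(ccm$rho, paths[[paste0("ccm_", tag)]],
                        paste0(tag, " cross-correlation matrix"))
    write_matrix_report(ccm$rho_gated, paths[[paste0("ccm_", tag, "_gated")]],
                        paste0(tag, " cross-correlation matrix (gated ",
                               ccm$gate[1], ", ", ccm$gate[2], ")"))
  }
  cluster_tbl <- NULL
  # exact indexing: cfg$structure would partial-match structure_offset when
  # modifyList() has dropped a NULL-valued structure entry
  if (!is.null(cfg[["structure"]])) {
    model <- read_structure(cfg[["structure"]], offset = cfg[["structure_offset"]])
    flagged <- intersect(unique(an$sum_delta_flags$residue_index),
                         unique(model$residue_index))
    if (length(flagged) > 0L) {
      cluster_tbl <- spatial_clusters(model, flagged, cutoff = cfg$cluster_cutoff)
      paths$clusters <- file.path(out, "spatial_clusters.tsv")
      write_tsv_report(cluster_tbl, paths$clusters, "single-linkage spatial clusters")
    }
    final_cum <- an$shift %>%
      group_by(.data$residue_index) %>%
      summarise(value = dplyr::last(.data$cum_delta), .groups = "drop")
    paths$bfactor_pdb <- file.path(out, "sum_delta_bfactor.pdb")
    export_bfactor_map(model, final_cum, paths$bfactor_pdb)
  }
  manifest <- list(
    tool = "shiftmelt", version = pkg_version(), command = "analyze",
    config = cfg[order(names(cfg))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    dropped_residues = an$dropped_residues,
    n_flagged_sum_delta = length(unique(an$sum_delta_flags$residue_index)),
    n_flagged_pi = nrow(an$pi_flags),
    outputs = paths[setdiff(names(paths), "manifest")]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  attr(an, "paths") <- paths
  attr(an, "clusters") <- cluster_tbl
  invisible(an)
}
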