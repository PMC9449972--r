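#' @section Synthetic scenarios:
#' A scenario table has one row per residue with the generating parameters:
#' linear per-kelvin drift of both shift axes, an optional two-state
#' (logistic) transition with midpoint/width/amplitudes, a quadratic
#' intensity profile peaking mid-melt, additive shift noise, multiplicative
#' (fractional) intensity noise, and a list of deliberately missing
#' temperatures. Ground-truth labels ride along for recovery scoring.
#' @name synthetic-scenarios
NULL

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

empty_scenarios <- function(n) {
  tibble(
    residue_index = integer(n), residue_type = character(n),
    base_h = double(n), base_n = double(n),
    drift_h = double(n), drift_n = double(n),
    trans_midpoint = NA_real_, trans_width = NA_real_,
    trans_amp_h = NA_real_, trans_amp_n = NA_real_,
    pi_peak_temperature = double(n), pi_peak_value = double(n),
    pi_curvature = double(n),
    noise_sd_h = double(n), noise_sd_n = double(n), noise_sd_pi = double(n),
    missing_temperatures = vector("list", n),
    label = character(n), group_id = NA_integer_
  )
}

draw_base_scenarios <- function(idx) {
  n <- length(idx)
  sc <- empty_scenarios(n)
  sc$residue_index <- as.integer(idx)
  sc$residue_type <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                            n, replace = TRUE)
  sc$base_h <- runif(n, 7.5, 9.5)
  sc$base_n <- runif(n, 108, 130)
  sc$drift_h <- -runif(n, 0.001, 0.004)
  sc$drift_n <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.005, 0.02)
  sc$pi_peak_temperature <- runif(n, 305, 313)
  sc$pi_peak_value <- runif(n, 0.8e6, 1.2e6)
  frac <- runif(n, 0.25, 0.45)
  sc$pi_curvature <- frac * sc$pi_peak_value / (sc$pi_peak_temperature - 295)^2
  sc$noise_sd_h <- 0.0015
  sc$noise_sd_n <- 0.008
  sc$noise_sd_pi <- 0.03
  sc$missing_temperatures <- replicate(n, numeric(0), simplify = FALSE)
  sc$label <- "drifting"
  sc
}

add_transition <- function(sc) {
  n <- nrow(sc)
  sc$trans_midpoint <- runif(n, 305, 307)
  sc$trans_width <- runif(n, 0.8, 1.6)
  sc$trans_amp_h <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.14, 0.22)
  sc$trans_amp_n <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.7, 1.1)
  sc$label <- "transitioning"
  sc
}

#' Scenarios for a group of residues sharing one latent transition
#'
#' Builds `k` residue scenarios that respond to one shared conformational
#' transition (same midpoint, width and base amplitudes, one shared sign per
#' axis) with small independent amplitude perturbations and independent
#' noise — the construction behind correlated off-diagonal blocks in the
#' shift-distance cross-correlation matrix.
#'
#' @param k Group size (>= 2).
#' @param seed Integer seed for the parameter draws.
#' @param residue_indices Residue indices to use (default `1:k`).
#' @param midpoint,width Shared transition midpoint and width (kelvin).
#' @param amp_h,amp_n Shared amplitude magnitudes (ppm).
#' @param amp_jitter Fractional independent perturbation of each member's
#'   amplitudes (default 0.05).
#' @param noise_sd_h,noise_sd_n,noise_sd_pi Independent noise levels.
#' @param group_id Label for the group (default 1).
#' @return A scenario tibble of `k` rows.
#' @export
make_correlated_group <- function(k = 4, seed = 1, residue_indices = seq_len(k),
                                  midpoint = 306, width = 2.0,
                                  amp_h = 0.18, amp_n = 1.0, amp_jitter = 0.05,
                                  noise_sd_h = 0.0015, noise_sd_n = 0.008,
                                  noise_sd_pi = 0.03, group_id = 1L) {
  stopifnot(k >= 2, length(residue_indices) == k, width > 0)
  local_seed(seed, {
    sc <- draw_base_scenarios(residue_indices)
    shared_drift_h <- -runif(1, 0.001, 0.004)
    shared_drift_n <- sample(c(-1, 1), 1) * runif(1, 0.005, 0.02)
    sign_h <- sample(c(-1, 1), 1)
    sign_n <- sample(c(-1, 1), 1)
    sc$drift_h <- shared_drift_h
    sc$drift_n <- shared_drift_n
    sc$trans_midpoint <- midpoint
    sc$trans_width <- width
    sc$trans_amp_h <- sign_h * amp_h * (1 + runif(k, -amp_jitter, amp_jitter))
    sc$trans_amp_n <- sign_n * amp_n * (1 + runif(k, -amp_jitter, amp_jitter))
    sc$noise_sd_h <- noise_sd_h
    sc$noise_sd_n <- noise_sd_n
    sc$noise_sd_pi <- noise_sd_pi
    sc$label <- "transitioning"
    sc$group_id <- as.integer(group_id)
    sc
  })
}

#' Default synthetic cohort (the package's standard study conditions)
#'
#' One hundred residues observed over a 295-323 K melt in 2 K steps: most
#' residues drift linearly with temperature-coefficient-scale slopes; a few
#' carry a localized two-state transition near 306 K; a few are highly
#' dynamic (elevated intensity throughout); one small group shares a latent
#' transition (see [make_correlated_group()]); a handful of residues have 1-3
#' missing temperature points and a couple exceed the missingness filter.
#' All parameter draws are seeded.
#'
#' @param n_residues Cohort size (default 100).
#' @param n_transitioning Residues with an independent planted transition
#'   (default 5).
#' @param n_high_dynamics Residues with elevated intensity (default 5).
#' @param group_size Size of the correlated group (default 4; 0 disables).
#' @param n_missing_light Residues given 1-3 missing points (default 8).
#' @param n_dropped Residues given 4-5 missing points, i.e. destined for the
#'   missingness filter (default 2).
#' @param seed Integer seed.
#' @return Scenario tibble (see [generate_series()]).
#' @export
default_cohort <- function(n_residues = 100, n_transitioning = 5,
                           n_high_dynamics = 5, group_size = 4,
                           n_missing_light = 8, n_dropped = 2, seed = 1) {
  stopifnot(n_residues >= n_transitioning + n_high_dynamics + group_size +
              n_missing_light + n_dropped)
  local_seed(seed, {
    idx <- seq_len(n_residues)
    sc <- draw_base_scenarios(idx)
    special <- sample(idx, n_transitioning + n_high_dynamics + group_size +
                        n_missing_light + n_dropped)
    take <- function(n) {
      out <- special[seq_len(n)]
      special <<- special[-seq_len(n)]
      out
    }
    trans_idx <- take(n_transitioning)
    dyn_idx <- take(n_high_dynamics)
    grp_idx <- if (group_size > 0) take(group_size) else integer(0)
    light_idx <- take(n_missing_light)
    drop_idx <- take(n_dropped)

    if (n_transitioning > 0) {
      sc[match(trans_idx, idx), ] <- add_transition(sc[match(trans_idx, idx), ])
    }
    if (n_high_dynamics > 0) {
      j <- match(dyn_idx, idx)
      sc$pi_peak_value[j] <- runif(length(j), 2.5e6, 3.5e6)
      sc$pi_curvature[j] <- runif(length(j), 0.25, 0.45) *
        sc$pi_peak_value[j] / (sc$pi_peak_temperature[j] - 295)^2
      sc$label[j] <- "high_dynamics"
    }
    if (group_size > 0) {
      grp <- make_correlated_group(group_size, seed = seed + 104729L,
                                   residue_indices = grp_idx)
      # keep the cohort's own base positions/PI draws, adopt the shared signal
      j <- match(grp_idx, idx)
      shared <- c("drift_h", "drift_n", "trans_midpoint", "trans_width",
                  "trans_amp_h", "trans_amp_n", "label", "group_id")
      sc[j, shared] <- grp[, shared]
    }
    temps <- seq(295, 323, by = 2)
    for (ri in light_idx) {
      sc$missing_temperatures[[match(ri, idx)]] <- sort(sample(temps, sample(1:3, 1)))
    }
    for (ri in drop_idx) {
      sc$missing_temperatures[[match(ri, idx)]] <- sort(sample(temps, sample(4:5, 1)))
    }
    sc
  })
}

#' Generate a synthetic temperature series from scenarios
#'
#' Evaluates each scenario over the temperature grid:
#' `dH(T) = base_h + drift_h*(T - T0) + amp_h * logistic((T - midpoint)/width)
#' + noise`, analogously for the 15N axis, and
#' `PI(T) = (peak - curvature*(T - peak_T)^2) * (1 + noise)` (floored at a
#' small positive value), then omits the listed missing temperatures.
#' Randomness comes exclusively from `seed` (Mersenne-Twister, inversion
#' normals, drawn in fixed residue-major order), so identical
#' (scenarios, seed) give bit-identical output.
#'
#' @param scenarios Scenario tibble ([default_cohort()],
#'   [make_correlated_group()], or hand-built).
#' @param temperatures Temperature grid in kelvin (default 295-323 K in 2 K
#'   steps).
#' @param seed Integer seed for the noise draws.
#' @return A `melt_series` with the scenario table (ground truth) in the
#'   `ground_truth` attribute; retrieve it with [ground_truth()].
#' @export
generate_series <- function(scenarios, temperatures = seq(295, 323, by = 2),
                            seed = 1) {
  stopifnot(nrow(scenarios) > 0, length(temperatures) >= 2,
            !is.unsorted(temperatures, strictly = TRUE))
  if (anyDuplicated(scenarios$residue_index)) {
    abort("duplicate residue_index across scenarios")
  }
  t0 <- temperatures[1L]
  nt <- length(temperatures)
  recs <- local_seed(seed, {
    purrr::pmap_dfr(scenarios, function(residue_index, residue_type, base_h,
                                        base_n, drift_h, drift_n,
                                        trans_midpoint, trans_width,
                                        trans_amp_h, trans_amp_n,
                                        pi_peak_temperature, pi_peak_value,
                                        pi_curvature, noise_sd_h, noise_sd_n,
                                        noise_sd_pi, missing_temperatures,
                                        ...) {
      sig <- if (!is.na(trans_midpoint)) {
        stats::plogis((temperatures - trans_midpoint) / trans_width)
      } else 0
      dh <- base_h + drift_h * (temperatures - t0) +
        (if (!is.na(trans_midpoint)) trans_amp_h * sig else 0) +
        rnorm(nt, sd = noise_sd_h)
      dn <- base_n + drift_n * (temperatures - t0) +
        (if (!is.na(trans_midpoint)) trans_amp_n * sig else 0) +
        rnorm(nt, sd = noise_sd_n)
      pi_det <- pi_peak_value - pi_curvature * (temperatures - pi_peak_temperature)^2
      pi <- pmax(pi_det * (1 + rnorm(nt, sd = noise_sd_pi)), 0.01 * pi_peak_value)
      keep <- !temperatures %in% missing_temperatures
      tibble(residue_index = residue_index, residue_type = residue_type,
             temperature = temperatures[keep], delta_h = dh[keep],
             delta_n = dn[keep], intensity = pi[keep])
    })
  })
  series <- assemble_series(recs)
  attr(series, "temperatures") <- temperatures
  attr(series, "ground_truth") <- scenarios
  series
}

#' Ground-truth labels of a synthetic series
#' @param series A `melt_series` made by [generate_series()].
#' @return The scenario tibble, or `NULL` for non-synthetic series.
#' @export
ground_truth <- function(series) attr(series, "ground_truth")
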