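#' Spearman rank correlation coefficient
#'
#' Rank correlation of two paired vectors. Pairs with a missing member are
#' dropped first. When the remaining values are tie-free in both vectors the
#' classic formula is used,
#' \deqn{\rho = 1 - \frac{6\sum d_i^2}{n(n^2-1)}}
#' with `d_i` the difference between a pair of ranks and `n` the number of
#' observations; in the presence of ties the coefficient falls back to the
#' Pearson correlation of mid-ranks (which reduces to the same value when
#' tie-free). Fewer than 2 complete pairs yields `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The coefficient as a single number, with attributes `n` (complete
#'   pairs used) and `ties` (whether the mid-rank fallback was taken).
#' @export
#' @examples
#' spearman_rho(1:5, c(3, 1, 2, 5, 4)) # 0.6
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) {
    return(structure(NA_real_, n = n, ties = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  rho <- if (!ties) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    NA_real_
  } else {
    cor(rx, ry)
  }
  structure(rho, n = n, ties = ties)
}

#' Residue-residue Spearman cross-correlation matrix
#'
#' Correlates every pair of residues' thermal responses across the melt. For
#' the `"delta"` observable each residue's vector is its per-step shift
#' distance at consecutive observed temperatures (the cumulative curve is
#' selectable via `delta_kind = "cumulative"`); for `"pi"` it is the
#' per-temperature peak intensity. Coefficients are computed on
#' pairwise-complete temperatures; cells with fewer than `min_overlap`
#' overlapping points are masked as low-confidence (`NA`).
#'
#' @param series A `melt_series`.
#' @param observable `"delta"` (shift-distance steps) or `"pi"` (intensity).
#' @param residues Residue subset to correlate (default: all residues in the
#'   series with enough observations; analyses typically pass the
#'   90th-percentile residues).
#' @param nitrogen_weight Passed to [cumulative_shift()] for `"delta"`.
#' @param delta_kind `"step"` (default) or `"cumulative"`.
#' @param min_overlap Minimum overlapping temperature count for a cell
#'   (default 4).
#' @return A `melt_ccm` object: list with `rho` (symmetric matrix, unit
#'   diagonal where defined), `n_obs` (overlap counts), `residues`,
#'   `observable`, `delta_kind`, `gate` (`NULL` until [gate_matrix()]).
#' @export
build_ccm <- function(series, observable = c("delta", "pi"), residues = NULL,
                      nitrogen_weight = 0.14, delta_kind = c("step", "cumulative"),
                      min_overlap = 4) {
  observable <- match.arg(observable)
  delta_kind <- match.arg(delta_kind)
  tbl <- as_tibble(series)
  if (observable == "delta") {
    cs <- cumulative_shift(series, nitrogen_weight = nitrogen_weight)
    val_col <- if (delta_kind == "step") "step_delta" else "cum_delta"
    long <- select(cs, "residue_index", "temperature", value = dplyr::all_of(val_col))
    if (delta_kind == "step") long <- filter(long, !is.na(.data$value))
  } else {
    long <- select(tbl, "residue_index", "temperature", value = "intensity")
  }
  if (is.null(residues)) residues <- sort(unique(long$residue_index))
  residues <- as.integer(residues)
  if (length(residues) == 0L) abort("residue subset is empty")
  long <- filter(long, .data$residue_index %in% residues)
  temps <- sort(unique(long$temperature))
  V <- matrix(NA_real_, nrow = length(temps), ncol = length(residues),
              dimnames = list(NULL, residues))
  V[cbind(match(long$temperature, temps), match(long$residue_index, residues))] <- long$value

  k <- ncol(V)
  obs <- !is.na(V)
  n_obs <- crossprod(obs)
  rho <- matrix(NA_real_, k, k, dimnames = dimnames(n_obs))
  complete <- colSums(obs) == nrow(V)
  if (sum(complete) >= 2L && nrow(V) >= 2L) {
    R <- apply(V[, complete, drop = FALSE], 2L, rank)
    rho[complete, complete] <- suppressWarnings(cor(R))
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i || (complete[i] && complete[j])) next
      r <- spearman_rho(V[, i], V[, j])
      rho[i, j] <- rho[j, i] <- as.numeric(r)
    }
  }
  rho[n_obs < min_overlap] <- NA_real_
  diag(rho) <- ifelse(diag(n_obs) >= 2L, 1, NA_real_)
  structure(
    list(rho = rho, n_obs = n_obs, residues = residues,
         observable = observable, delta_kind = delta_kind,
         min_overlap = min_overlap, gate = NULL),
    class = "melt_ccm"
  )
}

#' @export
print.melt_ccm <- function(x, ...) {
  cat(sprintf("<melt_ccm> %s (%s): %d x %d residues%s\n",
              x$observable,
              if (x$observable == "delta") x$delta_kind else "per-temperature",
              length(x$residues), length(x$residues),
              if (is.null(x$gate)) "" else sprintf(", gated (%g, %g)",
                                                   x$gate[1], x$gate[2])))
  invisible(x)
}

#' Mask weak correlations in a cross-correlation matrix
#'
#' Cells with `low < rho < high` (strict interior) are masked to reduce
#' noise, mirroring a white coloring gate on the matrix heat map; a value
#' sitting exactly on a gate boundary is retained. Defaults depend on the
#' observable: (-0.6, 0.6) for shift-distance matrices and (-0.95, 0.95) for
#' intensity matrices.
#'
#' @param ccm A `melt_ccm`.
#' @param low,high Gate bounds, `low < high`; `NULL` picks the observable's
#'   default.
#' @return The `melt_ccm` with `rho_gated` (masked matrix, symmetric) and
#'   `gate` filled in.
#' @export
gate_matrix <- function(ccm, low = NULL, high = NULL) {
  stopifnot(inherits(ccm, "melt_ccm"))
  default <- if (ccm$observable == "delta") c(-0.6, 0.6) else c(-0.95, 0.95)
  if (is.null(low)) low <- default[1L]
  if (is.null(high)) high <- default[2L]
  if (!(low < high)) abort("gate requires low < high")
  g <- ccm$rho
  g[!is.na(g) & g > low & g < high] <- NA_real_
  ccm$rho_gated <- g
  ccm$gate <- c(low = low, high = high)
  ccm
}

#' @describeIn build_ccm Tidy a `melt_ccm` into a long pair table
#'   (upper triangle): `residue_i`, `residue_j`, `rho`, `n_obs`, and `pass_gate`
#'   when gated.
#' @param x A `melt_ccm`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.melt_ccm <- function(x, ...) {
  k <- length(x$residues)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble(
    residue_i = x$residues[idx[, 1L]],
    residue_j = x$residues[idx[, 2L]],
    rho = x$rho[idx],
    n_obs = as.integer(x$n_obs[idx])
  )
  if (!is.null(x$gate)) out$pass_gate <- !is.na(x$rho_gated[idx])
  out
}

#' @describeIn build_ccm One-row summary of a `melt_ccm`: residue count, pair
#'   count, median absolute rho, and the gated-pair count when gated.
#' @exportS3Method generics::glance
glance.melt_ccm <- function(x, ...) {
  pairs <- tidy(x)
  tibble(
    observable = x$observable,
    n_residues = length(x$residues),
    n_pairs = nrow(pairs),
    median_abs_rho = stats::median(abs(pairs$rho), na.rm = TRUE),
    n_pass_gate = if (!is.null(x$gate)) sum(pairs$pass_gate, na.rm = TRUE) else NA_integer_
  )
}
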