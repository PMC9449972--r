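test_that("the rank-correlation worked example is exact", {
  rho <- spearman_rho(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  # sum d_i^2 = 8, 1 - 48/120
  expect_identical(as.numeric(rho), 0.6)
  expect_equal(attr(rho, "n"), 5L)
  expect_false(attr(rho, "ties"))
})

test_that("perfect concordance and discordance hit the bounds", {
  x <- sort(runif(10))
  expect_equal(as.numeric(spearman_rho(x, x)), 1)
  expect_equal(as.numeric(spearman_rho(x, rev(x))), -1)
})

test_that("incomplete pairs are dropped; n < 2 is not-a-value", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 1, 3, NA, 6)
  r <- spearman_rho(x, y)
  expect_equal(attr(r, "n"), 3L)
  r2 <- spearman_rho(c(1, NA), c(NA, 2))
  expect_true(is.na(as.numeric(r2)))
  expect_equal(attr(r2, "n"), 0L)
})

test_that("the mid-rank tie fallback agrees with the standard estimator", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    x <- sample(1:5, n, replace = TRUE) # plenty of ties
    y <- rnorm(n)
    expect_equal(as.numeric(spearman_rho(x, y)),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    # and tie-free data matches the classic formula route too
    xf <- rnorm(n); yf <- rnorm(n)
    expect_equal(as.numeric(spearman_rho(xf, yf)),
                 cor(xf, yf, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly increasing monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    base <- as.numeric(spearman_rho(x, y))
    expect_equal(as.numeric(spearman_rho(exp(x), y)), base)
    expect_equal(as.numeric(spearman_rho(x, y^3)), base)
    expect_equal(as.numeric(spearman_rho(2 * x + 7, atan(y))), base)
  }
})

test_that("matrix construction equals a brute-force double loop", {
  set.seed(41)
  for (i in 1:50) {
    n_res <- sample(3:6, 1)
    temps <- seq(295, 305, by = 2)
    recs <- expand.grid(residue_index = seq_len(n_res), temperature = temps)
    recs <- tibble::tibble(residue_index = as.integer(recs$residue_index),
                           residue_type = "A", temperature = recs$temperature,
                           delta_h = 8 + cumsum(rnorm(nrow(recs), sd = 0.01)),
                           delta_n = 115 + cumsum(rnorm(nrow(recs), sd = 0.05)),
                           intensity = runif(nrow(recs), 1e5, 1e6))
    # knock out a few observations to exercise pairwise-complete handling
    if (i %% 2 == 0) recs <- recs[-sample(nrow(recs), 2), ]
    s <- assemble_series(recs)
    for (obs in c("delta", "pi")) {
      ccm <- build_ccm(s, obs, min_overlap = 2)
      V <- if (obs == "pi") {
        tidyr::pivot_wider(tibble::as_tibble(s)[c("residue_index", "temperature", "intensity")],
                           names_from = "residue_index", values_from = "intensity")
      } else {
        cs <- suppressMessages(cumulative_shift(s))
        cs <- cs[!is.na(cs$step_delta), ]
        tidyr::pivot_wider(cs[c("residue_index", "temperature", "step_delta")],
                           names_from = "residue_index", values_from = "step_delta")
      }
      V <- as.matrix(V[order(V$temperature), as.character(ccm$residues)])
      for (a in seq_along(ccm$residues)) {
        for (b in seq_along(ccm$residues)) {
          if (a == b) next
          expected <- as.numeric(spearman_rho(V[, a], V[, b]))
          n_ab <- sum(is.finite(V[, a]) & is.finite(V[, b]))
          if (n_ab < 2) expected <- NA_real_
          expect_equal(unname(ccm$rho[a, b]), expected, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the matrix is symmetric with unit diagonal and bounded entries", {
  s <- generate_series(default_cohort(n_residues = 20, n_transitioning = 2,
                                      n_high_dynamics = 2, group_size = 2,
                                      n_missing_light = 3, n_dropped = 0,
                                      seed = 5), seed = 5)
  ccm <- suppressMessages(build_ccm(s, "delta"))
  expect_equal(ccm$rho, t(ccm$rho))
  expect_true(all(diag(ccm$rho) == 1, na.rm = TRUE))
  expect_true(all(abs(ccm$rho) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(ccm$n_obs <= length(series_temperatures(s))))
})

test_that("gating masks the strict interior and preserves symmetry", {
  s <- toy_series(4, c(295, 297, 299, 301, 303))
  ccm <- suppressMessages(build_ccm(s, "pi", min_overlap = 2))
  ccm$rho[1, 2] <- ccm$rho[2, 1] <- 0.6   # exact boundary value
  ccm$rho[1, 3] <- ccm$rho[3, 1] <- 0.3   # interior
  ccm$rho[2, 3] <- ccm$rho[3, 2] <- -1    # exact extreme
  g <- gate_matrix(ccm, -0.6, 0.6)
  expect_equal(g$rho_gated[1, 2], 0.6)        # boundary retained
  expect_true(is.na(g$rho_gated[1, 3]))       # interior masked
  expect_equal(g$rho_gated[2, 3], -1)
  expect_equal(g$rho_gated, t(g$rho_gated))
  # empty gate masks nothing; full gate keeps only exact +/-1 and diagonal
  g0 <- gate_matrix(ccm, 0, 0 + 1e-12)
  expect_equal(is.na(g0$rho_gated), is.na(ccm$rho))
  g1 <- gate_matrix(ccm, -1, 1)
  kept <- !is.na(g1$rho_gated)
  expect_true(all(abs(g1$rho_gated[kept]) == 1))
})

test_that("observable defaults pick the right gate", {
  s <- toy_series(3, c(295, 297, 299, 301))
  gd <- gate_matrix(suppressMessages(build_ccm(s, "delta", min_overlap = 2)))
  gp <- gate_matrix(build_ccm(s, "pi", min_overlap = 2))
  expect_equal(unname(gd$gate), c(-0.6, 0.6))
  expect_equal(unname(gp$gate), c(-0.95, 0.95))
})

test_that("tidy and glance summarize pair structure faithfully", {
  s <- toy_series(5, c(295, 297, 299, 301))
  ccm <- gate_matrix(build_ccm(s, "pi", min_overlap = 2))
  pairs <- tidy(ccm)
  expect_equal(nrow(pairs), choose(5, 2))
  gl <- glance(ccm)
  expect_equal(gl$n_pairs, choose(5, 2))
  expect_equal(gl$n_pass_gate, sum(pairs$pass_gate, na.rm = TRUE))
})
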