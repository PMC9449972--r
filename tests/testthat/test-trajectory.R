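test_that("the combined shift distance evaluates its closed form", {
  expect_equal(delta_shift(8, 115, 8, 115), 0)
  expect_equal(delta_shift(8, 115, 8.03, 115, nitrogen_weight = 0.5), 0.03)
  # sqrt(0.03^2 + (0.14 * 0.2)^2) = sqrt(0.0009 + 0.000784)
  expect_equal(delta_shift(8, 115, 8.03, 115.2, nitrogen_weight = 0.14),
               sqrt(0.0009 + 0.000784))
})

test_that("the shift distance is a metric on peak positions", {
  set.seed(101)
  for (i in 1:50) {
    p <- matrix(c(runif(3, 6, 10), runif(3, 105, 135)), ncol = 2)
    d12 <- delta_shift(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- delta_shift(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- delta_shift(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- delta_shift(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_identical(d12, d21)
    expect_gte(d13 + d23, d12 - 1e-12)
  }
  expect_equal(delta_shift(8.1, 120, 8.1, 120), 0)
})

test_that("cumulative distance accumulates step distances from zero", {
  # two points: the cumulative value at T2 is the single step
  recs <- tibble::tibble(residue_index = 1L, residue_type = "A",
                         temperature = c(295, 297),
                         delta_h = c(8, 8.05), delta_n = c(115, 115),
                         intensity = 1e5)
  cs <- cumulative_shift(assemble_series(recs))
  expect_equal(cs$cum_delta, c(0, 0.05))
  expect_true(is.na(cs$step_delta[1]))

  # four points with equal 0.01 steps sum to 0.03
  recs4 <- tibble::tibble(residue_index = 1L, residue_type = "A",
                          temperature = c(295, 297, 299, 301),
                          delta_h = 8 + 0.01 * (0:3), delta_n = 115,
                          intensity = 1e5)
  cs4 <- cumulative_shift(assemble_series(recs4))
  expect_equal(cs4$cum_delta, c(0, 0.01, 0.02, 0.03))

  # a static peak accumulates nothing
  recs0 <- recs4
  recs0$delta_h <- 8
  expect_equal(cumulative_shift(assemble_series(recs0))$cum_delta, rep(0, 4))
})

test_that("a gap is bridged by one distance between flanking observations", {
  recs <- tibble::tibble(residue_index = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
                         residue_type = "A",
                         temperature = c(295, 297, 301, 295, 297, 299, 301),
                         delta_h = c(8, 8.01, 8.03, 8, 8, 8, 8),
                         delta_n = 115, intensity = 1e5)
  cs <- cumulative_shift(assemble_series(recs), residues = 1)
  # the 297 -> 301 step (299 missing) is a single 0.02 distance at 301 K
  expect_equal(cs$temperature, c(295, 297, 301))
  expect_equal(cs$step_delta[3], 0.02)
  expect_equal(cs$cum_delta, c(0, 0.01, 0.03))
})

test_that("fewer than two observations is an explicit error", {
  recs <- tibble::tibble(residue_index = c(1L, 2L, 2L), residue_type = "A",
                         temperature = c(295, 295, 297), delta_h = 8,
                         delta_n = 115, intensity = 1e5)
  s <- assemble_series(recs)
  expect_error(cumulative_shift(s, residues = 1), "insufficient points")
  expect_message(cs <- cumulative_shift(s), "skipping")
  expect_equal(unique(cs$residue_index), 2L)
})

test_that("cumulative distance is monotone non-decreasing for every residue", {
  s <- generate_series(default_cohort(seed = 3), seed = 3)
  cs <- suppressMessages(cumulative_shift(s))
  diffs <- unlist(tapply(cs$cum_delta, cs$residue_index, diff))
  expect_true(all(diffs >= -1e-12))
})

test_that("collinear trajectories score zero and classify linear", {
  out <- classify_trajectory(8 + 0.01 * (0:5), 115 + 0.1 * (0:5))
  expect_equal(out$linearity_score, 0)
  expect_equal(out$trajectory_class, "linear")
})

test_that("a right-angle dog-leg matches the geometry oracle and is nonlinear", {
  # equal legs in weighted space: H leg then N leg of the same weighted size
  leg <- 0.05
  h <- c(0, leg, leg)
  n <- c(0, 0, leg / 0.14)
  out <- classify_trajectory(h, n)
  expect_equal(out$linearity_score, oracle_linearity(h, 0.14 * n))
  # closed form: single intermediate point at distance leg/sqrt(2), path 2*leg
  expect_equal(out$linearity_score, 1 / (2 * sqrt(2)))
  expect_equal(out$trajectory_class, "nonlinear")
})

test_that("the linearity score is invariant under scaling, rotation, translation", {
  set.seed(5)
  for (i in 1:20) {
    h <- cumsum(rnorm(6, sd = 0.01))
    n <- cumsum(rnorm(6, sd = 0.05))
    base <- classify_trajectory(h, n, nitrogen_weight = 1)$linearity_score
    s <- runif(1, 0.1, 10)
    expect_equal(classify_trajectory(s * h, s * n, nitrogen_weight = 1)$linearity_score,
                 base, tolerance = 1e-10)
    th <- runif(1, 0, 2 * pi)
    hr <- cos(th) * h - sin(th) * n + 3
    nr <- sin(th) * h + cos(th) * n - 2
    expect_equal(classify_trajectory(hr, nr, nitrogen_weight = 1)$linearity_score,
                 base, tolerance = 1e-10)
    expect_equal(base, oracle_linearity(h, n), tolerance = 1e-10)
  }
})

test_that("trajectory classification needs at least three positions", {
  expect_error(classify_trajectory(c(8, 8.1), c(115, 115.5)), "3 positions")
})
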