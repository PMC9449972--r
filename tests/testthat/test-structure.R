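test_that("a minimal PDB parses with exact coordinates and offset arithmetic", {
  f <- write_toy_pdb(resno = 7L, resid = "SER", elety = "CA",
                     xyz = matrix(c(1.5, -2.25, 3.125), ncol = 3))
  m <- read_structure(f)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$x, m$y, m$z), c(1.5, -2.25, 3.125))
  expect_equal(m$residue_type, "S")
  # structure residue 7 with offset +6 lands at pipeline residue 13
  m6 <- read_structure(f, offset = 6)
  expect_equal(m6$residue_index, 13L)
})

test_that("an isolated atom's SASA is the closed-form sphere area", {
  f <- write_toy_pdb(resno = 1L, resid = "ALA", elety = "CB",
                     xyz = matrix(c(0, 0, 0), ncol = 3))
  m <- read_structure(f)
  res <- sasa(m, probe_radius = 0.14, n_points = 960)
  exact <- 4 * pi * (1.70 + 1.40)^2 / 100 # nm^2
  expect_equal(res$sasa_nm2, exact, tolerance = 1e-12) # every point accessible
  expect_equal(res$sasa_nm2, 1.2076, tolerance = 1e-3)
})

test_that("far-apart atoms are additive and a caged atom is fully buried", {
  f <- write_toy_pdb(resno = 1:2, resid = rep("ALA", 2), elety = rep("CB", 2),
                     xyz = rbind(c(0, 0, 0), c(50, 0, 0)))
  m <- read_structure(f)
  res <- sasa(m)
  expect_equal(sum(res$sasa_nm2), 2 * 4 * pi * 3.1^2 / 100, tolerance = 1e-12)

  # icosahedral cage of carbons at 1 A traps every sample point of the center
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    expand.grid(x = 0, y = c(-1, 1), z = c(-phi, phi)),
    expand.grid(x = c(-1, 1), y = c(-phi, phi), z = 0),
    expand.grid(x = c(-phi, phi), y = 0, z = c(-1, 1))
  )
  ico <- as.matrix(ico)[, c("x", "y", "z")] / sqrt(1 + phi^2)
  coords <- rbind(c(0, 0, 0), ico)
  f2 <- write_toy_pdb(resno = c(1L, rep(2L, 12)), resid = rep("ALA", 13),
                      elety = c("CB", rep("CB", 12)), xyz = coords)
  m2 <- read_structure(f2)
  res2 <- sasa(m2)
  expect_equal(res2$sasa_nm2[res2$residue_index == 1], 0)
})

test_that("SASA is invariant under rigid motion to sampling tolerance", {
  # small fixture, so refine the angular sampling to keep the error angular,
  # not fixture-limited
  m <- dipeptide_structure()
  base <- sum(sasa(m, n_points = 3840)$sasa_nm2)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
  m2 <- m
  m2$x <- xyz[, 1] + 11.3
  m2$y <- xyz[, 2] - 4.2
  m2$z <- xyz[, 3] + 0.9
  rot <- sum(sasa(m2, n_points = 3840)$sasa_nm2)
  expect_lt(abs(rot - base) / base, 0.005)
})

test_that("SASA converges as the sphere sampling is refined", {
  m <- dipeptide_structure()
  s1 <- sum(sasa(m, n_points = 240)$sasa_nm2)
  s2 <- sum(sasa(m, n_points = 960)$sasa_nm2)
  s3 <- sum(sasa(m, n_points = 3840)$sasa_nm2)
  expect_lt(abs(s3 - s2), abs(s2 - s1) + 1e-9)
  expect_lt(abs(s3 - s2) / s3, 0.005)
})

test_that("unknown elements warn and fall back to the default radius", {
  f <- write_toy_pdb(resno = 1L, resid = "UNK", elety = "XX",
                     xyz = matrix(c(0, 0, 0), ncol = 3), elesy = "XX")
  m <- read_structure(f)
  expect_warning(res <- sasa(m), "default")
  expect_equal(res$sasa_nm2, 4 * pi * 3.1^2 / 100, tolerance = 1e-12)
})

test_that("minimum inter-residue distances behave like distances", {
  f <- write_toy_pdb(resno = c(1L, 2L), resid = rep("ALA", 2),
                     elety = rep("CB", 2), xyz = rbind(c(0, 0, 0), c(3, 0, 0)))
  m <- read_structure(f)
  expect_equal(residue_min_distance(m, 1, 2, "all_heavy"), 3)
  expect_equal(residue_min_distance(m, 1, 1, "all_heavy"), 0)
  expect_error(residue_min_distance(m, 1, 9, "all_heavy"), "residue 9")

  # symmetry and triangle inequality over CA triples
  set.seed(3)
  coords <- matrix(runif(30, 0, 20), ncol = 3)
  mc <- read_structure(ca_cloud_pdb(coords))
  for (i in 1:10) {
    tri <- sample(1:10, 3)
    dab <- residue_min_distance(mc, tri[1], tri[2], "CA")
    dba <- residue_min_distance(mc, tri[2], tri[1], "CA")
    dac <- residue_min_distance(mc, tri[1], tri[3], "CA")
    dcb <- residue_min_distance(mc, tri[3], tri[2], "CA")
    expect_equal(dab, dba)
    expect_gte(dac + dcb, dab - 1e-9)
  }
})

test_that("glycine falls back to the alpha carbon under side-chain selection", {
  f <- write_toy_pdb(resno = c(1L, 1L, 1L, 2L, 2L),
                     resid = c("GLY", "GLY", "GLY", "ALA", "ALA"),
                     elety = c("N", "CA", "C", "CA", "CB"),
                     xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.5, 1, 0),
                                 c(6.5, 0, 0), c(5.5, 0, 0)))
  m <- read_structure(f)
  # GLY side chain -> CA at (1.5,0,0); ALA side chain CB at (5.5,0,0)
  expect_equal(residue_min_distance(m, 1, 2, "side_chain_heavy"), 4)
})

test_that("single-linkage clusters match trivial cases and merge monotonically", {
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(30, 0, 0))
  m <- read_structure(ca_cloud_pdb(coords))
  cl <- spatial_clusters(m, 1:3, cutoff = 6, selection = "CA")
  expect_equal(attr(cl, "n_clusters"), 2L)
  expect_equal(cl$cluster[cl$residue_index %in% c(1, 2)], c(1L, 1L))
  expect_equal(cl$cluster[cl$residue_index == 3], 2L)
  # everyone isolated beyond the cutoff
  far <- read_structure(ca_cloud_pdb(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0))))
  expect_equal(attr(spatial_clusters(far, 1:3, 6, "CA"), "n_clusters"), 3L)
  # lowering the cutoff never merges clusters
  set.seed(19)
  mr <- read_structure(ca_cloud_pdb(matrix(runif(45, 0, 25), ncol = 3)))
  prev <- NULL
  for (h in c(12, 9, 6, 3)) {
    cl_h <- spatial_clusters(mr, 1:15, h, "CA")
    if (!is.null(prev)) {
      # each new cluster must sit inside one previous cluster
      for (g in unique(cl_h$cluster)) {
        members <- cl_h$residue_index[cl_h$cluster == g]
        expect_equal(length(unique(prev$cluster[match(members, prev$residue_index)])),
                     1L)
      }
      expect_gte(attr(cl_h, "n_clusters"), attr(prev, "n_clusters"))
    }
    prev <- cl_h
  }
})

test_that("clusters equal a connected-components oracle on random toys", {
  set.seed(47)
  for (i in 1:50) {
    n <- 20
    coords <- matrix(runif(3 * n, 0, 30), ncol = 3)
    m <- read_structure(ca_cloud_pdb(coords))
    cutoff <- runif(1, 4, 12)
    cl <- spatial_clusters(m, 1:n, cutoff, "CA")
    adj <- as.matrix(dist(coords)) <= cutoff
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    oracle <- igraph::components(g)$membership
    got <- cl$cluster[match(1:n, cl$residue_index)]
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(oracle)))
    for (g1 in unique(oracle)) {
      expect_equal(length(unique(got[oracle == g1])), 1L)
    }
  }
})

test_that("B-factor export round-trips the metric with a sentinel", {
  m <- dipeptide_structure()
  metric <- tibble::tibble(residue_index = 1L, value = 0.37)
  f <- tempfile(fileext = ".pdb")
  export_bfactor_map(m, metric, f)
  back <- read_structure(f)
  expect_equal(unique(back$b[back$residue_index == 1]), 0.37)
  expect_equal(unique(back$b[back$residue_index == 2]), -1) # unassigned sentinel
  # all-zero metric writes 0.00 everywhere
  f2 <- tempfile(fileext = ".pdb")
  export_bfactor_map(m, tibble::tibble(residue_index = 1:2, value = 0), f2)
  expect_true(all(read_structure(f2)$b == 0))
})
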