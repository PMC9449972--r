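# small in-code fixtures shared across test files

# a tiny complete series: `n_res` residues x `temps`, deterministic positions
toy_series <- function(n_res = 3, temps = c(295, 297, 299, 301)) {
  recs <- expand.grid(residue_index = seq_len(n_res), temperature = temps)
  recs <- tibble::tibble(
    residue_index = as.integer(recs$residue_index),
    residue_type = LETTERS[recs$residue_index],
    temperature = recs$temperature,
    delta_h = 8 + 0.1 * recs$residue_index + 0.001 * (recs$temperature - 295),
    delta_n = 115 + recs$residue_index + 0.01 * (recs$temperature - 295),
    intensity = 1e6 + 1e4 * recs$residue_index
  )
  assemble_series(recs)
}

# write a minimal PDB from per-atom vectors; returns the path
write_toy_pdb <- function(resno, resid, elety, xyz, file = tempfile(fileext = ".pdb"),
                          chain = "A", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)), resno = resno,
                   resid = resid, elety = elety, chain = rep(chain, length(resno)),
                   elesy = elesy, o = rep(1, length(resno)),
                   b = rep(0, length(resno)))
  file
}

# point-cloud "protein": one CA atom per residue at given coordinates
ca_cloud_pdb <- function(coords, file = tempfile(fileext = ".pdb")) {
  n <- nrow(coords)
  write_toy_pdb(resno = seq_len(n), resid = rep("ALA", n),
                elety = rep("CA", n), xyz = coords, file = file)
}

# a rigid two-residue fragment with side chains, for SASA/distance tests
dipeptide_structure <- function() {
  atoms <- rbind(
    c(1, "ALA", "N",  0.0, 0.0, 0.0),
    c(1, "ALA", "CA", 1.46, 0.0, 0.0),
    c(1, "ALA", "C",  2.2, 1.3, 0.0),
    c(1, "ALA", "O",  1.6, 2.35, 0.0),
    c(1, "ALA", "CB", 2.2, -1.2, 0.6),
    c(2, "SER", "N",  3.5, 1.3, 0.2),
    c(2, "SER", "CA", 4.4, 2.4, 0.4),
    c(2, "SER", "C",  5.8, 1.9, 0.7),
    c(2, "SER", "O",  6.1, 0.7, 0.6),
    c(2, "SER", "CB", 4.4, 3.4, -0.8),
    c(2, "SER", "OG", 3.2, 4.1, -0.9)
  )
  f <- write_toy_pdb(resno = as.integer(atoms[, 1]), resid = atoms[, 2],
                     elety = atoms[, 3],
                     xyz = matrix(as.numeric(atoms[, 4:6]), ncol = 3))
  read_structure(f)
}

# brute-force point-to-chord linearity score, independent of the implementation
oracle_linearity <- function(x, y) {
  n <- length(x)
  a <- c(x[1], y[1]); b <- c(x[n], y[n])
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path == 0) return(0)
  d <- vapply(2:(n - 1), function(i) {
    p <- c(x[i], y[i])
    ab <- b - a
    if (sum(ab^2) == 0) return(sqrt(sum((p - a)^2)))
    # distance from p to the infinite line through a and b
    t <- sum((p - a) * ab) / sum(ab^2)
    sqrt(sum((p - (a + t * ab))^2))
  }, 0)
  sqrt(mean(d^2)) / path
}
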