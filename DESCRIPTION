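Package: shiftmelt
Title: Residue-Level Analysis of Thermal-Series 1H-15N HSQC Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking per-residue chemical-shift perturbation and
    peak-intensity changes across a thermal series of assigned 1H-15N HSQC
    peak lists. Computes per-step and cumulative combined chemical-shift
    distances, trajectory-linearity classification, quadratic peak-intensity
    trends and percentage changes, normal-distribution percentile flagging of
    outlier residues, residue-residue Spearman cross-correlation matrices
    with noise gating, and structure-based follow-up (Shrake-Rupley
    solvent-accessible surface area, minimum inter-residue distances,
    single-linkage spatial clustering, B-factor metric export). Includes a
    seeded synthetic peak-list generator with ground-truth labels so the
    whole pipeline is testable without experimental spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
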