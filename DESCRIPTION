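Package: spinmatch
Title: Field-Independent Simulation and Similarity Scoring of 1D 1H NMR
    Metabolite Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 1D proton NMR spectra of metabolites from
    spin-system matrices (chemical shifts plus scalar J-couplings) by
    diagonalization of the spin-1/2 Hamiltonian, including strong-coupling
    (second-order) multiplet effects, and renders annotated peak lists as
    sums of Lorentzian lines on arbitrary spectral grids. Simulated
    spectra are compared against experimental-like spectra with
    region-of-interest cosine-similarity scoring, and an automatic
    remediation pipeline adjusts solvent regions, global alignment
    offsets, and line widths to reach a similarity threshold. Metabolite
    annotation data (peaks, multiplets, couplings, samples, metadata) are
    stored one-file-per-metabolite in a documented STAR-syntax exchange
    dialect with InChI-based deduplication, and a synthetic-data module
    generates complete fixture entries and experimental-like spectra so
    the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
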