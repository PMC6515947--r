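Package: pepzone
Title: Epitope Mapping of Beta-2 Glycoprotein I on Overlapping-Peptide Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linear B-cell epitope mapping of beta-2 glycoprotein I
    (B2GP1) with overlapping-peptide (pepscan) arrays. Reconstructs the mature
    326-residue antigen from a printed peptide table, generates 15-mer tilings
    stepped by 4 residues, quantifies 16-bit array images by fixed-circle
    integrated optical density with a background-plus-2SD positivity threshold,
    derives per-peptide antigenicity profiles and contiguous high-antigenicity
    zones, performs ELISA calibration, percentile cutoffs, positivity calls and
    two-regime correlation analysis, and localizes epitope zones on the two
    faces (L and J) of the open fish-hook 3D structure via a fitted reference
    plane. Includes seed-deterministic synthetic-data generators for serum
    reactivity, ELISA mixtures, array slides and structures so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    bio3d,
    png,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
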