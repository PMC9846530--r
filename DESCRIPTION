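Package: nmrcsp
Title: Chemical Shift Perturbation Analysis for Solid-State NMR of
    Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue chemical shift perturbation (CSP) analysis for
    protein backbone NMR, developed around solid-state NMR studies of the
    histone H3 core domain in nucleosome arrays. Reads and writes assigned
    backbone chemical shifts (NMR-STAR v3 and TSV), computes weighted
    combined chemical shift differences between experimental conditions,
    derives data-driven significance thresholds from trimmed subsets,
    accounts for assignment completeness over a residue range, normalizes
    per-residue peak-intensity profiles, projects per-residue values onto
    PDB coordinates via the B-factor column, and generates synthetic
    condition sets of shift tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    seqinr,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
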