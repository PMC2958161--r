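Package: sopescan
Title: Detection of Sensory Organ Precursor Enhancers and Classification
    of Arthropod Achaete-Scute Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans arthropod transcript UTRs for heterotypic clusters of the
    four sensory organ precursor enhancer (SOPE) binding-site classes (E,
    alpha, beta and N boxes), calls candidate enhancers and localizes them
    relative to the open reading frame, classifies achaete-scute family
    proteins into proneural (ASH) versus precursor-specific (ase-like)
    classes from two diagnostic motifs (the 16-residue C-terminal ASH
    domain and the five-residue Ase motif), summarizes aligned box
    instances as frequency matrices, information-content logo tracks and
    IUPAC consensus strings with a permutation test for flank
    conservation, and provides a seeded synthetic-data generator with
    planted ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
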