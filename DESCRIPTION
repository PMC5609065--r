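Package: exbtools
Title: Error-Correcting Exponentially-Expanded Molecular Barcodes for
    Single-Molecule Counting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and decoding of exponentially-expanded molecular
    barcodes (EXBs) for RNA-Seq single-molecule counting. Builds the 64
    error-correcting 6-bp barcode subunits of a [6,3,4] linear code over
    GF(4), decodes inline paired-end barcodes from sequencing reads by
    syndrome (coset-leader) decoding, groups reads into single-molecule
    read groups, calls majority consensus sequences, characterizes
    random-mer (UMI) barcode errors within read groups, fits Poisson
    models of PCR and sequencing barcode errors, and simulates
    tagmentation libraries with branching PCR amplification and per-base
    substitution errors for end-to-end validation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
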