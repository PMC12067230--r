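Package: nucleateR
Title: Nucleation Scores from Deep Mutational Scanning Selection Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of amyloid-nucleation selection experiments read out by
    deep sequencing. Enumerates designed substitution/truncation libraries and
    degenerate-codon (NNK) random-extension libraries, processes amplicon reads
    into variant count tables, estimates per-variant nucleation scores as
    input/output log-ratios with delta-method errors and error-weighted
    replicate merging, classifies variants by Z-test with Benjamini-Hochberg
    false discovery rate control, and compares the sequence composition of
    nucleating and non-nucleating peptides. Includes a synthetic
    selection-experiment generator for power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
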