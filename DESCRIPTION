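Package: aptaquad
Title: Quadruplex and i-Motif Propensity Analysis for Aptamer Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Run-length based scoring of G-quadruplex (G4) and i-motif
    propensity in DNA and RNA aptamer sequences. Implements per-base
    guanine/cytosine run scores, whole-sequence and sliding-window means,
    merged potential-quadruplex-sequence (PQS) region calls at configurable
    thresholds, composition-preserving shuffle null models, random-library
    baselines with two-proportion z-tests, and a SELEX-like synthetic library
    generator with ground-truth labels for benchmarking. Reads and writes
    FASTA, tabular catalogs, and BED-like region output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
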