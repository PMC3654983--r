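Package: prdscan
Title: Prediction of Q/N-Rich Prion-Forming Domains in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic detection of glutamine/asparagine-rich prion-forming
    domains (PrDs) in protein sequences. Amino-acid log2-odds propensities
    (statistical potentials in bits) are estimated from a training set of
    prion proteins against a background composition, combined with a
    correction for the spacing pattern of proline pairs, and applied with a
    60-residue sliding window calibrated at a 50-bit predictive cutoff.
    Includes readers for FASTA and SwissProt flat files, per-taxon and
    tabular prediction writers, a full classifier benchmarking stack (ROC
    with trapezoid AUC, precision-recall, accuracy against cutoff, rank-sum
    test, half-exclusion bootstrap with averaged ROC curves, randomization
    z-scores for category enrichment), synthetic sequence generators with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
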