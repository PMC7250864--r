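Package: riboTails
Title: Ribosome Profiling Translation Efficiency and RNA 3'-Tail Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two linked analyses of translational control. The
    ribosome-profiling half filters ribosome-protected fragments, infers
    A sites at a fixed offset, computes codon occupancy with basal
    normalization, builds binned metagene profiles over coding regions,
    and calls differential translation efficiency between conditions,
    with Fisher's exact enrichment of signal-peptide/transmembrane
    annotations and codon-usage comparisons downstream. The cRACE half
    reconstructs exact RNA 3' termini from circularization-RACE reads,
    separates templated from non-templated tail nucleotides, calls
    oligo(U) tails, and fits a logistic model of uridylation probability
    against 3' truncation. Synthetic-data generators with per-read truth
    tables support parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
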