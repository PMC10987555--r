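Package: repliquant
Title: Quantification of Replication Origin Firing and Fork Dynamics from
    EdU-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify DNA replication origin firing and replication
    fork progression from nascent-strand (EdU-seq) sequencing tracks binned on
    the genome. Normalizes EdU read counts against a genomic-DNA control,
    expresses per-bin enrichment as sigma values (normalized counts divided by
    the background standard deviation), calls origin peaks, quantifies and
    classifies per-origin firing efficiency under normal versus elevated
    Cyclin E expression (constitutive, intermediate, oncogene-induced),
    computes adjusted-sigma metagene profiles around origins across
    hydroxyurea-release timepoints to estimate fork progression rates, scores
    mitotic DNA synthesis (MiDAS) by EdU-foci positivity and region-set signal
    profiling, and analyses DNA-fiber (combing) track lengths with two-way
    ANOVA, Fisher's LSD and Tukey comparisons. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
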