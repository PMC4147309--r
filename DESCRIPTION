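Package: smallRNAcascade
Title: Sequential Annotation and Differential Expression of Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for profiling small noncoding RNAs from two-library
    (condition versus control) deep-sequencing experiments without replicates.
    Implements 3'-adapter trimming, spike-in removal, read collapsing with
    singleton and length filters, a sequential miRNA annotation cascade
    (mature, then mature-star, then hairpin, with unique and ambiguous match
    accounting and removal between stages), length-routed piRNA and
    repeat-associated RNA branches with strand-specific mismatch-tolerant
    mapping, median-of-ratios count normalization, a posterior generalized
    fold change for no-replicate designs, Bland-Altman summaries, and
    RepeatMasker family/class aggregation with sense/antisense ratios.
    Includes a seeded synthetic-data generator that emulates a two-library
    small RNA experiment with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, Normalization, DifferentialExpression
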