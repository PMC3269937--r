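Package: gnbench
Title: Scoring and Consensus Machinery for Gene Normalization Benchmarks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for scoring ranked, confidence-scored submissions to
    gene normalization benchmarks. Implements the Threshold Average
    Precision metric (TAP-k) with median-false-positive threshold
    selection; a latent-class EM algorithm in the Dawid-Skene/Hui-Walter
    family that infers per-source sensitivity and specificity together
    with consensus ("silver standard") labels from multiple submissions
    without a gold standard; entropy-based selection of maximally
    discriminative evaluation documents; a feature-stratified composite
    classifier with modified Huber loss that combines submissions; paired
    run comparison statistics; and a seeded synthetic-corpus generator
    whose observation model mirrors the EM likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'labelMatrix.R'
    'fixtures.R'
    'tap.R'
    'em.R'
    'selection.R'
    'ensemble.R'
    'evalStats.R'
    'synthetic.R'
    'cli.R'
    'gnbench-package.R'
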