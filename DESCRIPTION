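Package: clockscreen
Title: Multi-Omics Evidence Scoring and Phase Modelling for Circadian Clock
    Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates ChIP-seq, proteomics and protein-protein interaction
    evidence into per-gene candidate scores for circadian clock gene
    discovery. Provides weighted binary evidence scoring over a registry of
    evidence datasets, an empirical permutation null (with an exact
    convolution oracle) for score significance, a weight-robustness screen
    over a constrained simplex of class pre-factors, a von Mises circular
    regression of transcript peak phase on transcription-factor-group binding
    scores with an arctan link, hypergeometric over-representation tests, and
    a synthetic-data generator with planted ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
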