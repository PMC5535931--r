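Package: apmsq
Title: Semi-Quantitative Analysis of Affinity-Purification Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral-count based analysis of affinity-purification mass
    spectrometry (AP-MS) experiments with isotype (IgG) controls, built
    around the design used to map the EZH2 interactome in acute myeloid
    leukaemia cells. Provides fold-change quantitation over pooled controls
    with a count floor, one-sided Fisher exact enrichment tests with
    Benjamini-Hochberg correction, a Poisson-mixture confidence score for
    bait-prey interactions, contaminant-frequency filtering, a staged
    differential-interactome cascade across a treatment condition,
    methylated-residue calling with per-condition occupancy, triangulation
    of candidate direct methyltransferase substrates, Markov clustering of
    interaction networks with hypergeometric term enrichment, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
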