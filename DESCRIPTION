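Package: laminatools
Title: Nuclear Lamina Organization: DamID LAD Calling, Envelope
    Heterogeneity Imaging, and Microneedle Nuclear Stiffness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tested re-implementation of three quantitative procedures for
    studying nuclear-lamina organization in Drosophila muscle: (1) the
    muscle DamID-seq pipeline, from adaptor-anchored read preprocessing and
    GATC-fragment counting through replicate-averaged log2(Dam-Lam/Dam)
    score tracks, two-state Student-t hidden Markov model segmentation into
    lamina-associated domains (LADs), differential cLAD/fLAD/fiLAD
    classification between genotypes, gene-model feature annotation, and
    chromosome-region contact statistics; (2) the Distribution Index
    (D.I. = SD/mean of fluorescence intensity within an eroded nuclear
    ROI), including faithful re-implementations of the published ImageJ
    macro steps (8-bit conversion, Huang and Mean auto-thresholds, disc
    median filter, count-based binary erosion/dilation, particle analysis);
    and (3) microneedle force-deformation nuclear-stiffness estimation by
    plateau extraction and linear regression with subtraction of the
    non-nuclear contribution. Seeded synthetic-data generators emulate
    every input so the full pipelines are exercisable at desk scale with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    png
Config/testthat/edition: 3
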