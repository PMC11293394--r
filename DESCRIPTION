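Package: nfkbcodep
Title: Codependence Analysis of NF-kB p50 and IkBzeta Regulatory Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying genes codependent on the
    NF-kB p50 subunit (Nfkb1) and the nuclear IkB protein IkBzeta (Nfkbiz)
    from genotype-contrast nascent RNA time courses and multi-factor ChIP-seq
    kinetics in stimulated macrophages. Provides knockout-versus-wild-type
    dependence classification with a negative-binomial exact contrast test,
    reproducible-peak filtering and peak-set union, six-cluster kinetic
    k-means, p50:RelA binding-preference scoring with equal-size binning,
    genotype dependence of cofactor binding with banded classification and
    gene-class enrichment, kappaB homodimer motif scanning with PWM
    enrichment, and lipid A versus TNF stimulus-differential classification.
    A seeded synthetic-data generator with planted ground truth supports
    end-to-end validation of every classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
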