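Package: ssdripr
Title: Strand-Aware R-Loop Calling and Annotation for ssDRIP-Seq
Version: 0.1.0
Authors@R: person("Retina", "Genomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-strand DNA:RNA immunoprecipitation
    sequencing (ssDRIP-seq). Calls R-loops against RNase-H-treated controls
    with a local-lambda Poisson window test and Benjamini-Hochberg q-values,
    builds replicate consensus sets, classifies R-loops as stranded or
    unstranded using the opposite strand as control, annotates calls against
    genomic features with observed/expected enrichment, computes metaprofiles
    of external signal tracks centered on R-loop classes, runs replicate PCA
    quality control, and tests protein-set overlap with the Fisher exact test.
    Includes a seeded synthetic-cohort generator with planted ground-truth
    R-loops for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
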