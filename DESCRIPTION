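Package: smMRD
Title: Error-Corrected smMIPS Sequencing Analysis of Measurable Residual
    Disease in AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-molecule molecular inversion probe (smMIPS) sequencing
    with unique molecular identifiers (UMIs) permits tracking of patient-
    specific mutations in acute myeloid leukemia at variant allele fractions
    far below the error floor of conventional NGS. smMRD implements the
    complete computational workflow: a synthetic-read generator emulating
    UMI-tagged smMIPS capture, UMI family grouping with singleton discard and
    quorum consensus calling, a site- and mutation-specific binomial
    background error model fitted on control samples, a tracked-mutation MRD
    caller with clonal-hematopoiesis (DNMT3A/TET2/ASXL1) gene policy and
    time-point kinetics, an ultrasensitive FLT3 internal tandem duplication
    detector for deep single-amplicon reads, dual-modality concordance and
    predictive-value metrics, and a seeded limit-of-detection experiment
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
biocViews: Sequencing, VariantDetection, TargetedResequencing, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
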