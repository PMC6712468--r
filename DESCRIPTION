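Package: pjflow
Title: Somatic Variant and Copy-Number Analysis of Pancreatic Juice Cell-Free DNA Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-usable pipeline for exome sequencing of pancreatic
    juice cell-free DNA (PJD) from intraductal papillary mucinous neoplasm
    (IPMN) patients. Implements paired tumor/normal Fisher-exact somatic
    SNV/indel calling with read-level quality filters, three-evidence
    8-oxoguanine (OxoG) artifact sample QC based on trinucleotide mutation
    spectra, tumor-fraction estimation from variant allele frequencies,
    copy-ratio binning and circular binary segmentation with undo-splits,
    off-target segment filtering and residual-variance sample QC, GISTIC-style
    recurrent copy-number region scoring with a permutation null, and the
    grade-association statistics (Spearman burden-grade correlation, exact
    2xK contingency tests, co-occurrence tables). A seeded synthetic-cohort
    generator emulates grade-labelled paired pileups, truth mutations,
    copy-number profiles, purity, and artifact pathologies so every stage is
    testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
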