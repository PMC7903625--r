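Package: varbench
Title: Benchmarking of Germline Small-Variant Calling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for the analytical validation of germline
    small-variant calling assays. Classifies query variant calls against a
    truth set as true positive, false positive or false negative within
    stratified regions of interest using haplotype-equivalence matching that
    is robust to differences in allelic representation (adjacent SNP/MNP
    splits, InDel shifts, allele padding). Computes precision, recall, true
    negatives and negative percent agreement (NPA) from region base counts,
    stratifies InDel metrics by size bin with user-controlled bin merging,
    verifies the presence of named clinically relevant variants, and emits a
    consolidated multi-sample validation report. Ships a deterministic
    synthetic-fixture generator (toy references, truth/query VCF pairs with
    planted classifications, confidence and region-of-interest BED files,
    assertion tables) used as the test bed for the whole workflow.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    vcfR,
    methods,
    tools,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
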