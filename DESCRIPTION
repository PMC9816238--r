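Package: snvdrift
Title: Storage-Induced Artificial SNVs and Time-Since-Deposition Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of artificial single-nucleotide variants that arise in
    stored biological traces through hydrolytic DNA damage. From per-site,
    per-sample variant read counts (multi-sample VCF or a counts table) the
    package computes the percentage of reads of the variant allele (PRV),
    allocates genotypes with a configurable read-count band caller, classifies
    per-site temporal trajectories across storage time points (genotype
    transitions, failed-call onset, homozygote switches, gradual PRV drift),
    characterises the base-change spectrum (deamination-type transitions,
    transversions, spanning deletions), and applies stepwise filters to
    nominate candidate markers for estimating the time since deposition of a
    trace. A forward simulator of time-dependent cytosine/guanine deamination,
    coverage decay and sequencing error generates read-count data with planted
    ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
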