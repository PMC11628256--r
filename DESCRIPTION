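Package: editscape
Title: Genome-Wide Evaluation of CRISPR/Cas9 Editing Outcomes in F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing on- and off-target CRISPR/Cas9 editing
    outcomes in heterozygous F1 plant material by whole-genome and amplicon
    sequencing. Builds a synthetic F1 genome assembly by binning
    haplotype-specific SNP markers with a sliding-window congruence rule,
    detecting recombination breakpoints, and stitching parental assembly
    intervals with an AGP segment map and coordinate liftover. Applies
    hard filters (QD, MQ, DP, AD) and control subtraction to variant calls,
    enumerates candidate Cas9 off-target sites under canonical and
    non-canonical PAMs with mismatch tolerance, and triages in-site variants
    against cross-sample support. Classifies on-target amplicon outcomes
    (net indel spectra, zygosity, mosaicism, transgenerational editing) and
    infers repair pathways (MMEJ, cNHEJ, SDSA-like) from junction
    microhomology. A truth-tracked synthetic-data generator emulates the
    full input regime so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
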