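Package: cnvtrio
Title: Trio-Based Copy Number Variant Target Discovery with
    Multi-Platform Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery pipeline for rare, recurrent copy number variants
    (CNVs) in affected family trios. Classifies proband calls as de novo
    versus inherited by reciprocal-overlap matching against genotyped
    relatives, removes calls seen in independent family controls, matches
    survivors against whole-exome, SNP-array and whole-genome replication
    cohorts with control veto, merges supported calls into recurrent
    regions, annotates regions against knowledge bases (known
    disease-associated loci, common-variant catalogues, embryonic-heart
    expressed gene lists), tests case/control carrier asymmetry with a
    permutation test backed by an exact hypergeometric oracle, and
    contrasts carrier versus non-carrier gene expression (FPKM) after
    housekeeping-gene normalization. Includes a synthetic multi-platform
    cohort generator with known ground truth so every stage is testable
    without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    IRanges
Config/testthat/edition: 3
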