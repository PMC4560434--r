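Package: isodiverge
Title: Cis and Trans Regulatory Divergence of Transcript Isoform Usage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the regulatory divergence of transcript isoform usage
    between two inbred strains and their F1 hybrids. Genes expressing exactly
    two overlapping isoforms are selected through an expression and
    heterozygosity funnel, each gene's strain-level and allele-level isoform
    log-odds differences are summarised, and a Bayesian comparison of four
    models (conserved, cis, trans, cis-and-trans) assigns a regulatory class.
    Structural differences between the two isoforms are classified into
    alternative first exon, transcription start site, internal splicing,
    alternative last exon and alternative polyadenylation categories, and
    cross-tabulation statistics (Fisher and chi-squared enrichment with FDR
    control) relate structural categories to regulatory classes. A synthetic
    data generator with known ground truth, including an in-silico F1
    construction, makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
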