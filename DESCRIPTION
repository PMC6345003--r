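Package: bshprof
Title: Profiling of the Bile Salt Hydrolase Gene Family in Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("BSH", "Profiling Team", email = "bshprof@example.org",
           role = c("aut", "cre"))
Description: Tools for census and abundance profiling of a bacterial protein
    family (bile salt hydrolase, EC 3.5.1.24) across strain proteomes and
    per-individual gut metagenomes. Implements identity-threshold homology
    screening against a curated reference, a per-strain paralog census,
    construction of a non-redundant gene catalog, length-normalized relative
    abundance, phylogeny-based phylotype reclassification with an
    unclassifiable outlier group, and the cohort association statistics
    (Mann-Whitney with false discovery rate control, Spearman phenotype
    correlation, chi-squared presence tests, and multivariable-adjusted
    linear models with per-factor variance explained). A synthetic-data
    module generates strain proteomes, metagenome read sets, cohort metadata
    and phenotype tables with planted truth so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
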