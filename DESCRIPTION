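Package: svatlas
Title: Post-Calling Analysis of Genotyped Structural Variants in Population Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and population-genetic analysis of genotyped
    structural variants (SVs) from short-read cohorts. Implements a five-step
    post-calling filter cascade with depth fold-change (DHFFC) genotype
    masking, SnpEff-style consequence annotation against gene models,
    reciprocal-overlap interval arithmetic for repeat and constrained-element
    joins, per-site Weir-Cockerham F_ST with a farmed-versus-wild
    domestication candidate scan, Fisher/hypergeometric enrichment statistics
    with Benjamini-Hochberg correction, and a truth-labelled multi-population
    cohort simulator based on the Balding-Nichols model for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3),
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    vcfR,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'domestication.R'
    'enrichment.R'
    'filtering.R'
    'intervals.R'
    'io.R'
    'pipeline.R'
    'popgen.R'
    'simulate.R'
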