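Package: scClonality
Title: Clonal Evolution, Metastatic Seeding and Mutational Signatures from
    Single-Cell Exome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clonality analysis of single-cell whole-exome data from
    paired primary tumors and metastases. Provides allele-dropout (ADO) and
    false-positive rate estimation from control sites, a Bayesian diploid
    genotyper that accounts for ADO, a missing-data-tolerant cell-pair
    similarity statistic with tissue heterogeneity indices, origin tracing of
    metastatic cells, hierarchical clustering and PCA of mutation landscapes,
    96-class mutational-signature extraction by non-negative matrix
    factorization with stability-based selection of the number of signatures,
    pigeonhole subclonal phylogenies from cancer-cell-fraction clusters with
    monoclonal/polyclonal seeding calls, single-cell transcriptome scores
    (cluster projection, metastatic-contribution, EMT module and quadratic CNV
    scores), exact contingency-table tests, and a fully specified synthetic
    data generator so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, ape, cluster, mclust
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohortStats.R'
    'genotyper.R'
    'heterogeneity.R'
    'noiseRates.R'
    'pigeonhole.R'
    'pipeline.R'
    'scrnaScores.R'
    'signatures.R'
    'simdata.R'
    'utils.R'
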