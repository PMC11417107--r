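# scClonality

Clonal evolution, metastatic seeding and mutational signatures from
single-cell exome data.

## What it is for

When a solid tumor seeds a metastasis, the founding population may be a
single circulating tumor cell (monoclonal seeding) or a multicellular
cluster carrying several subclones (polyclonal seeding). scClonality is an R
package for analysts of paired primary/metastasis single-cell whole-exome
cohorts who want to make that call and quantify the evidence behind it. It
covers the full chain from amplification noise to biology:

* **Noise estimation** — per-cell allele-dropout (ADO) and false-positive
  rates from germline control sites (`estimateADORate`, `estimateFPRate`).
* **Genotyping** — a Bayesian diploid caller whose heterozygous likelihood
  is a mixture over amplification outcomes,
  `L(RA) = (1−a)·Bin(alt|n,½) + (a/2)·Bin(alt|n,ε) + (a/2)·Bin(ref|n,ε)`,
  with statuses MUT / WT / CND (`genotypePosterior`, `callStatus`,
  `genotypeCase`).
* **Heterogeneity** — the binary cell-pair similarity R (+1 unless some
  site is determinably mutant in one cell and wild type in the other), the
  tissue similarity index (mean R over all pairs, with H = (1 − index)/2),
  origin tracing of metastatic cells by graded concordance, normal-cell
  exclusion, hierarchical clustering and PCA (`pairSimilarity`,
  `tissueHeterogeneity`, `traceOrigin`, `clusterAndEmbed`).
* **Mutational signatures** — 96-class catalogs, multiplicative-update NMF
  with bootstrap per-signature stability and elbow-based selection of the
  number of signatures, cosine matching (`build96Catalog`,
  `extractSignatures`, `matchSignatures`).
* **Subclonal reconstruction** — CCF clustering of paired primary/metastasis
  VAFs, pigeonhole trees (children's CCFs may not exceed the parent's in any
  sample), branch lengths as mutation proportions, and
  monoclonal/polyclonal seeding calls (`clusterCCF`, `buildTree`,
  `classifySeeding`).
* **Transcriptome scores** — centroid projection of metastatic cells onto
  primary clusters, per-cluster metastatic-contribution (MC) scores,
  expression-bin-matched EMT module scores, quadratic CNV scores, and the
  EMT~MC regression (`projectCells`, `mcScore`, `emtModuleScore`,
  `cnvScore`, `regressEmtMc`).
* **Clinical tests** — exact 2×2 and r×c contingency tests with the
  minimum-likelihood two-sided rule (`fisherExact2x2`, `fisherExactRxC`,
  `stageAssociationTests`).

Because raw per-cell exome data of this kind are rarely deposited reusably,
the package ships a synthetic-data generator (`simulateCase` and friends)
that produces fully specified ground truth — clone trees, seeding modes, MDA
noise, read counts, bulk VAFs, expression — against which every stage is
tested.

## A worked example

```r
library(scClonality)

# a polyclonally seeded tumor: 4 primary regions, liver + lymph metastases
case <- simulateCase(seedingMode = "polyclonal", seed = 42)
status <- genotypeCase(case$refCounts, case$altCounts,
                       tissue = case$cellData$tissue,
                       region = case$cellData$region,
                       gene   = case$siteData$gene)
status
#> StatusMatrix: 117 sites x 60 cells
#>   tissues: region1, region2, region3, region4, liver, lymph
#>   status: MUT 2623 | WT 3838 | CND 559

tissueHeterogeneity(status)[, c("tissue", "nPairs", "similarityIndex")]
#>    tissue nPairs similarityIndex
#> 1 region1     45      -0.9555556
#> 2 region2     45      -1.0000000
#> 3 region3     45      -1.0000000
#> 4 region4     45      -0.9555556
#> 5   liver     45      -1.0000000
#> 6   lymph     45      -0.9555556

tr <- traceOrigin(status, "liver",
                  sourceRegions = case$seeding$sourceRegions)
tr$tracedFraction   # share of liver cells traced to the true source regions
#> [1] 1
tr$p                # enrichment vs the primary sampling composition
#> [1] 0.003433374

seedingCallFromCase(case, seed = 42)$call$mode
#> [1] "polyclonal"

# clinical stage table: Fisher exact for the 2x2 stratum,
# Pearson chi-square for the larger strata
stageAssociationTests(clinicalStageTable())
#>   block   test          p
#> 1     T  chisq 0.66791961
#> 2     N  chisq 0.74982276
#> 3     M fisher 0.03144815
#> 4  AJCC  chisq 0.16361265
```

The similarity indices sit near −1 even within one region — with a 10%
allele-dropout rate almost every cell pair conflicts somewhere, which is why
seeding calls rest on lineage counting and the pigeonhole tree rather than
on the index alone (see the methods vignette,
`vignettes/clonality-methods.Rmd`).

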