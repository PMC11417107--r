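---
title: "Models and methods behind scClonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scClonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scClonality)
```

# The problem

When a colorectal tumor seeds a liver or lymph-node metastasis, the founding
population may be a single circulating tumor cell (monoclonal seeding) or a
multicellular cluster carrying several subclones (polyclonal seeding). The
two scenarios leave different genetic footprints: a monoclonal metastasis is
genetically more homogeneous than its source region, while a polyclonal
metastasis preserves much of the source region's heterogeneity and contains
cells from more than one branch of the subclonal tree. scClonality implements
the statistics needed to make this distinction from single-cell whole-exome
data of paired primary/metastasis samples, together with the surrounding
machinery: amplification-noise estimation, ADO-aware genotyping, cell-pair
similarity and tissue heterogeneity, origin tracing, mutational-signature
extraction, pigeonhole subclonal reconstruction, single-cell transcriptome
scores, and exact clinical contingency tests.

Because raw per-cell exome data of this kind are rarely deposited in a
reusable form, the package is organized around a synthetic-data generator
(`simulateCase()`, `simulateExpressionCase()`, `simulateCCFCase()`,
`simulateCatalog()`) that produces fully specified ground truth. Every
downstream claim the package makes is tested against that truth.

# Amplification noise and the genotype model

Multiple displacement amplification of single-cell DNA introduces two
characteristic artifacts:

* **Allele dropout (ADO)**: at a truly heterozygous site, one allele
  (chosen at random) contributes no reads, producing a false homozygous
  call. The generator's default rate is 10.3% — a typical cohort median
  for MDA-amplified exomes.
* **False positives (FP)**: a spurious variant call at a truly
  homozygous-reference site. Default rate 2.68e-6 per site, far below the
  per-read sequencing error (default 0.5%).

Both rates are estimated from control sites (`estimateADORate()`,
`estimateFPRate()`): confident homozygous calls at known germline
heterozygous SNPs count as ADO events; non-reference calls at confident
homozygous-reference sites count as FPs. No-calls are excluded from the
denominators; the cohort summary is the median for ADO and the mean for FP.

`genotypePosterior()` scores the three diploid genotypes at a site from its
reference/alternate read counts. With \(n\) reads, sequencing error
\(\varepsilon\) and dropout rate \(a\):

\[
L(RR) = \mathrm{Bin}(alt \mid n, \varepsilon), \qquad
L(AA) = \mathrm{Bin}(ref \mid n, \varepsilon),
\]
\[
L(RA) = (1-a)\,\mathrm{Bin}(alt \mid n, \tfrac12)
 + \tfrac{a}{2}\,\mathrm{Bin}(alt \mid n, \varepsilon)
 + \tfrac{a}{2}\,\mathrm{Bin}(ref \mid n, \varepsilon).
\]

The heterozygous likelihood is a mixture over the three amplification
outcomes (no dropout, reference kept, alternate kept), with the dropout mass
split evenly between alleles because dropout is a random loss of one allele.
At \(a = 0\) the model reduces term by term to the standard diploid caller.
The prior is flat by default (the data carry no cohort information at a
single site); `callStatus()` turns posteriors into the status vocabulary
MUT / WT / CND, with CND (cannot determine) assigned below `minDepth = 5`
reads or below `minPosterior = 0.95` MAP probability.

One property of this model deserves emphasis: when all reads carry one
allele, the posterior for the homozygote saturates at
\(1/(1 + a/2) \approx 0.95\) for \(a = 0.103\) — the model knows a dropout
could have produced the same data. A dropout event is therefore
*informationally unrecoverable*: no caller can beat an error floor
proportional to the dropout rate at heterozygous sites. For this reason
`genotypeAccuracy()` reports accuracy both over informative amplifications
(its headline number, >99% at depth 20) and over all sites including
dropouts (~96% under default noise), and the package never claims the
latter can approach 1.

# Cell-pair similarity and tissue heterogeneity

The similarity statistic `pairSimilarity()` is deliberately binary: two
cells are the same (R = +1) unless some site is determinably mutant in one
and wild type in the other (R = −1); CND is compatible with everything.
`tissueHeterogeneity()` averages R over all unordered within-tissue pairs
(the similarity index) and reports H, the fraction of discordant pairs, with
index = 1 − 2H exactly. Pairs with no informative overlap count as
concordant by the rule above; a flag excludes them.

Because a binary statistic cannot rank candidate matches, origin tracing
(`traceOrigin()`) uses the graded concordance — the fraction of agreeing
sites among sites determinable in both cells — to assign each metastatic
cell to the region of its most concordant primary cell (at least 5 shared
informative sites; ties broken by more informative sites, then
lexicographic region). Enrichment of assignments in a candidate source
group is tested with the package's own two-sided Fisher exact test against
the primary sampling composition.

Under realistic ADO, almost every cell pair conflicts somewhere, so R-based
indices sit near −1 in tumor tissue and the index alone discriminates
seeding modes poorly. The discriminating single-cell signal is the number
of distinct metastasis lineages: `countMetLineages()` clusters the
metastatic cells on the 1 − concordance distance and cuts the average
linkage dendrogram at 0.15 — chosen between the within-clone disagreement
floor (≈ 2·(a/2)·(1−a/2) times the carried-site fraction, ≈ 0.03–0.06
under defaults) and the between-clone divergence (≥ 0.2). The combined
rule in `heterogeneitySeedingRule()` calls polyclonal seeding when the
metastasis H is within 0.1 of the source region's H and at least two
lineages are present.

# Pigeonhole subclonal reconstruction

`clusterCCF()` converts VAFs to cancer cell fractions assuming diploid,
copy-neutral loci (CCF = min(1, 2·VAF/purity)) and clusters the paired
(primary, metastasis) CCF points. The default clustering is a Gaussian
mixture with spherical per-cluster covariance selected by BIC. We initially
used k-means with silhouette-based selection; on simulated truth it
systematically merged the two seeding lineages of a polyclonal case when
they were ~0.2 CCF apart (noise sd 0.04), a regime mixture models resolve
reliably — mixture modelling is also the convention of subclone callers.
The silhouette variant is retained as `method = "kmeans"`.

`buildTree()` places clusters under the trunk subject to the pigeonhole
constraint: in every sample, the CCFs of a node's children must not exceed
the node's CCF (tolerance 0.1 CCF by default, absorbing estimation noise).
Clusters are inserted in decreasing total CCF and attached to the valid
parent closest to the root, so trees are maximally branched subject to the
constraint; nesting into a chain happens exactly when a sibling sum would
violate it in some sample. Branch lengths are mutation proportions and sum
to 1. `classifySeeding()` then calls the seeding mode: monoclonal when the
metastasis-present clusters (CCF > 0.05) lie on a single root-to-leaf path,
polyclonal when they span incomparable branches.

The generator draws the polyclonal mixing weight from U(0.55, 0.8) rather
than symmetrically around 0.5: real multicellular seeds carry unequal
subclone proportions, and a case in which both branches have identical CCFs
in both samples is unidentifiable from bulk data for any method. Likewise,
each designated source region is guaranteed at least one cell of each
seeding clone — these regions are sampled precisely because they harbor
the seeding lineages.

# Mutational signatures

`build96Catalog()` bins substitutions into the 96 pyrimidine-centric
classes (purine-reference records are reverse-complemented; totals are
conserved). `extractSignatures()` runs multiplicative-update NMF under the
Frobenius objective (the objective is asserted non-increasing every
iteration), with multiple random initializations per rank plus one warm
start from the previous rank — the warm start makes the reconstruction
error provably non-increasing in K. Stability per signature is the mean
silhouette of its cluster after pooling signatures from bootstrap-resampled
catalogs and partitioning them by cosine dissimilarity.

Rank selection uses two conditions, both needed: the minimum per-signature
stability must reach 0.8, and the K-th signature must improve the
reconstruction error by at least 5% over the K−1 solution. The per-signature
minimum matters: at one rank above the truth, the spurious signature's own
stability collapses (typically below 0.65) while the *average* stability can
stay above 0.8 and is therefore a poor discriminator. The error condition
guards against stable-but-redundant splits. The selected K is the largest K
meeting both; if none does, the K of maximum stability is reported.

`matchSignatures()` reports cosine similarities against a reference matrix
and hierarchically co-clusters the combined set. The packaged reference
(`syntheticReferenceSignatures()`) is a synthetic five-signature set:
published reference catalogues are license-bearing data the user supplies
themselves.

# Single-cell transcriptome scores

`projectCells()` assigns metastatic cells to primary clusters by centroid
similarity on the 500 most variable genes: per-gene median centroids, and
assignment when at least two of cosine/Pearson/Spearman agree on the top
centroid with similarity ≥ 0.7. The per-cluster metastatic contribution
(MC) score is the fraction of assigned metastatic cells projecting onto
that cluster (`mcScore()`; scores sum to 1 — unassigned cells are excluded
from the denominator by default).

`emtModuleScore()` implements expression-bin-matched module scoring: 24
equal-frequency bins by cohort-average expression, 100 control genes per
set gene sampled with replacement from the non-set genes of the same bin
(widening to neighboring bins when necessary). Excluding set genes from
the control pool keeps the recovered effect unbiased even in small gene
universes. `cnvScore()` is the quadratic sum of copy-number deviations
from baseline 1. `regressEmtMc()` regresses the per-cluster MC score on
the per-cluster mean EMT score by ordinary least squares; the packaged
synthetic expression case plants the association (high-contribution
clusters carry the EMT elevation and larger CNV deviations), so only its
sign and a planted floor are asserted — external per-patient values are
not reproducible from synthetic data.

# Clinical contingency tests

`fisherExact2x2()` and `fisherExactRxC()` are exact conditional tests with
the minimum-likelihood two-sided rule; the r×c version enumerates every
margin-consistent table and is verified against an independent enumeration
oracle and `stats::fisher.test`. `stageAssociationTests()` reproduces a
clinical stage-by-mutation-status table the way mainstream clinical
software reports it: Fisher's exact test for 2×2 strata and Pearson's
chi-square (no continuity correction) for larger strata. The packaged
107-patient example table's larger strata indeed match chi-square values,
not exact-test values — worth knowing when comparing against published
tables of this kind.

# Simulation design and problem sizes

The default `simulateCase()` emulates the motivating study design: four
primary regions (the first two are the metastasis source regions), liver
and lymph metastases, 6 clones on a uniform random recursive tree, 117
somatic mutations (each clone at least one, the rest multinomial),
coverage negative-binomial with mean 30 and dispersion 3, and the noise
defaults above. Bulk VAFs are clone prevalences halved plus Gaussian noise
(sd 0.02). In the zero-noise limit both alleles amplify evenly
(allele sampling is treated as part of amplification noise), which gives
the exact observed-equals-truth contract used in tests.

The test suite and the acceptance script use these problem sizes: 2,000
het control sites × 50 cells and 1e6 hom sites × 20 cells for rate
recovery; 100 simulated cases per seeding mode for classification
accuracy; 25 catalogs of 50 samples × 500 mutations for signature
recovery; 10–30 replicate simulations for property checks. These sizes
keep every stage's sampling error well inside the asserted margins while
remaining quick to run.

What passing these tests shows — and what it does not: the synthetic
generator plants clean clonal structure, independent per-site noise and
Poisson/negative-binomial sampling. Real MDA data add coverage waves,
chimeric reads, locus-specific dropout and copy-number distortion of VAFs,
none of which are modeled (deliberately: see the non-goals of each
module). Results on real data therefore depend on upstream QC that these
simulations do not exercise.

# Known limitations

* CCF conversion assumes diploid copy-neutral loci; no copy-number-aware
  correction is attempted.
* The pigeonhole tree is reconstructed from two samples only
  (primary + one metastasis).
* The binary R statistic saturates near −1 at realistic ADO; quantitative
  tissue comparisons should use the per-pair concordance distributions
  retained alongside.
* Signature extraction ships no published reference catalogue; matching
  is against user-supplied or synthetic references.
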