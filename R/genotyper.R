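#' @include AllClasses.R
NULL

#' Bayesian diploid genotype posterior under allele dropout
#'
#' Posterior over the three diploid genotypes (hom-ref RR, het RA, hom-alt AA)
#' from per-site reference and alternate read counts, taking both allele
#' dropout and sequencing error into account. With \eqn{n = ref + alt} reads
#' and sequencing error \eqn{\epsilon}:
#' \deqn{L(RR) = Binom(alt \mid n, \epsilon)}
#' \deqn{L(AA) = Binom(ref \mid n, \epsilon)}
#' \deqn{L(RA) = (1 - ado)\,Binom(alt \mid n, 1/2) +
#'   \frac{ado}{2} Binom(alt \mid n, \epsilon) +
#'   \frac{ado}{2} Binom(ref \mid n, \epsilon)}
#' i.e. at a heterozygous site either both alleles amplified, or one allele
#' (chosen with equal probability) dropped out and the reads behave like a
#' homozygote of the remaining allele. The posterior is the prior times the
#' likelihood, normalized. With zero reads the posterior equals the prior.
#'
#' @param refCount,altCount non-negative integer vectors of equal length.
#' @param noise a \linkS4class{NoiseRates} (only \code{ado} and
#'   \code{seqError} are used).
#' @param prior numeric length-3 prior over (RR, RA, AA), summing to 1.
#' @return A data.frame with columns \code{pRR}, \code{pRA}, \code{pAA},
#'   \code{depth}, \code{map} (the maximum-a-posteriori genotype) and
#'   \code{mapProb}.
#' @examples
#' genotypePosterior(20, 0, NoiseRates(ado = 0.1, seqError = 0.001))
#' @export
genotypePosterior <- function(refCount, altCount, noise = NoiseRates(),
                              prior = c(1, 1, 1) / 3) {
  if (any(refCount < 0) || any(altCount < 0))
    stop("read counts must be non-negative")
  if (length(prior) != 3 || abs(sum(prior) - 1) > 1e-8)
    stop("prior must be a 3-vector summing to 1")
  eps <- seqError(noise); ado <- adoRate(noise)
  n <- refCount + altCount
  likRR <- stats::dbinom(altCount, n, eps)
  likAA <- stats::dbinom(refCount, n, eps)
  likRA <- (1 - ado) * stats::dbinom(altCount, n, 0.5) +
    (ado / 2) * stats::dbinom(altCount, n, eps) +
    (ado / 2) * stats::dbinom(refCount, n, eps)
  post <- cbind(RR = prior[1] * likRR, RA = prior[2] * likRA,
                AA = prior[3] * likAA)
  post <- post / rowSums(post)
  map <- colnames(post)[max.col(post, ties.method = "first")]
  data.frame(pRR = post[, "RR"], pRA = post[, "RA"], pAA = post[, "AA"],
             depth = n, map = map,
             mapProb = post[cbind(seq_len(nrow(post)),
                                  match(map, colnames(post)))],
             stringsAsFactors = FALSE)
}

#' Classify genotype posteriors into mutation statuses
#'
#' A cell-site is \code{CND} (cannot determine) when its depth is below
#' \code{minDepth} or its maximum posterior probability is below
#' \code{minPosterior}; otherwise \code{MUT} for a heterozygous or
#' homozygous-alternate MAP genotype and \code{WT} for homozygous-reference.
#'
#' @param posterior data.frame from \code{\link{genotypePosterior}}.
#' @param minDepth minimum depth for a determinable call.
#' @param minPosterior minimum MAP posterior for a determinable call.
#' @return A data.frame with columns \code{status} (MUT/WT/CND) and
#'   \code{zygosity} (RR/RA/AA/unknown).
#' @examples
#' p <- genotypePosterior(c(20, 0), c(0, 0), NoiseRates())
#' callStatus(p)
#' @export
callStatus <- function(posterior, minDepth = 5, minPosterior = 0.95) {
  stopifnot(minPosterior > 0, minPosterior <= 1, minDepth >= 0)
  cnd <- posterior$depth < minDepth | posterior$mapProb < minPosterior
  zyg <- ifelse(cnd, "unknown", posterior$map)
  status <- ifelse(cnd, "CND", ifelse(zyg == "RR", "WT", "MUT"))
  data.frame(status = status, zygosity = zyg, stringsAsFactors = FALSE)
}

#' Genotype a whole case into a StatusMatrix
#'
#' Applies \code{\link{genotypePosterior}} and \code{\link{callStatus}} to
#' every cell-site of a read-count matrix pair.
#'
#' @param refCounts,altCounts integer matrices (sites x cells).
#' @param tissue per-cell tissue labels.
#' @param region optional per-cell region labels.
#' @param gene optional per-site gene labels.
#' @param noise a \linkS4class{NoiseRates}.
#' @param prior genotype prior, see \code{\link{genotypePosterior}}.
#' @param minDepth,minPosterior thresholds, see \code{\link{callStatus}}.
#' @return A \linkS4class{StatusMatrix} with \code{status} and
#'   \code{zygosity} assays.
#' @examples
#' case <- simulateCase(seed = 1, cellsPerRegion = 3, cellsPerMet = 3,
#'                      nHetControls = 10, nHomControls = 10)
#' sm <- genotypeCase(case$refCounts, case$altCounts,
#'                    tissue = case$cellData$tissue,
#'                    region = case$cellData$region)
#' @export
genotypeCase <- function(refCounts, altCounts, tissue, region = NULL,
                         gene = NULL, noise = NoiseRates(),
                         prior = c(1, 1, 1) / 3, minDepth = 5,
                         minPosterior = 0.95) {
  stopifnot(identical(dim(refCounts), dim(altCounts)))
  post <- genotypePosterior(as.vector(refCounts), as.vector(altCounts),
                            noise, prior)
  calls <- callStatus(post, minDepth, minPosterior)
  status <- matrix(calls$status, nrow(refCounts), ncol(refCounts),
                   dimnames = dimnames(refCounts))
  zyg <- matrix(calls$zygosity, nrow(refCounts), ncol(refCounts),
                dimnames = dimnames(refCounts))
  StatusMatrix(status, tissue = tissue, region = region, gene = gene,
               zygosity = zyg)
}

#' Genotyping accuracy on a simulated case
#'
#' Fraction of cell-sites at which the MAP genotype equals the simulated
#' truth, restricted to sites with depth at least \code{minDepth}. By
#' default the accuracy is evaluated at informative amplifications, i.e.
#' excluding allele-dropout events: at a dropout the reads contain zero
#' evidence of the lost allele, so no caller can recover the truth there
#' and the Bayes-optimal error at heterozygous sites is bounded below by a
#' multiple of the dropout rate. The accuracy over all sites (dropout
#' included) is reported alongside.
#'
#' @param case a \code{\link{simulateCase}} output.
#' @param minDepth minimum depth of evaluated cell-sites.
#' @param noise a \linkS4class{NoiseRates}; defaults to the case's own
#'   generating rates.
#' @param prior genotype prior.
#' @return A list with \code{accuracy} (at informative amplifications),
#'   \code{accuracyAll} (dropout included), \code{n} (evaluated cell-sites).
#' @export
genotypeAccuracy <- function(case, minDepth = 20, noise = NULL,
                             prior = c(1, 1, 1) / 3) {
  if (is.null(noise))
    noise <- NoiseRates(ado = case$params$ado, fp = case$params$fp,
                        seqError = case$params$seqError)
  post <- genotypePosterior(as.vector(case$refCounts),
                            as.vector(case$altCounts), noise, prior)
  map <- matrix(post$map, nrow(case$refCounts), ncol(case$refCounts))
  depth <- case$refCounts + case$altCounts
  evalAll <- depth >= minDepth
  evalInf <- evalAll & !case$dropout
  list(accuracy = mean((map == case$truthGenotypes)[evalInf]),
       accuracyAll = mean((map == case$truthGenotypes)[evalAll]),
       n = sum(evalInf))
}

#' Filter candidate SNVs by tissue read support and single-cell detection
#'
#' Retains a candidate site when it has at least \code{minTissueReads}
#' supporting reads in at least one tissue and/or is detected as mutant in at
#' least \code{minCells} single cells. Both combinations of the two clauses
#' are exposed because both phrasings are in circulation: \code{rule = "OR"}
#' (default) retains a site satisfying either clause, \code{rule = "AND"}
#' requires both.
#'
#' @param status a \linkS4class{StatusMatrix} (used for per-cell detection
#'   counts).
#' @param tissueSupport numeric matrix (sites x tissues) of supporting read
#'   counts from bulk tissue sequencing.
#' @param rule \code{"OR"} or \code{"AND"}.
#' @param minTissueReads minimum supporting reads in one tissue.
#' @param minCells minimum number of cells with a MUT call.
#' @return Character vector of retained site names.
#' @export
filterSNVs <- function(status, tissueSupport, rule = c("OR", "AND"),
                       minTissueReads = 10, minCells = 3) {
  rule <- match.arg(rule)
  if (missing(tissueSupport) || is.null(tissueSupport))
    stop("tissue support table is required by the ", rule, " rule")
  st <- statusCalls(status)
  if (!all(rownames(st) %in% rownames(tissueSupport)))
    stop("tissueSupport must cover all candidate sites")
  nMutCells <- rowSums(st == "MUT")
  tissueOK <- apply(tissueSupport[rownames(st), , drop = FALSE] >=
                      minTissueReads, 1, any)
  cellsOK <- nMutCells >= minCells
  keep <- if (rule == "OR") tissueOK | cellsOK else tissueOK & cellsOK
  rownames(st)[keep]
}

#' Per-cell mutation burden
#'
#' Counts MUT sites per cell and converts to a rate per megabase of callable
#' sequence. Cells without any determinable site are flagged.
#'
#' @param status a \linkS4class{StatusMatrix}.
#' @param callableMb callable megabases per cell (positive).
#' @return data.frame with columns \code{cell}, \code{nMut},
#'   \code{nInformative}, \code{ratePerMb}.
#' @examples
#' st <- matrix(c("MUT", "WT", "MUT", "CND"), 2, 2)
#' mutationBurden(StatusMatrix(st, tissue = c("a", "a")), callableMb = 50)
#' @export
mutationBurden <- function(status, callableMb) {
  stopifnot(callableMb > 0)
  st <- statusCalls(status)
  nMut <- colSums(st == "MUT")
  nInf <- colSums(st != "CND")
  data.frame(cell = colnames(st), nMut = nMut, nInformative = nInf,
             ratePerMb = nMut / callableMb, row.names = NULL)
}

#' Single-cell versus bulk mutant-fraction concordance
#'
#' For every site and tissue with at least one determinable cell, the
#' single-cell mutant fraction is the number of MUT cells over the number of
#' determinable (MUT or WT) cells. Bulk VAFs are converted to cell fractions
#' under the diploid convention (fraction = min(1, 2 VAF), appropriate for
#' heterozygous mutations at copy-neutral loci) and compared by Pearson
#' correlation.
#'
#' @param status a \linkS4class{StatusMatrix}.
#' @param bulkVAF numeric matrix (sites x tissues) of bulk variant allele
#'   fractions; tissue columns are matched to the cell tissue labels.
#' @param vafScale multiplier converting VAF to cell fraction (default 2).
#' @return A list with \code{perSite} (data.frame: site, tissue,
#'   scFraction, bulkFraction, nDeterminable) and \code{pearson}.
#' @export
siteFractionConcordance <- function(status, bulkVAF, vafScale = 2) {
  st <- statusCalls(status)
  tis <- cellTissue(status)
  shared <- intersect(unique(tis), colnames(bulkVAF))
  rows <- list()
  for (t in shared) {
    sub <- st[, tis == t, drop = FALSE]
    nMut <- rowSums(sub == "MUT")
    nDet <- nMut + rowSums(sub == "WT")
    ok <- nDet > 0 & rownames(sub) %in% rownames(bulkVAF)
    if (!any(ok)) next
    rows[[t]] <- data.frame(
      site = rownames(sub)[ok], tissue = t,
      scFraction = nMut[ok] / nDet[ok],
      bulkFraction = clamp(vafScale * bulkVAF[rownames(sub)[ok], t], 0, 1),
      nDeterminable = nDet[ok], row.names = NULL)
  }
  perSite <- do.call(rbind, rows)
  if (is.null(perSite) || nrow(perSite) < 2)
    stop("need at least 2 determinable site fractions for a correlation")
  r <- stats::cor(perSite$scFraction, perSite$bulkFraction)
  list(perSite = perSite, pearson = r)
}
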