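#' @include AllClasses.R
NULL

# pairwise concordance machinery: given sites x cells status matrices X and Y,
# returns cross matrices of informative-site counts, concordant-site counts
# and the binary similarity R (cells of X in rows, cells of Y in columns)
.pairStats <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  M1 <- (X == "MUT") + 0; W1 <- (X == "WT") + 0
  M2 <- (Y == "MUT") + 0; W2 <- (Y == "WT") + 0
  agree <- crossprod(M1, M2) + crossprod(W1, W2)
  disagree <- crossprod(M1, W2) + crossprod(W1, M2)
  inform <- agree + disagree
  conc <- ifelse(inform > 0, agree / inform, NA_real_)
  R <- ifelse(disagree > 0, -1, 1)
  list(conc = conc, inform = inform, R = R)
}

#' Binary similarity of a pair of single cells
#'
#' Two cells are considered the same (R = +1) when, at every site, their
#' mutation statuses agree or at least one of them cannot be determined
#' (CND); they are different (R = -1) as soon as any site is determinably
#' mutant in one cell and wild type in the other. The graded concordance
#' (fraction of agreeing sites among sites determinable in both cells) is
#' returned alongside for ranking purposes.
#'
#' @param statusA,statusB character vectors over the same sites, with values
#'   MUT/WT/CND.
#' @return A list with \code{R} (+1 or -1), \code{nInformative} and
#'   \code{concordance} (NA when no site is informative).
#' @examples
#' pairSimilarity(c("MUT", "WT", "CND"), c("MUT", "CND", "MUT"))
#' @export
pairSimilarity <- function(statusA, statusB) {
  if (length(statusA) != length(statusB))
    stop("status vectors must cover the same sites")
  if (!is.null(names(statusA)) && !is.null(names(statusB)) &&
      !identical(names(statusA), names(statusB)))
    stop("status vectors must have identical site ordering")
  ps <- .pairStats(cbind(statusA), cbind(statusB))
  list(R = as.numeric(ps$R[1, 1]),
       nInformative = as.numeric(ps$inform[1, 1]),
       concordance = as.numeric(ps$conc[1, 1]))
}

#' Tissue heterogeneity from all cell-pair similarities
#'
#' The similarity index of a tissue is the average R value over all unordered
#' cell pairs within it; the heterogeneity H is the fraction of discordant
#' pairs, so that index = 1 - 2 H exactly. Pairs without any informative site
#' have R = +1 and are included by default (a flag excludes them).
#'
#' @param status a \linkS4class{StatusMatrix}.
#' @param includeEmptyPairs count pairs with zero informative sites
#'   (default TRUE).
#' @return data.frame with one row per tissue: \code{tissue}, \code{nCells},
#'   \code{nPairs}, \code{similarityIndex}, \code{H}. Tissues with fewer than
#'   2 cells get NA. The per-pair R values are attached as the
#'   \code{"pairR"} attribute (a named list of vectors) for density displays.
#' @examples
#' st <- matrix(rep(c("MUT", "WT"), each = 4), 2, 4, byrow = TRUE)
#' tissueHeterogeneity(StatusMatrix(st, tissue = rep("primary", 4)))
#' @export
tissueHeterogeneity <- function(status, includeEmptyPairs = TRUE) {
  st <- statusCalls(status)
  tis <- cellTissue(status)
  out <- list(); pairR <- list()
  for (t in unique(tis)) {
    sub <- st[, tis == t, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) {
      out[[t]] <- data.frame(tissue = t, nCells = n, nPairs = 0L,
                             similarityIndex = NA_real_, H = NA_real_)
      next
    }
    ps <- .pairStats(sub)
    up <- upper.tri(ps$R)
    R <- ps$R[up]
    if (!includeEmptyPairs) R <- R[ps$inform[up] > 0]
    idx <- mean(R)
    out[[t]] <- data.frame(tissue = t, nCells = n,
                           nPairs = length(R),
                           similarityIndex = idx, H = (1 - idx) / 2)
    pairR[[t]] <- R
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  attr(res, "pairR") <- pairR
  res
}

#' Exclude presumed normal cells from a status matrix
#'
#' Cells that cluster with normal tissue typically carry only 1-2 mutations
#' and no driver mutations. A cell is excluded when its mutation burden is at
#' most \code{maxNormalBurden} AND it has no MUT call in any driver gene.
#'
#' @param status a \linkS4class{StatusMatrix} with per-site gene labels.
#' @param driverGenes non-empty character vector of driver gene labels.
#' @param maxNormalBurden maximum MUT count of a presumed normal cell.
#' @return A list with \code{tumor} (the retained \linkS4class{StatusMatrix})
#'   and \code{excluded} (character vector of excluded cell names).
#' @export
excludeNormalCells <- function(status, driverGenes, maxNormalBurden = 2) {
  if (!length(driverGenes)) stop("driverGenes must be non-empty")
  st <- statusCalls(status)
  genes <- siteGene(status)
  if (is.null(genes)) stop("status matrix carries no gene labels")
  burden <- colSums(st == "MUT")
  driverRows <- genes %in% driverGenes
  hasDriver <- colSums(st[driverRows, , drop = FALSE] == "MUT") > 0
  excl <- burden <= maxNormalBurden & !hasDriver
  list(tumor = status[, !excl], excluded = colnames(st)[excl])
}

#' Trace the primary-region origin of metastatic cells
#'
#' Each metastatic cell is compared with every primary single cell and
#' assigned to the region of its maximum-concordance primary cell, requiring
#' at least \code{minInformative} sites determinable in both cells. Ties are
#' broken by the larger number of informative sites, then by lexicographic
#' region label (the tie is flagged). When \code{sourceRegions} is given, a
#' two-sided Fisher exact test compares the assigned counts
#' (source regions vs rest) against the primary sampling composition.
#'
#' @param status a \linkS4class{StatusMatrix} containing both primary cells
#'   (with region labels) and metastatic cells.
#' @param metTissue tissue label of the metastasis to trace.
#' @param minInformative minimum shared determinable sites for a candidate.
#' @param sourceRegions optional character vector of regions to group for the
#'   enrichment test.
#' @return A list with \code{assignments} (data.frame: cell, region,
#'   concordance, nInformative, tie), \code{counts} (assigned cells per
#'   region), and, when \code{sourceRegions} is given, \code{p} and
#'   \code{tracedFraction} (share of assigned cells in the source regions).
#' @export
traceOrigin <- function(status, metTissue, minInformative = 5,
                        sourceRegions = NULL) {
  st <- statusCalls(status)
  tis <- cellTissue(status)
  reg <- cellRegion(status)
  if (is.null(reg)) stop("status matrix carries no region labels")
  isMet <- tis == metTissue
  isPrim <- !is.na(reg)
  if (!any(isMet)) stop("no cells in tissue ", metTissue)
  if (!any(isPrim)) stop("no primary cells with region labels")
  ps <- .pairStats(st[, isMet, drop = FALSE], st[, isPrim, drop = FALSE])
  conc <- ps$conc; inform <- ps$inform
  conc[inform < minInformative] <- NA
  primReg <- reg[isPrim]
  metCells <- colnames(st)[isMet]
  rows <- lapply(seq_along(metCells), function(i) {
    ci <- conc[i, ]
    if (all(is.na(ci)))
      return(data.frame(cell = metCells[i], region = NA_character_,
                        concordance = NA_real_, nInformative = NA_real_,
                        tie = FALSE))
    best <- max(ci, na.rm = TRUE)
    cand <- which(!is.na(ci) & ci >= best - 1e-12)
    tie <- length(unique(primReg[cand])) > 1
    cand <- cand[order(-inform[i, cand], primReg[cand])]
    data.frame(cell = metCells[i], region = primReg[cand[1]],
               concordance = best, nInformative = inform[i, cand[1]],
               tie = tie)
  })
  assignments <- do.call(rbind, rows)
  assigned <- assignments[!is.na(assignments$region), ]
  counts <- table(factor(assigned$region, levels = sort(unique(primReg))))
  out <- list(assignments = assignments, counts = counts)
  if (!is.null(sourceRegions)) {
    inSrc <- assigned$region %in% sourceRegions
    primSrc <- primReg %in% sourceRegions
    tab <- matrix(c(sum(inSrc), sum(!inSrc),
                    sum(primSrc), sum(!primSrc)), 2, 2, byrow = TRUE)
    out$p <- fisherExact2x2(tab)
    out$tracedFraction <- mean(inSrc)
  }
  out
}

#' Hierarchical clustering and PCA of the single-cell mutation landscape
#'
#' Cells are clustered with average-linkage hierarchical clustering on the
#' CND-aware distance 1 - concordance (pairs without informative overlap get
#' distance 0, consistent with the R = +1 convention for such pairs). PCA is
#' run on the MUT = 1 / WT = 0 encoding with CND imputed to the site mean.
#'
#' @param status a \linkS4class{StatusMatrix} with at least 3 cells.
#' @param linkage linkage method for \code{\link[stats]{hclust}}.
#' @param nComponents number of principal components to return.
#' @return A list with \code{hclust}, \code{newick} (the dendrogram as a
#'   Newick string), \code{pca} (cells x components score matrix) and
#'   \code{varExplained}.
#' @export
clusterAndEmbed <- function(status, linkage = "average", nComponents = 2) {
  st <- statusCalls(status)
  if (ncol(st) < 3) stop("need at least 3 cells")
  if (all(st == "CND")) stop("all statuses are CND; nothing to cluster")
  ps <- .pairStats(st)
  D <- 1 - ps$conc
  D[is.na(D)] <- 0
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  enc <- matrix(NA_real_, nrow(st), ncol(st), dimnames = dimnames(st))
  enc[st == "MUT"] <- 1; enc[st == "WT"] <- 0
  siteMean <- rowMeans(enc, na.rm = TRUE)
  siteMean[is.nan(siteMean)] <- 0
  idx <- which(is.na(enc), arr.ind = TRUE)
  if (nrow(idx)) enc[idx] <- siteMean[idx[, 1]]
  keep <- apply(enc, 1, stats::var) > 0
  pc <- stats::prcomp(t(enc[keep, , drop = FALSE]), center = TRUE)
  k <- min(nComponents, ncol(pc$x))
  list(hclust = hc, newick = newick,
       pca = pc$x[, seq_len(k), drop = FALSE],
       varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Count distinct metastasis lineages from single-cell data
#'
#' Clusters the metastatic cells on the 1 - concordance distance and counts
#' the clusters obtained by cutting the average-linkage dendrogram at
#' \code{cutHeight}. The cut height sits between the within-clone
#' disagreement floor induced by allele dropout and the between-clone
#' divergence of distinct seeding lineages.
#'
#' @param status a \linkS4class{StatusMatrix}.
#' @param metTissue metastasis tissue label.
#' @param cutHeight dendrogram cut height on the distance scale.
#' @return Integer number of lineages (1 for a single metastatic cell).
#' @export
countMetLineages <- function(status, metTissue, cutHeight = 0.15) {
  st <- statusCalls(status)
  sub <- st[, cellTissue(status) == metTissue, drop = FALSE]
  if (ncol(sub) < 2) return(as.integer(min(1L, ncol(sub))))
  ps <- .pairStats(sub)
  D <- 1 - ps$conc
  D[is.na(D)] <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  length(unique(stats::cutree(hc, h = cutHeight)))
}

#' Heterogeneity-based mono/polyclonal seeding rule
#'
#' Classifies the seeding of a metastasis as polyclonal when the metastasis
#' heterogeneity H is within \code{hTol} of the source-region H and the
#' metastasis contains at least two distinct seeded lineages
#' (\code{\link{countMetLineages}}); monoclonal otherwise.
#'
#' @param status a \linkS4class{StatusMatrix}.
#' @param metTissue metastasis tissue label.
#' @param sourceRegions primary regions the metastasis derives from.
#' @param hTol tolerance on the H difference.
#' @param cutHeight lineage-counting cut height.
#' @return A list with \code{mode}, \code{nLineages}, \code{metH},
#'   \code{sourceH}.
#' @export
heterogeneitySeedingRule <- function(status, metTissue, sourceRegions,
                                     hTol = 0.1, cutHeight = 0.15) {
  st <- statusCalls(status)
  tis <- cellTissue(status)
  reg <- cellRegion(status)
  het <- tissueHeterogeneity(status)
  metH <- het$H[het$tissue == metTissue]
  srcCells <- !is.na(reg) & reg %in% sourceRegions
  srcSub <- status[, srcCells]
  colData(srcSub)$tissue <- "source"
  srcH <- tissueHeterogeneity(srcSub)$H[1]
  nl <- countMetLineages(status, metTissue, cutHeight)
  mode <- if (!is.na(metH) && !is.na(srcH) &&
              abs(metH - srcH) <= hTol && nl >= 2) "polyclonal"
          else "monoclonal"
  list(mode = mode, nLineages = nl, metH = metH, sourceH = srcH)
}
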