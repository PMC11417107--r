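#' @include AllClasses.R
NULL

#' Project metastatic cells onto primary clusters
#'
#' Centroid projection in the style of cluster-level scmap: per primary
#' cluster the centroid is the per-gene median over its cells, computed on
#' the \code{nFeatures} most variable genes of the primary matrix. Every
#' metastatic cell computes cosine, Pearson and Spearman similarity to every
#' centroid and is assigned to the top centroid when at least two of the
#' three measures agree on it and the maximum similarity reaches
#' \code{threshold}; otherwise it is unassigned. Clusters with fewer than 3
#' cells are excluded from the centroid set with a warning.
#'
#' @param met genes x cells metastasis expression matrix.
#' @param primary genes x cells primary expression matrix (same gene
#'   universe as \code{met}).
#' @param clusters named character vector: primary cell -> cluster.
#' @param nFeatures number of variance-ranked genes used.
#' @param threshold minimum similarity for an assignment, in [0, 1].
#' @return data.frame with columns \code{cell}, \code{cluster} (NA when
#'   unassigned), \code{cosine}, \code{pearson}, \code{spearman}.
#' @export
projectCells <- function(met, primary, clusters, nFeatures = 500,
                         threshold = 0.7) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!identical(rownames(met), rownames(primary)))
    stop("met and primary must share the same gene universe")
  clusters <- clusters[colnames(primary)]
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("clusters with < 3 cells excluded from centroids: ",
            paste(small, collapse = ", "))
    keep <- !clusters %in% small
    primary <- primary[, keep, drop = FALSE]
    clusters <- clusters[keep]
  }
  if (!length(clusters)) stop("no usable primary clusters")
  v <- apply(primary, 1, stats::var)
  feats <- order(v, decreasing = TRUE)[seq_len(min(nFeatures, nrow(primary)))]
  P <- primary[feats, , drop = FALSE]
  M <- met[feats, , drop = FALSE]
  cls <- sort(unique(clusters))
  centroids <- vapply(cls, function(k)
    apply(P[, clusters == k, drop = FALSE], 1, stats::median),
    numeric(length(feats)))
  simOne <- function(x) {
    if (all(x == 0)) return(NULL)
    cosv <- apply(centroids, 2, function(cc) cosineSimilarity(x, cc))
    pear <- suppressWarnings(apply(centroids, 2, stats::cor, y = x))
    spea <- suppressWarnings(apply(centroids, 2, stats::cor, y = x,
                                   method = "spearman"))
    list(cos = cosv, pear = pear, spea = spea)
  }
  rows <- lapply(seq_len(ncol(M)), function(j) {
    s <- simOne(M[, j])
    res <- data.frame(cell = colnames(M)[j], cluster = NA_character_,
                      cosine = NA_real_, pearson = NA_real_,
                      spearman = NA_real_)
    if (is.null(s)) return(res)
    tops <- c(cls[which.max(s$cos)], cls[which.max(s$pear)],
              cls[which.max(s$spea)])
    tt <- table(tops)
    if (max(tt) >= 2) {
      top <- names(tt)[which.max(tt)]
      maxSim <- max(s$cos[top], s$pear[top], s$spea[top], na.rm = TRUE)
      if (is.finite(maxSim) && maxSim >= threshold) res$cluster <- top
    }
    res$cosine <- max(s$cos, na.rm = TRUE)
    res$pearson <- max(s$pear, na.rm = TRUE)
    res$spearman <- max(s$spea, na.rm = TRUE)
    res
  })
  do.call(rbind, rows)
}

#' Metastatic contribution (MC) score per primary cluster
#'
#' The MC score of a primary cluster is the fraction of assigned metastatic
#' cells that project onto it; scores sum to 1 over clusters.
#'
#' @param assignments data.frame from \code{\link{projectCells}}.
#' @param clusters optional cluster universe (so that clusters receiving no
#'   cells report 0).
#' @return Named numeric vector of per-cluster scores.
#' @examples
#' a <- data.frame(cell = c("m1", "m2"), cluster = c("k1", "k1"))
#' mcScore(a, clusters = c("k1", "k2"))
#' @export
mcScore <- function(assignments, clusters = NULL) {
  asg <- assignments$cluster[!is.na(assignments$cluster)]
  if (!length(asg)) {
    warning("no assigned cells; MC score undefined")
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.null(clusters)) clusters <- sort(unique(asg))
  tab <- table(factor(asg, levels = clusters))
  stats::setNames(as.numeric(tab) / length(asg), clusters)
}

#' Expression-bin-matched gene-set module score
#'
#' Module scoring with expression-matched controls: genes are ranked by
#' cohort-average expression and split into \code{nBins} equal-frequency
#' bins; for every gene of the set, \code{nCtrl} control genes are sampled
#' (with replacement) from the non-set genes of its bin (falling back to the
#' nearest bins when a bin holds only set genes); the per-cell score is the
#' mean expression of the set genes minus the mean expression of the sampled
#' control genes. Excluding the set genes from the control pool keeps the
#' score an unbiased estimate of the set's excess expression even for small
#' gene universes. A constant matrix scores exactly 0 for every cell.
#'
#' @param expr genes x cells expression matrix.
#' @param geneSet non-empty character vector of set genes, all present in
#'   \code{expr}.
#' @param nBins number of expression bins (>= 2).
#' @param nCtrl control genes sampled per set gene.
#' @param seed integer seed for the control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
emtModuleScore <- function(expr, geneSet, nBins = 24, nCtrl = 100,
                           seed = 1) {
  if (!length(geneSet)) stop("gene set is empty")
  if (!all(geneSet %in% rownames(expr)))
    stop("gene set contains genes absent from the expression matrix")
  stopifnot(nBins >= 2)
  avg <- rowMeans(expr)
  nBins <- min(nBins, length(avg))
  bins <- cut(rank(avg, ties.method = "first"), breaks = nBins,
              labels = FALSE)
  names(bins) <- rownames(expr)
  notSet <- setdiff(rownames(expr), geneSet)
  if (!length(notSet)) stop("no non-set genes available as controls")
  withSeed(deriveSeed(seed, "module-score"), {
    ctrl <- unlist(lapply(geneSet, function(g) {
      pool <- notSet[bins[notSet] == bins[[g]]]
      width <- 0L
      while (!length(pool)) {   # widen to neighboring bins if necessary
        width <- width + 1L
        pool <- notSet[abs(bins[notSet] - bins[[g]]) <= width]
      }
      sample(pool, nCtrl, replace = TRUE)
    }))
    setMean <- colMeans(expr[geneSet, , drop = FALSE])
    ctrlMean <- colMeans(expr[ctrl, , drop = FALSE])
    setMean - ctrlMean
  })
}

#' Quadratic CNV score
#'
#' The genomic-instability score of a cell is the quadratic sum of its
#' copy-number region values' deviations from the neutral baseline:
#' score = sum over regions of (value - baseline)^2.
#'
#' @param cnv cells x regions numeric matrix (no missing values).
#' @param baseline neutral level (default 1, the modified-expression
#'   convention).
#' @return Named numeric vector of per-cell scores.
#' @examples
#' cnvScore(matrix(c(1, 1.3, 1, 0.8), 2, 2))
#' @export
cnvScore <- function(cnv, baseline = 1) {
  if (anyNA(cnv))
    stop("cnv matrix contains missing values; impute upstream")
  rowSums((cnv - baseline)^2)
}

#' Linear regression of MC score on EMT score across clusters
#'
#' Ordinary least squares of the per-cluster MC score on the per-cluster
#' mean EMT score.
#'
#' @param emt named numeric vector of per-cluster mean EMT scores.
#' @param mc named numeric vector of per-cluster MC scores (same clusters).
#' @return A list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{p}.
#' @examples
#' regressEmtMc(c(a = 0, b = 1, c = 2), c(a = 0, b = 1, c = 2))
#' @export
regressEmtMc <- function(emt, mc) {
  common <- intersect(names(emt), names(mc))
  if (length(common) < 3) stop("need at least 3 clusters")
  emt <- emt[common]; mc <- mc[common]
  if (stats::var(emt) == 0) stop("zero-variance EMT predictor")
  fit <- stats::lm(mc ~ emt)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = sm$r.squared,
       p = sm$coefficients[2, 4])
}

#' Basic single-cell QC filter
#'
#' Removes cells with fewer than \code{minGenes} detected genes or with a
#' mitochondrial fraction of \code{maxMitoFrac} or more.
#'
#' @param expr genes x cells matrix.
#' @param minGenes minimum detected genes per cell.
#' @param maxMitoFrac maximum mitochondrial expression fraction.
#' @param mitoPattern regular expression identifying mitochondrial genes.
#' @return The filtered matrix.
#' @export
qcFilterCells <- function(expr, minGenes = 200, maxMitoFrac = 0.2,
                          mitoPattern = "^MT-") {
  detected <- colSums(expr > 0)
  mito <- grepl(mitoPattern, rownames(expr))
  mitoFrac <- if (any(mito))
    colSums(expr[mito, , drop = FALSE]) / pmax(colSums(expr), 1)
  else rep(0, ncol(expr))
  expr[, detected >= minGenes & mitoFrac < maxMitoFrac, drop = FALSE]
}

#' Score a simulated expression case end to end
#'
#' Runs projection, MC scoring, EMT module scoring, CNV scoring and the
#' EMT-MC regression on a \code{\link{simulateExpressionCase}} output.
#'
#' @param ec a \code{\link{simulateExpressionCase}} output.
#' @param nFeatures,threshold projection controls.
#' @param seed seed for the module-score control sampling.
#' @return A list with \code{assignments}, \code{mc}, \code{emtPrimary}
#'   (per-cell), \code{emtByCluster}, \code{cnv}, \code{regression},
#'   \code{accuracy} (fraction of assigned cells whose assignment matches
#'   the recorded truth).
#' @export
scoreExpressionCase <- function(ec, nFeatures = 500, threshold = 0.7,
                                seed = 1) {
  asg <- projectCells(ec$metastasis, ec$primary, ec$primaryClusters,
                      nFeatures = nFeatures, threshold = threshold)
  clusters <- sort(unique(ec$primaryClusters))
  mc <- mcScore(asg, clusters = clusters)
  emt <- emtModuleScore(ec$primary, ec$emtGenes, seed = seed)
  emtBy <- tapply(emt[names(ec$primaryClusters)], ec$primaryClusters, mean)
  emtBy <- stats::setNames(as.numeric(emtBy), names(emtBy))[clusters]
  cnv <- cnvScore(ec$cnv)
  reg <- regressEmtMc(emtBy, mc)
  merged <- merge(asg, ec$truth, by = "cell")
  ok <- !is.na(merged$cluster)
  accuracy <- if (any(ok))
    mean(merged$cluster[ok] == merged$sourceCluster[ok]) else NA_real_
  list(assignments = asg, mc = mc, emtPrimary = emt, emtByCluster = emtBy,
       cnv = cnv, regression = reg, accuracy = accuracy)
}
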