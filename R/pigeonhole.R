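#' @include AllClasses.R
#' @importFrom mclust Mclust mclustBIC
NULL

.validateClusterSet <- function(clusters, clonalThreshold = 0.85) {
  need <- c("cluster", "n_mutations", "ccf_primary", "ccf_met")
  if (!all(need %in% colnames(clusters)))
    stop("cluster set needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(clusters$cluster)) stop("cluster ids must be unique")
  if (any(clusters$n_mutations < 1)) stop("clusters need >= 1 mutation")
  if (any(clusters$ccf_primary < -1e-9 | clusters$ccf_primary > 1 + 1e-9) ||
      any(clusters$ccf_met < -1e-9 | clusters$ccf_met > 1 + 1e-9))
    stop("CCFs must lie in [0, 1]")
  trunk <- clusters$ccf_primary >= clonalThreshold &
    clusters$ccf_met >= clonalThreshold
  if (sum(trunk) != 1)
    stop("exactly one clonal (trunk) cluster with CCF >= ", clonalThreshold,
         " in both samples is required; found ", sum(trunk))
  clusters$cluster[trunk]
}

#' Cluster mutation VAFs into cancer-cell-fraction clusters
#'
#' Converts paired primary/metastasis variant allele fractions to cancer cell
#' fractions under the diploid copy-neutral convention
#' CCF = min(1, 2 VAF / purity), then clusters the 2-D CCF points. The
#' default method fits Gaussian mixtures with spherical per-cluster
#' covariances and selects the number of clusters by BIC (the convention of
#' mixture-model subclone callers, and markedly better than silhouette-based
#' k-means at separating close clusters); \code{method = "kmeans"} uses
#' k-means with the number of clusters chosen by maximum average silhouette
#' width over 2..\code{kMax}. A single cluster is returned when all points
#' lie within \code{mergeTol} of each other.
#'
#' @param vafPrimary,vafMet numeric vectors of per-mutation VAFs.
#' @param purity length-2 sample purities in (0, 1].
#' @param kMax maximum number of clusters considered.
#' @param mergeTol CCF radius below which all mutations form one cluster.
#' @param method \code{"gmm"} (default) or \code{"kmeans"}.
#' @param seed integer seed for k-means restarts (the mixture fit is
#'   deterministic).
#' @return data.frame with columns \code{cluster}, \code{n_mutations},
#'   \code{ccf_primary}, \code{ccf_met}; per-mutation assignments are
#'   attached as attribute \code{"assignment"}.
#' @examples
#' cl <- clusterCCF(c(.5, .5, .25, .24), c(.5, .49, .01, 0), seed = 1)
#' @export
clusterCCF <- function(vafPrimary, vafMet, purity = c(1, 1), kMax = 8,
                       mergeTol = 0.1, method = c("gmm", "kmeans"),
                       seed = 1) {
  method <- match.arg(method)
  if (!length(vafPrimary)) stop("empty VAF list")
  stopifnot(length(vafPrimary) == length(vafMet),
            all(purity > 0), all(purity <= 1))
  if (any(vafPrimary < 0 | vafPrimary > 0.55 + 1e-9) ||
      any(vafMet < 0 | vafMet > 0.55 + 1e-9))
    stop("VAFs must lie in [0, 0.55]")
  ccf <- cbind(primary = pmin(1, 2 * vafPrimary / purity[1]),
               met = pmin(1, 2 * vafMet / purity[2]))
  n <- nrow(ccf)
  spread <- if (n > 1) max(stats::dist(ccf)) else 0
  if (n == 1 || spread <= mergeTol) {
    assignment <- rep(1L, n)
  } else if (method == "gmm") {
    fit <- mclust::Mclust(ccf, G = 1:min(kMax, n - 1),
                          modelNames = "VII", verbose = FALSE)
    if (is.null(fit))
      fit <- mclust::Mclust(ccf, G = 1:min(kMax, n - 1), verbose = FALSE)
    assignment <- fit$classification
  } else {
    withSeed(deriveSeed(seed, "ccf-kmeans"), {
      ks <- 2:min(kMax, n - 1, nrow(unique(round(ccf, 6))))
      bestSil <- -Inf; assignment <- NULL
      d <- stats::dist(ccf)
      for (k in ks) {
        km <- stats::kmeans(ccf, centers = k, nstart = 10, iter.max = 50)
        sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
        if (sil > bestSil) { bestSil <- sil; assignment <- km$cluster }
      }
    })
  }
  agg <- function(v) tapply(v, assignment, mean)
  out <- data.frame(
    cluster = paste0("C", sort(unique(assignment))),
    n_mutations = as.integer(table(assignment)),
    ccf_primary = clamp(as.numeric(agg(ccf[, 1])), 0, 1),
    ccf_met = clamp(as.numeric(agg(ccf[, 2])), 0, 1),
    row.names = NULL)
  attr(out, "assignment") <- paste0("C", assignment)
  out
}

# does adding `child` under `parent` keep the pigeonhole constraint in every
# sample? (child fits under parent; siblings' CCFs sum to at most the parent's)
.placementValid <- function(clusters, parentOf, child, parent, tol) {
  ccf <- as.matrix(clusters[, c("ccf_primary", "ccf_met")])
  rownames(ccf) <- clusters$cluster
  sibs <- names(parentOf)[!is.na(parentOf) & parentOf == parent]
  sibSum <- ccf[child, ] + if (length(sibs))
    colSums(ccf[sibs, , drop = FALSE]) else c(0, 0)
  all(ccf[child, ] <= ccf[parent, ] + tol) &&
    all(sibSum <= ccf[parent, ] + tol)
}

#' Build a subclonal tree by the pigeonhole principle
#'
#' Places every cluster under the trunk-rooted tree such that, in every
#' sample, the CCFs of the children of a node sum to at most the node's CCF
#' (plus \code{tolerance}). Clusters are inserted in decreasing total CCF;
#' each is attached to the valid parent closest to the root (largest CCF), so
#' trees are maximally branched subject to the constraint, and nesting into a
#' chain occurs exactly when a sibling sum would violate the constraint in
#' some sample. A cluster with no valid parent is attached to the trunk and
#' flagged as a constraint violation.
#'
#' Branch lengths are the proportion of all mutations in each cluster and sum
#' to 1 over the tree.
#'
#' @param clusters data.frame with columns \code{cluster},
#'   \code{n_mutations}, \code{ccf_primary}, \code{ccf_met}.
#' @param tolerance CCF slack for the constraint (default 0.1).
#' @param clonalThreshold trunk definition: CCF at least this in both
#'   samples.
#' @param strict refuse (TRUE, default) when the trunk invariant fails;
#'   with FALSE the cluster with the largest total CCF is taken as trunk
#'   with a warning, which keeps automated pipelines running on noisy
#'   cluster sets.
#' @return data.frame with columns \code{cluster}, \code{parent} (NA for the
#'   trunk), \code{ccf_primary}, \code{ccf_met}, \code{n_mutations},
#'   \code{branch_length}, \code{violation}.
#' @examples
#' cl <- data.frame(cluster = c("A", "B", "C"), n_mutations = c(10, 6, 4),
#'                  ccf_primary = c(1, .6, .5), ccf_met = c(1, .9, .8))
#' buildTree(cl)
#' @export
buildTree <- function(clusters, tolerance = 0.1, clonalThreshold = 0.85,
                      strict = TRUE) {
  trunk <- if (strict) .validateClusterSet(clusters, clonalThreshold)
  else tryCatch(.validateClusterSet(clusters, clonalThreshold),
                error = function(e) {
                  warning("trunk invariant not met (", conditionMessage(e),
                          "); using the largest-CCF cluster as trunk")
                  tot <- clusters$ccf_primary + clusters$ccf_met
                  clusters$cluster[which.max(tot)]
                })
  ids <- clusters$cluster
  ccfSum <- clusters$ccf_primary + clusters$ccf_met
  names(ccfSum) <- ids
  parentOf <- stats::setNames(rep(NA_character_, length(ids)), ids)
  placed <- trunk
  violation <- stats::setNames(rep(FALSE, length(ids)), ids)
  todo <- setdiff(ids[order(-ccfSum)], trunk)
  for (child in todo) {
    cand <- placed[vapply(placed, function(p)
      .placementValid(clusters, parentOf[placed], child, p, tolerance),
      logical(1))]
    if (!length(cand)) {
      warning("cluster ", child, " has no pigeonhole-consistent placement; ",
              "attached to trunk")
      parentOf[child] <- trunk
      violation[child] <- TRUE
    } else {
      parentOf[child] <- cand[which.max(ccfSum[cand])]
    }
    placed <- c(placed, child)
  }
  data.frame(cluster = ids, parent = unname(parentOf[ids]),
             ccf_primary = clusters$ccf_primary,
             ccf_met = clusters$ccf_met,
             n_mutations = clusters$n_mutations,
             branch_length = clusters$n_mutations /
               sum(clusters$n_mutations),
             violation = unname(violation[ids]),
             stringsAsFactors = FALSE)
}

# verify the sibling-sum pigeonhole constraint on a built tree
.treeSatisfiesPigeonhole <- function(tree, tolerance = 0.1) {
  for (p in tree$cluster) {
    kids <- tree$cluster[!is.na(tree$parent) & tree$parent == p]
    if (!length(kids)) next
    pc <- tree[tree$cluster == p, c("ccf_primary", "ccf_met")]
    ks <- colSums(tree[tree$cluster %in% kids,
                       c("ccf_primary", "ccf_met"), drop = FALSE])
    if (any(ks > unlist(pc) + tolerance + 1e-9)) return(FALSE)
  }
  TRUE
}

#' Classify metastatic seeding as monoclonal or polyclonal
#'
#' The metastasis-present clusters are those with
#' \code{ccf_met > presenceThreshold}. Seeding is monoclonal when they lie on
#' a single root-to-leaf path of the subclonal tree (every pair in an
#' ancestor-descendant relation) and polyclonal when they span at least two
#' branches not in such a relation.
#'
#' @param tree data.frame from \code{\link{buildTree}}.
#' @param presenceThreshold CCF above which a cluster counts as present in
#'   the metastasis.
#' @return A list with \code{mode} ("monoclonal"/"polyclonal", or NA with a
#'   warning when nothing is metastasis-present), \code{metPresent} (cluster
#'   ids) and \code{seedingLineages} (the maximal met-present branches).
#' @examples
#' cl <- data.frame(cluster = c("A", "B", "C"), n_mutations = c(10, 6, 4),
#'                  ccf_primary = c(1, .6, .3), ccf_met = c(1, .7, .2))
#' classifySeeding(buildTree(cl))
#' @export
classifySeeding <- function(tree, presenceThreshold = 0.05) {
  parent <- stats::setNames(tree$parent, tree$cluster)
  present <- tree$cluster[tree$ccf_met > presenceThreshold]
  if (!length(present)) {
    warning("no metastasis-present cluster; seeding mode undefined")
    return(list(mode = NA_character_, metPresent = character(0),
                seedingLineages = character(0)))
  }
  comparable <- function(a, b)
    .isAncestorOrSelf(parent, a, b) || .isAncestorOrSelf(parent, b, a)
  mono <- TRUE
  for (a in present) for (b in present)
    if (a < b && !comparable(a, b)) mono <- FALSE
  # maximal met-present lineages: present clusters with no present descendant
  hasPresentDesc <- vapply(present, function(a)
    any(vapply(setdiff(present, a), function(b)
      .isAncestorOrSelf(parent, a, b), logical(1))), logical(1))
  list(mode = if (mono) "monoclonal" else "polyclonal",
       metPresent = present,
       seedingLineages = present[!hasPresentDesc])
}

#' Export a subclonal tree as a Newick string
#'
#' @param tree data.frame from \code{\link{buildTree}}.
#' @return Newick string with branch lengths equal to the mutation
#'   proportions.
#' @export
treeNewick <- function(tree) {
  kids <- function(p) tree$cluster[!is.na(tree$parent) & tree$parent == p]
  rec <- function(node) {
    k <- kids(node)
    bl <- tree$branch_length[tree$cluster == node]
    inner <- if (length(k))
      paste0("(", paste(vapply(k, rec, character(1)), collapse = ","), ")")
    else ""
    paste0(inner, node, ":", format(bl, digits = 10))
  }
  root <- tree$cluster[is.na(tree$parent)]
  paste0(rec(root), ";")
}

#' Simulate a paired-sample CCF cluster case
#'
#' Generates a random clone tree, pigeonhole-consistent true cluster CCFs in
#' a primary and a metastasis sample (monoclonal: all metastasis cells from
#' one clone; polyclonal: from two clones on distinct branches), and noisy
#' per-mutation CCF observations around the cluster values.
#'
#' @param seedingMode \code{"monoclonal"} or \code{"polyclonal"}.
#' @param nClusters number of clones/clusters (>= 3 for polyclonal).
#' @param mutationsPerCluster mutations per cluster.
#' @param ccfNoiseSd standard deviation of per-mutation CCF noise.
#' @param seed integer seed.
#' @return A list with \code{trueClusters} (data.frame with true CCFs and
#'   parents), \code{mutations} (per-mutation noisy CCF pairs),
#'   \code{mode}.
#' @export
simulateCCFCase <- function(seedingMode = c("polyclonal", "monoclonal"),
                            nClusters = 5, mutationsPerCluster = 40,
                            ccfNoiseSd = 0.05, seed = 1) {
  seedingMode <- match.arg(seedingMode)
  if (seedingMode == "polyclonal" && nClusters < 3)
    stop("polyclonal requires at least 3 clusters")
  withSeed(deriveSeed(seed, "ccf-case"), {
    ids <- paste0("C", seq_len(nClusters))
    repeat {
      parent <- .randomRecursiveTree(ids)
      if (seedingMode == "monoclonal") break
      ok <- FALSE
      for (a in ids) for (b in ids)
        if (a < b && !.isAncestorOrSelf(parent, a, b) &&
            !.isAncestorOrSelf(parent, b, a)) ok <- TRUE
      if (ok) break
    }
    dirichlet <- function(n) { g <- stats::rgamma(n, 2); g / sum(g) }
    wPrim <- stats::setNames(dirichlet(nClusters), ids)
    if (seedingMode == "monoclonal") {
      tgt <- sample(ids, 1)
      wMet <- stats::setNames(rep(0, nClusters), ids); wMet[tgt] <- 1
    } else {
      pairs <- list()
      for (a in ids) for (b in ids)
        if (a < b && !.isAncestorOrSelf(parent, a, b) &&
            !.isAncestorOrSelf(parent, b, a))
          pairs[[length(pairs) + 1]] <- c(a, b)
      pick <- sample(pairs[[sample.int(length(pairs), 1)]])
      u <- stats::runif(1, 0.55, 0.8)
      wMet <- stats::setNames(rep(0, nClusters), ids)
      wMet[pick] <- c(u, 1 - u)
    }
    ccfP <- .subtreePrevalence(parent, wPrim)
    ccfM <- .subtreePrevalence(parent, wMet)
    trueClusters <- data.frame(cluster = ids, parent = unname(parent[ids]),
                               ccf_primary = unname(ccfP[ids]),
                               ccf_met = unname(ccfM[ids]),
                               n_mutations = mutationsPerCluster)
    mut <- do.call(rbind, lapply(ids, function(cid) data.frame(
      cluster = cid,
      ccf_primary = clamp(ccfP[cid] +
        stats::rnorm(mutationsPerCluster, 0, ccfNoiseSd), 0, 1),
      ccf_met = clamp(ccfM[cid] +
        stats::rnorm(mutationsPerCluster, 0, ccfNoiseSd), 0, 1))))
    list(trueClusters = trueClusters, mutations = mut, mode = seedingMode)
  })
}

#' Pipeline seeding call for a simulated or observed CCF case
#'
#' Clusters per-mutation CCF observations, builds the pigeonhole tree and
#' classifies the seeding mode.
#'
#' @param mutations data.frame with \code{ccf_primary} and \code{ccf_met}
#'   per mutation.
#' @param kMax,mergeTol,seed passed to \code{\link{clusterCCF}}.
#' @param tolerance,presenceThreshold passed to \code{\link{buildTree}} and
#'   \code{\link{classifySeeding}}.
#' @return A list with \code{clusters}, \code{tree}, \code{call}.
#' @export
seedingCallFromCCF <- function(mutations, kMax = 8, mergeTol = 0.1,
                               tolerance = 0.1, presenceThreshold = 0.05,
                               seed = 1) {
  clusters <- clusterCCF(vafPrimary = mutations$ccf_primary / 2,
                         vafMet = mutations$ccf_met / 2,
                         purity = c(1, 1), kMax = kMax,
                         mergeTol = mergeTol, seed = seed)
  tree <- suppressWarnings(buildTree(clusters, tolerance = tolerance,
                                     strict = FALSE))
  call <- classifySeeding(tree, presenceThreshold = presenceThreshold)
  list(clusters = clusters, tree = tree, call = call)
}

#' Seeding call from a simulated single-cell case via its bulk VAF table
#'
#' Derives per-mutation CCF pairs from the bulk VAF table of a
#' \code{\link{simulateCase}} output (primary CCF = pooled mean over the
#' primary regions, metastasis CCF from the metastasis tissue column), then
#' applies \code{\link{seedingCallFromCCF}}.
#'
#' @param case a \code{\link{simulateCase}} output.
#' @param metTissue metastasis tissue column to use (default the first).
#' @param ... passed to \code{\link{seedingCallFromCCF}}.
#' @return As \code{\link{seedingCallFromCCF}}.
#' @export
seedingCallFromCase <- function(case, metTissue = NULL, ...) {
  regions <- unique(case$cellData$region)
  regions <- regions[!is.na(regions)]
  mets <- setdiff(colnames(case$bulkVAF), regions)
  if (is.null(metTissue)) metTissue <- mets[1]
  vafP <- rowMeans(case$bulkVAF[, regions, drop = FALSE])
  vafM <- case$bulkVAF[, metTissue]
  mutations <- data.frame(ccf_primary = pmin(1, 2 * vafP),
                          ccf_met = pmin(1, 2 * vafM))
  seedingCallFromCCF(mutations, ...)
}

#' A deterministic ten-patient CCF cluster cohort
#'
#' Ten paired primary/liver-metastasis cluster configurations built to cover
#' the qualitative seeding patterns of small metastatic colon cancer cohorts:
#' four patients with monoclonal configurations (the metastasis-present
#' clusters form a single chain) and six with polyclonal configurations (two
#' metastasis-present branches). The cohort is synthetic and generated in
#' code; patient labels are P1..P10.
#'
#' @return A named list of cluster data.frames, one per patient.
#' @examples
#' cohort <- tenPatientCohort()
#' classifySeeding(buildTree(cohort$P2))$mode
#' @export
tenPatientCohort <- function() {
  mk <- function(...) {
    df <- data.frame(...)
    colnames(df) <- c("cluster", "n_mutations", "ccf_primary", "ccf_met")
    df
  }
  list(
    # monoclonal: metastasis-present clusters form a chain
    P1 = mk(c("A", "B", "C"), c(55, 30, 15), c(1, .55, .40), c(1, .90, .80)),
    P4 = mk(c("A", "B"), c(70, 30), c(1, .45), c(1, .85)),
    P8 = mk(c("A", "B", "C"), c(50, 30, 20), c(1, .60, .30), c(1, .02, .01)),
    P10 = mk(c("A", "B", "C", "D"), c(40, 25, 20, 15),
             c(1, .50, .42, .35), c(1, .95, .88, .80)),
    # polyclonal: two metastasis-present branches
    P2 = mk(c("A", "B", "C"), c(50, 28, 22), c(1, .55, .35), c(1, .60, .35)),
    P3 = mk(c("A", "B", "C"), c(45, 35, 20), c(1, .60, .30), c(1, .55, .40)),
    P5 = mk(c("A", "B", "C", "D"), c(40, 25, 20, 15),
            c(1, .50, .30, .15), c(1, .45, .40, .10)),
    P6 = mk(c("A", "B", "C"), c(60, 22, 18), c(1, .40, .35), c(1, .50, .45)),
    P7 = mk(c("A", "B", "C", "D"), c(35, 30, 20, 15),
            c(1, .55, .25, .12), c(1, .50, .35, .12)),
    P9 = mk(c("A", "B", "C"), c(52, 26, 22), c(1, .45, .40), c(1, .40, .50))
  )
}
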