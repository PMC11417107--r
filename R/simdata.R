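#' @include AllClasses.R
NULL

# path from root to node (inclusive), following the parent map
.ancestorsOrSelf <- function(parent, node) {
  path <- node
  while (!is.na(parent[[node]])) {
    node <- parent[[node]]
    path <- c(node, path)
  }
  path
}

.isAncestorOrSelf <- function(parent, a, b) {
  # TRUE if a is an ancestor of b or a == b
  a %in% .ancestorsOrSelf(parent, b)
}

# uniform random recursive tree: node i attaches to a uniformly chosen
# earlier node; returns a named parent vector with NA at the root
.randomRecursiveTree <- function(nodes) {
  n <- length(nodes)
  parent <- rep(NA_character_, n)
  names(parent) <- nodes
  for (i in seq_len(n)[-1])
    parent[i] <- nodes[sample.int(i - 1L, 1L)]
  parent
}

# clones (by label) whose subtree contains each cell-assignable clone weight;
# prevalence(clone) = sum of weights over the subtree rooted at clone
.subtreePrevalence <- function(parent, weights) {
  nodes <- names(parent)
  prev <- vapply(nodes, function(n) {
    inSub <- vapply(nodes, function(m) .isAncestorOrSelf(parent, n, m),
                    logical(1))
    sum(weights[inSub])
  }, numeric(1))
  names(prev) <- nodes
  prev
}

#' Simulate calls at germline control sites
#'
#' Generates the per-cell call tables at known germline-heterozygous sites and
#' at confident homozygous-reference sites under the operational noise model:
#' at a heterozygous site an allele-dropout event (probability \code{ado})
#' produces a confident homozygous call (reference or alternate allele with
#' equal chance); at a homozygous-reference site a false positive (probability
#' \code{fp}) produces a spurious variant call. Sites with insufficient
#' coverage are emitted as no-calls (\code{NC}) at rate \code{noCallRate}.
#'
#' @param nHet number of germline heterozygous control sites.
#' @param nHom number of homozygous-reference control sites.
#' @param nCells number of cells.
#' @param noise a \linkS4class{NoiseRates}.
#' @param noCallRate probability that a control site yields no confident call.
#' @param seed integer seed.
#' @return A \linkS4class{ControlSites}.
#' @examples
#' cs <- simulateControls(100, 100, 5, NoiseRates(), seed = 1)
#' dim(hetCalls(cs))
#' @export
simulateControls <- function(nHet, nHom, nCells, noise = NoiseRates(),
                             noCallRate = 0.05, seed = 1) {
  withSeed(deriveSeed(seed, "controls"), {
    ado <- adoRate(noise); fp <- fpRate(noise)
    het <- matrix("RA", nHet, nCells)
    u <- matrix(stats::runif(nHet * nCells), nHet, nCells)
    d <- matrix(stats::runif(nHet * nCells), nHet, nCells)
    het[u < ado] <- ifelse(d[u < ado] < 0.5, "RR", "AA")
    nc <- matrix(stats::runif(nHet * nCells), nHet, nCells) < noCallRate
    het[nc] <- "NC"
    hom <- matrix("RR", nHom, nCells)
    u2 <- matrix(stats::runif(nHom * nCells), nHom, nCells)
    hom[u2 < fp] <- "RA"
    nc2 <- matrix(stats::runif(nHom * nCells), nHom, nCells) < noCallRate
    hom[nc2] <- "NC"
    dimnames(het) <- list(paste0("hetctrl", seq_len(nHet)),
                          paste0("cell", seq_len(nCells)))
    dimnames(hom) <- list(paste0("homctrl", seq_len(nHom)),
                          paste0("cell", seq_len(nCells)))
    new("ControlSites", het = het, hom = hom)
  })
}

#' Simulate a complete single-cell exome case
#'
#' Generates the full ground truth of a regionally structured primary tumor
#' with metastases: a clone tree (uniform random recursive topology, private
#' mutation counts multinomial over clones), per-region clone compositions in
#' which two designated source regions harbor the metastasis-seeding clones,
#' mono- or polyclonal seeding of the metastases, per-cell true genotypes,
#' read counts under negative-binomial coverage with allele dropout,
#' false-positive and sequencing-error noise, germline control-site calls, and
#' per-tissue bulk variant-allele-fraction tables.
#'
#' Monoclonal seeding draws every metastatic cell from a single clone (the
#' seeding lineage is one root-to-node chain); polyclonal seeding draws
#' metastatic cells from two clones on distinct branches of the tree (mixing
#' weight uniform in [0.3, 0.7]), and requires \code{nClones >= 3}.
#'
#' In the zero-noise limit (all three rates 0) amplification is ideal: both
#' alleles of a heterozygous site are represented equally in the reads
#' (allelic sampling is treated as part of amplification noise), so observed
#' genotypes equal the truth at every site with depth >= 2.
#'
#' @param nRegions number of primary-tumor regions (the first
#'   \code{min(2, nRegions)} are the metastasis source regions).
#' @param cellsPerRegion cells sampled per primary region.
#' @param nClones number of clones.
#' @param nMutations total number of somatic mutations across clones.
#' @param seedingMode \code{"monoclonal"} or \code{"polyclonal"}.
#' @param noise a \linkS4class{NoiseRates}.
#' @param seed integer master seed; all randomness flows from it through
#'   named substreams.
#' @param metTissues labels of the metastasis tissues.
#' @param cellsPerMet cells sampled per metastasis.
#' @param coverageMean,coverageSize negative-binomial coverage parameters
#'   (mean and dispersion size) per cell-site.
#' @param nHetControls,nHomControls control-site counts for the
#'   \linkS4class{ControlSites} table.
#' @param vafNoiseSd Gaussian noise added to bulk VAFs.
#' @return A list with elements \code{tree} (\linkS4class{CloneTree}),
#'   \code{seeding} (mode, source regions, seeding clones),
#'   \code{truthGenotypes} (sites x cells, \code{"RR"}/\code{"RA"}),
#'   \code{refCounts}/\code{altCounts} (sites x cells integer matrices),
#'   \code{dropout} (logical matrix marking allele-dropout events),
#'   \code{siteData}, \code{cellData}, \code{controls}, \code{bulkVAF}
#'   (sites x tissues), and \code{params}.
#' @examples
#' case <- simulateCase(seed = 1, cellsPerRegion = 4, cellsPerMet = 4)
#' case$seeding$mode
#' @export
simulateCase <- function(nRegions = 4, cellsPerRegion = 10, nClones = 6,
                         nMutations = 117,
                         seedingMode = c("polyclonal", "monoclonal"),
                         noise = NoiseRates(), seed = 1,
                         metTissues = c("liver", "lymph"),
                         cellsPerMet = cellsPerRegion,
                         coverageMean = 30, coverageSize = 3,
                         nHetControls = 2000, nHomControls = 10000,
                         vafNoiseSd = 0.02) {
  seedingMode <- match.arg(seedingMode)
  stopifnot(nRegions >= 1, cellsPerRegion >= 1, nClones >= 1,
            nMutations >= 1)
  if (seedingMode == "polyclonal" && nClones < 3)
    stop("polyclonal seeding requires at least 3 clones ",
         "(no two distinct non-nested branches exist otherwise)")

  clones <- paste0("clone", seq_len(nClones))
  regions <- paste0("region", seq_len(nRegions))
  sourceRegions <- regions[seq_len(min(2L, nRegions))]

  res <- withSeed(deriveSeed(seed, "case"), {
    ## --- clone tree -----------------------------------------------------
    parent <- .randomRecursiveTree(clones)
    if (seedingMode == "polyclonal") {
      hasIncomparable <- function(p) {
        for (a in clones) for (b in clones)
          if (a != b && !.isAncestorOrSelf(p, a, b) &&
              !.isAncestorOrSelf(p, b, a)) return(TRUE)
        FALSE
      }
      tries <- 0L
      while (!hasIncomparable(parent) && tries < 200L) {
        parent <- .randomRecursiveTree(clones)
        tries <- tries + 1L
      }
      if (!hasIncomparable(parent))
        stop("could not draw a branching clone tree")
    }

    ## private mutations per clone: at least one each, rest multinomial
    extra <- nMutations - nClones
    mut <- rep(1L, nClones)
    if (extra > 0)
      mut <- mut + as.integer(stats::rmultinom(1, extra,
                                               rep(1 / nClones, nClones)))
    names(mut) <- clones

    ## --- seeding truth --------------------------------------------------
    if (seedingMode == "monoclonal") {
      target <- sample(clones, 1L)
      seedingClones <- target
      metMix <- stats::setNames(1, target)
    } else {
      pairs <- list()
      for (a in clones) for (b in clones)
        if (a < b && !.isAncestorOrSelf(parent, a, b) &&
            !.isAncestorOrSelf(parent, b, a))
          pairs[[length(pairs) + 1L]] <- c(a, b)
      pick <- sample(pairs[[sample.int(length(pairs), 1L)]])
      seedingClones <- pick
      # unequal lineage contributions: the dominant lineage of a CTC cluster
      # carries 55-80% of the metastasis, keeping the branches identifiable
      u <- stats::runif(1, 0.55, 0.8)
      metMix <- stats::setNames(c(u, 1 - u), pick)
    }

    ## --- per-region clone compositions ---------------------------------
    root <- clones[is.na(parent)]
    others <- setdiff(clones, c(root, seedingClones))
    weights <- matrix(0, nClones, nRegions,
                      dimnames = list(clones, regions))
    dirichlet <- function(n) { g <- stats::rgamma(n, shape = 2); g / sum(g) }
    nonSource <- setdiff(regions, sourceRegions)
    for (r in sourceRegions) {
      weights[root, r] <- 0.2
      if (length(others) && !length(nonSource)) {
        weights[seedingClones, r] <- 0.6 * dirichlet(length(seedingClones))
        weights[others, r] <- 0.2 * dirichlet(length(others))
      } else {
        weights[seedingClones, r] <- 0.8 * dirichlet(length(seedingClones))
      }
    }
    if (length(nonSource)) {
      if (length(others)) {
        assign_to <- rep(seq_along(nonSource), length.out = length(others))
        for (j in seq_along(nonSource)) {
          r <- nonSource[j]
          dom <- others[assign_to == j]
          weights[root, r] <- if (length(dom)) 0.2 else 1
          if (length(dom)) weights[dom, r] <- 0.8 * dirichlet(length(dom))
        }
      } else {
        weights[root, nonSource] <- 1
      }
    }

    ## per-tissue prevalence (subtree sums) -------------------------------
    tissues <- c(regions, metTissues)
    prev <- matrix(0, nClones, length(tissues),
                   dimnames = list(clones, tissues))
    for (r in regions)
      prev[, r] <- .subtreePrevalence(parent, weights[, r])
    metW <- stats::setNames(rep(0, nClones), clones)
    metW[names(metMix)] <- metMix
    for (m in metTissues)
      prev[, m] <- .subtreePrevalence(parent, metW)

    tree <- new("CloneTree", nodes = clones, parent = parent,
                mutationsPerClone = mut, prevalence = prev)

    ## --- cells ----------------------------------------------------------
    cellClone <- character(0); cellTissue <- character(0)
    cellRegion <- character(0)
    for (r in regions) {
      cl <- sample(clones, cellsPerRegion, replace = TRUE, prob = weights[, r])
      # the source regions are sampled because they harbor the seeding
      # lineages: guarantee each seeding clone is represented there
      if (r %in% sourceRegions) {
        head <- seedingClones[seq_len(min(length(seedingClones),
                                          cellsPerRegion))]
        cl[seq_along(head)] <- head
      }
      cellClone <- c(cellClone, cl)
      cellTissue <- c(cellTissue, rep(r, cellsPerRegion))
      cellRegion <- c(cellRegion, rep(r, cellsPerRegion))
    }
    for (m in metTissues) {
      cl <- sample(names(metMix), cellsPerMet, replace = TRUE, prob = metMix)
      cellClone <- c(cellClone, cl)
      cellTissue <- c(cellTissue, rep(m, cellsPerMet))
      cellRegion <- c(cellRegion, rep(NA_character_, cellsPerMet))
    }
    nCells <- length(cellClone)
    cellNames <- paste0("cell", sprintf("%03d", seq_len(nCells)))
    cellData <- data.frame(cell = cellNames, tissue = cellTissue,
                           region = cellRegion, clone = cellClone,
                           stringsAsFactors = FALSE)

    ## --- sites ----------------------------------------------------------
    siteClone <- rep(clones, times = mut)
    nSites <- length(siteClone)
    siteNames <- paste0("site", sprintf("%03d", seq_len(nSites)))
    bases <- c("A", "C", "G", "T")
    refBase <- sample(bases, nSites, replace = TRUE)
    altBase <- vapply(refBase, function(b) sample(setdiff(bases, b), 1L),
                      character(1))
    context <- paste0(sample(bases, nSites, TRUE), refBase,
                      sample(bases, nSites, TRUE))
    genes <- paste0("GENE", seq_len(nSites))
    # one driver-style gene label per clone's first site, mirroring APC/TP53
    genes[match(clones, siteClone)] <-
      paste0("DRIVER", seq_len(nClones))
    siteData <- data.frame(site = siteNames, gene = genes, context = context,
                           ref = refBase, alt = altBase,
                           chrom = "chr1", pos = seq_len(nSites) * 1000L,
                           clone = siteClone, candidate = TRUE,
                           stringsAsFactors = FALSE)

    ## --- truth genotypes ------------------------------------------------
    carries <- matrix(FALSE, nSites, nCells,
                      dimnames = list(siteNames, cellNames))
    pathOf <- lapply(stats::setNames(clones, clones),
                     function(c) .ancestorsOrSelf(parent, c))
    for (j in seq_len(nCells))
      carries[, j] <- siteClone %in% pathOf[[cellClone[j]]]
    truth <- ifelse(carries, "RA", "RR")

    ## --- read counts ----------------------------------------------------
    eps <- seqError(noise); ado <- adoRate(noise); fp <- fpRate(noise)
    n <- matrix(stats::rnbinom(nSites * nCells, mu = coverageMean,
                               size = coverageSize), nSites, nCells)
    zeroNoise <- (ado == 0 && fp == 0 && eps == 0)
    dropout <- matrix(FALSE, nSites, nCells,
                      dimnames = list(siteNames, cellNames))
    if (zeroNoise) {
      alt <- ifelse(carries, n %/% 2L, 0L)
    } else {
      p <- matrix(eps, nSites, nCells)
      u <- matrix(stats::runif(nSites * nCells), nSites, nCells)
      d <- matrix(stats::runif(nSites * nCells), nSites, nCells)
      # heterozygous truth: dropout with prob ado, lost allele uniform
      p[carries] <- ifelse(u[carries] < ado,
                           ifelse(d[carries] < 0.5, eps, 1 - eps),
                           0.5)
      dropout[carries & u < ado] <- TRUE
      # reference truth: false positive with prob fp emits a variant site
      isFP <- !carries & (u < fp)
      p[isFP] <- 0.5
      alt <- matrix(stats::rbinom(nSites * nCells, as.vector(n),
                                  as.vector(p)), nSites, nCells)
    }
    ref <- n - alt
    storage.mode(ref) <- "integer"
    storage.mode(alt) <- "integer"
    dimnames(ref) <- dimnames(alt) <- list(siteNames, cellNames)

    ## --- bulk VAFs ------------------------------------------------------
    bulk <- prev[siteClone, , drop = FALSE] / 2
    bulk <- bulk + matrix(stats::rnorm(length(bulk), 0, vafNoiseSd),
                          nrow(bulk), ncol(bulk))
    bulk <- clamp(bulk, 0, 0.55)
    rownames(bulk) <- siteNames

    list(tree = tree,
         seeding = list(mode = seedingMode, sourceRegions = sourceRegions,
                        seedingClones = seedingClones, metMix = metMix),
         truthGenotypes = truth, refCounts = ref, altCounts = alt,
         dropout = dropout,
         siteData = siteData, cellData = cellData, bulkVAF = bulk)
  })

  res$controls <- simulateControls(nHetControls, nHomControls,
                                   nrow(res$cellData), noise,
                                   seed = deriveSeed(seed, "case-controls"))
  colnames(res$controls@het) <- res$cellData$cell
  colnames(res$controls@hom) <- res$cellData$cell
  res$params <- list(nRegions = nRegions, cellsPerRegion = cellsPerRegion,
                     nClones = nClones, nMutations = nMutations,
                     seedingMode = seedingMode, seed = seed,
                     ado = adoRate(noise), fp = fpRate(noise),
                     seqError = seqError(noise),
                     coverageMean = coverageMean, coverageSize = coverageSize)
  res
}

#' Simulate a paired primary/metastasis expression case
#'
#' Generates a primary expression matrix with planted cluster structure, a
#' metastasis matrix whose cells are drawn from a recorded subset of primary
#' clusters (two designated high-contribution clusters receive most of the
#' metastatic cells), an EMT gene set whose genes are shifted upward by
#' \code{emtEffect} in the high-contribution clusters, and a per-cell CNV
#' region matrix centered on baseline 1 in which high-contribution clusters
#' carry larger copy-number deviations.
#'
#' @param nClusters number of primary clusters.
#' @param cellsPerCluster cells per primary cluster.
#' @param nMetCells number of metastasis cells.
#' @param nGenes size of the gene universe.
#' @param nEmtGenes number of genes in the EMT set (must not exceed
#'   \code{nGenes}).
#' @param emtEffect non-negative shift added to the mean expression of EMT
#'   genes in high-contribution clusters.
#' @param cnvProfile \code{"planted"} for cluster-specific deviations, or
#'   \code{"neutral"} for a constant-baseline CNV matrix.
#' @param nCnvRegions number of CNV regions.
#' @param seed integer seed.
#' @return A list with \code{primary} (genes x cells), \code{primaryClusters},
#'   \code{metastasis} (genes x cells), \code{emtGenes}, \code{cnv}
#'   (cells x regions, primary and metastasis cells), \code{truth}
#'   (data.frame: metastasis cell, source cluster), and
#'   \code{highClusters}.
#' @examples
#' ec <- simulateExpressionCase(nClusters = 3, cellsPerCluster = 10,
#'                              nMetCells = 10, nGenes = 100, seed = 1)
#' nrow(ec$truth)
#' @export
simulateExpressionCase <- function(nClusters = 8, cellsPerCluster = 50,
                                   nMetCells = 150, nGenes = 1000,
                                   nEmtGenes = 50, emtEffect = 1,
                                   cnvProfile = c("planted", "neutral"),
                                   nCnvRegions = 20, seed = 1) {
  cnvProfile <- match.arg(cnvProfile)
  stopifnot(emtEffect >= 0, nClusters >= 1)
  if (nEmtGenes > nGenes)
    stop("EMT gene set cannot be larger than the gene universe")
  withSeed(deriveSeed(seed, "expression"), {
    genes <- paste0("gene", seq_len(nGenes))
    emtGenes <- genes[seq_len(nEmtGenes)]
    clusters <- paste0("cluster", seq_len(nClusters))
    highClusters <- clusters[seq_len(min(2L, nClusters))]

    # base means and cluster-specific marker programs
    base <- stats::rgamma(nGenes, shape = 2, rate = 0.5)
    names(base) <- genes
    nonEmt <- setdiff(genes, emtGenes)
    markerPool <- sample(nonEmt)
    perCluster <- max(1L, min(40L, length(markerPool) %/% nClusters))
    mu <- matrix(base, nGenes, nClusters, dimnames = list(genes, clusters))
    for (k in seq_len(nClusters)) {
      mk <- markerPool[((k - 1) * perCluster + 1):(k * perCluster)]
      mu[mk, k] <- mu[mk, k] * 4
    }
    mu[emtGenes, highClusters] <- mu[emtGenes, highClusters] + emtEffect

    drawCells <- function(cl, n) {
      m <- matrix(stats::rpois(nGenes * n, mu[, cl]), nGenes, n)
      rownames(m) <- genes
      m
    }
    primary <- do.call(cbind, lapply(clusters, drawCells,
                                     n = cellsPerCluster))
    colnames(primary) <- paste0("p", seq_len(ncol(primary)))
    primaryClusters <- stats::setNames(rep(clusters, each = cellsPerCluster),
                                       colnames(primary))

    # metastasis cells mostly from the high-contribution clusters
    w <- stats::setNames(rep(0.3 / max(1, nClusters - length(highClusters)),
                             nClusters), clusters)
    w[highClusters] <- 0.7 / length(highClusters)
    if (nClusters <= length(highClusters)) w[] <- 1 / nClusters
    src <- sample(clusters, nMetCells, replace = TRUE, prob = w)
    metastasis <- do.call(cbind, lapply(src, drawCells, n = 1L))
    colnames(metastasis) <- paste0("m", seq_len(nMetCells))
    truth <- data.frame(cell = colnames(metastasis), sourceCluster = src,
                        stringsAsFactors = FALSE)

    # CNV region matrix over all cells, baseline 1
    allCells <- c(colnames(primary), colnames(metastasis))
    cellCl <- c(primaryClusters, stats::setNames(src, colnames(metastasis)))
    cnv <- matrix(1, length(allCells), nCnvRegions,
                  dimnames = list(allCells,
                                  paste0("regionchr", seq_len(nCnvRegions))))
    if (cnvProfile == "planted") {
      dev <- matrix(0, nClusters, nCnvRegions,
                    dimnames = list(clusters, NULL))
      for (k in seq_len(nClusters)) {
        amp <- if (clusters[k] %in% highClusters) 0.4 else 0.1
        hit <- sample.int(nCnvRegions, max(2L, nCnvRegions %/% 4L))
        dev[k, hit] <- amp * sample(c(-1, 1), length(hit), TRUE)
      }
      cnv <- cnv + dev[cellCl[allCells], , drop = FALSE] +
        matrix(stats::rnorm(length(cnv), 0, 0.02), nrow(cnv), ncol(cnv))
    }

    list(primary = primary, primaryClusters = primaryClusters,
         metastasis = metastasis, emtGenes = emtGenes, cnv = cnv,
         truth = truth, highClusters = highClusters,
         params = list(nClusters = nClusters, emtEffect = emtEffect,
                       cnvProfile = cnvProfile, seed = seed))
  })
}

#' Write a simulated case to a fixture directory
#'
#' Writes the plain-text fixture files \code{genotypes.tsv} (long format:
#' cell, site, ref_count, alt_count), \code{sites.tsv}, \code{cells.tsv},
#' \code{controls.tsv}, \code{bulk_vaf.tsv}, \code{truth_genotypes.tsv},
#' \code{truth.json} (tree and seeding truth) and \code{manifest.json}
#' (seeds and parameters). \code{\link{readFixture}} reconstructs the case
#' exactly.
#'
#' @param case a list from \code{\link{simulateCase}}.
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return \code{dir}, invisibly.
#' @examples
#' case <- simulateCase(seed = 1, cellsPerRegion = 3, cellsPerMet = 3,
#'                      nHetControls = 10, nHomControls = 10)
#' d <- file.path(tempdir(), "fx")
#' writeFixture(case, d, overwrite = TRUE)
#' @export
writeFixture <- function(case, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  long <- data.frame(
    cell = rep(colnames(case$refCounts), each = nrow(case$refCounts)),
    site = rep(rownames(case$refCounts), ncol(case$refCounts)),
    ref_count = as.vector(case$refCounts),
    alt_count = as.vector(case$altCounts))
  wtsv(long, "genotypes.tsv")
  wtsv(case$siteData, "sites.tsv")
  wtsv(case$cellData, "cells.tsv")
  het <- case$controls@het; hom <- case$controls@hom
  ctrl <- rbind(
    if (length(het)) data.frame(
      cell = rep(colnames(het), each = nrow(het)),
      site = rep(rownames(het), ncol(het)),
      type = "het", call = as.vector(het)),
    if (length(hom)) data.frame(
      cell = rep(colnames(hom), each = nrow(hom)),
      site = rep(rownames(hom), ncol(hom)),
      type = "hom", call = as.vector(hom)))
  if (is.null(ctrl))
    ctrl <- data.frame(cell = character(0), site = character(0),
                       type = character(0), call = character(0))
  wtsv(ctrl, "controls.tsv")
  bv <- data.frame(site = rownames(case$bulkVAF), case$bulkVAF,
                   check.names = FALSE)
  wtsv(bv, "bulk_vaf.tsv")
  tg <- data.frame(site = rownames(case$truthGenotypes),
                   case$truthGenotypes, check.names = FALSE)
  wtsv(tg, "truth_genotypes.tsv")
  tree <- case$tree
  truth <- list(
    tree = list(nodes = tree@nodes,
                parent = as.list(tree@parent),
                mutationsPerClone = as.list(tree@mutationsPerClone),
                prevalence = lapply(as.data.frame(tree@prevalence),
                                    identity)),
    seeding = case$seeding)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(case$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by writeFixture
#'
#' @param dir fixture directory.
#' @return A case list with the same structure as
#'   \code{\link{simulateCase}} output.
#' @export
readFixture <- function(dir) {
  rtsv <- function(f)
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
  long <- rtsv("genotypes.tsv")
  siteData <- rtsv("sites.tsv")
  cellData <- rtsv("cells.tsv")
  sites <- siteData$site; cells <- cellData$cell
  mk <- function(v) {
    m <- matrix(v[order(match(long$cell, cells), match(long$site, sites))],
                length(sites), length(cells),
                dimnames = list(sites, cells))
    m
  }
  ref <- mk(long$ref_count); alt <- mk(long$alt_count)
  ctrl <- rtsv("controls.tsv")
  mkCtrl <- function(type) {
    sub <- ctrl[ctrl$type == type, , drop = FALSE]
    if (!nrow(sub)) return(matrix(character(0), 0, length(cells)))
    ss <- unique(sub$site)
    matrix(sub$call[order(match(sub$cell, cells), match(sub$site, ss))],
           length(ss), length(cells), dimnames = list(ss, cells))
  }
  controls <- new("ControlSites", het = mkCtrl("het"), hom = mkCtrl("hom"))
  bv <- rtsv("bulk_vaf.tsv")
  bulk <- as.matrix(bv[, -1, drop = FALSE]); rownames(bulk) <- bv$site
  tg <- rtsv("truth_genotypes.tsv")
  truthG <- as.matrix(tg[, -1, drop = FALSE]); rownames(truthG) <- tg$site
  tj <- jsonlite::read_json(file.path(dir, "truth.json"))
  nodes <- unlist(tj$tree$nodes)
  parent <- vapply(tj$tree$parent,
                   function(p) if (is.null(p)) NA_character_ else p,
                   character(1))[nodes]
  names(parent) <- nodes
  mut <- vapply(tj$tree$mutationsPerClone, as.integer, integer(1))[nodes]
  names(mut) <- nodes
  prev <- matrix(unlist(lapply(tj$tree$prevalence, unlist)),
                 nrow = length(nodes),
                 dimnames = list(nodes, names(tj$tree$prevalence)))
  tree <- new("CloneTree", nodes = nodes, parent = parent,
              mutationsPerClone = mut, prevalence = prev)
  seeding <- tj$seeding
  seeding$seedingClones <- unlist(seeding$seedingClones)
  seeding$sourceRegions <- unlist(seeding$sourceRegions)
  seeding$metMix <- unlist(seeding$metMix)
  params <- lapply(jsonlite::read_json(file.path(dir, "manifest.json")),
                   function(x) if (is.list(x)) unlist(x) else x)
  list(tree = tree, seeding = seeding, truthGenotypes = truthG,
       refCounts = ref, altCounts = alt, siteData = siteData,
       cellData = cellData, controls = controls, bulkVAF = bulk,
       params = params)
}
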