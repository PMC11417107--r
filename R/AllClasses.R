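#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList
NULL

#' Noise parameters of single-cell whole-genome-amplified exome data
#'
#' Container for the three noise rates shared by the synthetic-data generator
#' and the genotype model: the allele-dropout probability (\code{ado}, the
#' chance that one allele of a truly heterozygous site contributes no reads
#' after amplification), the per-site false-positive call probability
#' (\code{fp}, a spurious variant emitted at a truly homozygous-reference
#' site), and the per-read sequencing error (\code{seqError}).
#'
#' @slot ado numeric in [0,1]; allele dropout probability.
#' @slot fp numeric in [0,1]; per-site false-positive probability.
#' @slot seqError numeric in [0,1]; per-read base error.
#' @export
setClass("NoiseRates",
  representation(ado = "numeric", fp = "numeric", seqError = "numeric"))

setValidity("NoiseRates", function(object) {
  v <- c(object@ado, object@fp, object@seqError)
  if (length(object@ado) != 1L || length(object@fp) != 1L ||
      length(object@seqError) != 1L)
    return("ado, fp and seqError must each be a single value")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("all rates must be finite and in [0, 1]")
  TRUE
})

#' Construct a NoiseRates object
#'
#' Defaults are the cohort medians/means of the motivating single-cell exome
#' study design: a median ADO rate of 10.3\%, an average false-positive rate
#' of 2.68e-6, and a per-read sequencing error of 0.5\%.
#'
#' @param ado allele dropout probability in [0,1].
#' @param fp per-site false-positive probability in [0,1].
#' @param seqError per-read sequencing error in [0,1].
#' @return A \linkS4class{NoiseRates} object.
#' @examples
#' NoiseRates(ado = 0.103, fp = 2.68e-6)
#' @export
NoiseRates <- function(ado = 0.103, fp = 2.68e-6, seqError = 0.005) {
  new("NoiseRates", ado = ado, fp = fp, seqError = seqError)
}

setMethod("show", "NoiseRates", function(object) {
  cat("NoiseRates: ado =", object@ado, ", fp =", object@fp,
      ", seqError =", object@seqError, "\n")
})

#' Per-cell mutation status matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the determined mutation status
#' of every candidate site (rows) in every single cell (columns). The
#' \code{status} assay takes values \code{MUT}, \code{WT} or \code{CND}
#' (cannot determine, from insufficient coverage or posterior confidence); an
#' optional \code{zygosity} assay carries \code{RR}, \code{RA}, \code{AA} or
#' \code{unknown}. Column data carry the \code{tissue} (and optionally
#' \code{region}) of each cell; row data may carry the \code{gene} of each
#' site.
#'
#' @export
setClass("StatusMatrix", contains = "SummarizedExperiment")

setValidity("StatusMatrix", function(object) {
  if (!"status" %in% assayNames(object))
    return("a 'status' assay is required")
  st <- assay(object, "status")
  if (!all(st %in% .STATUS_LEVELS))
    return("status values must be MUT, WT or CND")
  if (!"tissue" %in% colnames(colData(object)))
    return("colData must contain a 'tissue' column")
  if ("zygosity" %in% assayNames(object)) {
    zy <- assay(object, "zygosity")
    if (!all(zy %in% c("RR", "RA", "AA", "unknown")))
      return("zygosity values must be RR, RA, AA or unknown")
    if (!all((st == "CND") == (zy == "unknown")))
      return("status CND must coincide with zygosity 'unknown'")
    if (!all((st == "MUT") == (zy %in% c("RA", "AA"))))
      return("status MUT must coincide with zygosity RA or AA")
  }
  TRUE
})

#' Construct a StatusMatrix
#'
#' @param status character matrix (sites x cells) with values MUT/WT/CND.
#' @param tissue character vector of per-cell tissue labels.
#' @param region optional character vector of per-cell region labels.
#' @param gene optional character vector of per-site gene labels.
#' @param zygosity optional character matrix (sites x cells) with values
#'   RR/RA/AA/unknown, consistent with \code{status}.
#' @return A \linkS4class{StatusMatrix}.
#' @examples
#' st <- matrix(c("MUT", "WT", "CND", "MUT"), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("c1", "c2")))
#' StatusMatrix(st, tissue = c("primary", "liver"))
#' @export
StatusMatrix <- function(status, tissue, region = NULL, gene = NULL,
                         zygosity = NULL) {
  status <- as.matrix(status)
  if (is.null(rownames(status)))
    rownames(status) <- paste0("site", seq_len(nrow(status)))
  if (is.null(colnames(status)))
    colnames(status) <- paste0("cell", seq_len(ncol(status)))
  cd <- DataFrame(tissue = as.character(tissue), row.names = colnames(status))
  if (!is.null(region)) cd$region <- as.character(region)
  rd <- DataFrame(row.names = rownames(status))
  if (!is.null(gene)) rd$gene <- as.character(gene)
  assays <- SimpleList(status = status)
  if (!is.null(zygosity)) {
    zygosity <- as.matrix(zygosity)
    dimnames(zygosity) <- dimnames(status)
    assays$zygosity <- zygosity
  }
  new("StatusMatrix",
      SummarizedExperiment(assays = assays, colData = cd, rowData = rd))
}

setMethod("show", "StatusMatrix", function(object) {
  st <- assay(object, "status")
  cat("StatusMatrix:", nrow(object), "sites x", ncol(object), "cells\n")
  cat("  tissues:", paste(unique(colData(object)$tissue), collapse = ", "), "\n")
  tab <- table(factor(st, levels = .STATUS_LEVELS))
  cat("  status: MUT", tab[["MUT"]], "| WT", tab[["WT"]],
      "| CND", tab[["CND"]], "\n")
})

#' Clone tree with per-tissue clone prevalences
#'
#' Rooted tree over clones, the number of private mutations of each clone, and
#' the prevalence (fraction of cells whose clone lies in the subtree of a
#' clone) of each clone in each tissue. Prevalences satisfy the pigeonhole
#' constraint: within every tissue, the prevalence of a parent is at least the
#' sum of the prevalences of its children.
#'
#' @slot nodes character vector of clone identifiers.
#' @slot parent named character vector mapping each clone to its parent
#'   (\code{NA} for the root).
#' @slot mutationsPerClone named integer vector of private mutation counts.
#' @slot prevalence numeric matrix, clones x tissues, entries in [0,1].
#' @export
setClass("CloneTree",
  representation(nodes = "character", parent = "character",
                 mutationsPerClone = "integer", prevalence = "matrix"))

setValidity("CloneTree", function(object) {
  nd <- object@nodes
  pa <- object@parent
  if (!identical(sort(names(pa)), sort(nd)))
    return("parent must be named by every node")
  roots <- nd[is.na(pa[nd])]
  if (length(roots) != 1L) return("exactly one root is required")
  if (!all(pa[!is.na(pa)] %in% nd)) return("parents must be nodes")
  if (any(object@mutationsPerClone < 0L))
    return("mutation counts must be >= 0")
  pv <- object@prevalence
  if (!identical(rownames(pv), nd))
    return("prevalence rows must match nodes")
  if (any(pv < -1e-9 | pv > 1 + 1e-9))
    return("prevalences must lie in [0, 1]")
  for (tis in colnames(pv)) {
    for (n in nd) {
      kids <- nd[!is.na(pa[nd]) & pa[nd] == n]
      if (length(kids) && sum(pv[kids, tis]) > pv[n, tis] + 1e-6)
        return(sprintf(
          "pigeonhole violation at node %s in tissue %s", n, tis))
    }
  }
  TRUE
})

setMethod("show", "CloneTree", function(object) {
  cat("CloneTree:", length(object@nodes), "clones,",
      sum(object@mutationsPerClone), "mutations,",
      ncol(object@prevalence), "tissues\n")
})

#' Control-site call tables for noise-rate estimation
#'
#' Calls of every cell at known germline-heterozygous control sites
#' (\code{het}) and at confident homozygous-reference sites (\code{hom}).
#' Calls are \code{RR}, \code{RA}, \code{AA} or \code{NC} (no call). Control
#' sites are disjoint from somatic candidate sites by construction.
#'
#' @slot het character matrix (het control sites x cells).
#' @slot hom character matrix (hom-ref control sites x cells).
#' @export
setClass("ControlSites",
  representation(het = "matrix", hom = "matrix"))

setValidity("ControlSites", function(object) {
  if (length(object@het) && !all(object@het %in% .CALL_LEVELS))
    return("het calls must be RR, RA, AA or NC")
  if (length(object@hom) && !all(object@hom %in% .CALL_LEVELS))
    return("hom calls must be RR, RA, AA or NC")
  if (length(object@het) && length(object@hom) &&
      ncol(object@het) != ncol(object@hom))
    return("het and hom tables must cover the same cells")
  TRUE
})

setMethod("show", "ControlSites", function(object) {
  cat("ControlSites:", nrow(object@het), "het +", nrow(object@hom),
      "hom-ref sites x", ncol(object@het), "cells\n")
})

#' A mutational-signature factorization at a fixed rank
#'
#' @slot k integer, number of signatures.
#' @slot signatures numeric 96 x k matrix; columns sum to 1.
#' @slot exposures numeric k x samples matrix, non-negative.
#' @slot stability numeric vector of length k; per-signature mean silhouette
#'   of the bootstrap signature clusters, in [-1, 1].
#' @slot frobeniusError numeric; Frobenius reconstruction error on the
#'   original catalog.
#' @export
setClass("SignatureSolution",
  representation(k = "integer", signatures = "matrix", exposures = "matrix",
                 stability = "numeric", frobeniusError = "numeric"))

setValidity("SignatureSolution", function(object) {
  if (nrow(object@signatures) != 96L) return("signatures must have 96 rows")
  if (ncol(object@signatures) != object@k) return("k mismatch")
  cs <- colSums(object@signatures)
  if (any(abs(cs - 1) > 1e-9)) return("signature columns must sum to 1")
  if (any(object@exposures < -1e-12)) return("exposures must be non-negative")
  if (length(object@stability) != object@k)
    return("stability must hold one value per signature")
  if (any(object@stability < -1 - 1e-9 | object@stability > 1 + 1e-9))
    return("stability values must lie in [-1, 1]")
  TRUE
})

setMethod("show", "SignatureSolution", function(object) {
  cat("SignatureSolution: K =", object@k,
      "| min stability =", round(min(object@stability), 3),
      "| Frobenius error =", round(object@frobeniusError, 3), "\n")
})
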