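#' @include AllClasses.R
NULL

#' Accessors for scClonality classes
#'
#' \code{adoRate}, \code{fpRate} and \code{seqError} return the components of
#' a \linkS4class{NoiseRates} object. \code{statusCalls} and
#' \code{zygosityCalls} return the assay matrices of a
#' \linkS4class{StatusMatrix}; \code{cellTissue} and \code{cellRegion} its
#' per-cell labels; \code{siteGene} its per-site gene labels.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot or assay.
#' @name accessors
#' @examples
#' adoRate(NoiseRates())
NULL

#' @rdname accessors
#' @export
setGeneric("adoRate", function(x) standardGeneric("adoRate"))
#' @rdname accessors
#' @export
setGeneric("fpRate", function(x) standardGeneric("fpRate"))
#' @rdname accessors
#' @export
setGeneric("seqError", function(x) standardGeneric("seqError"))
#' @rdname accessors
#' @export
setGeneric("statusCalls", function(x) standardGeneric("statusCalls"))
#' @rdname accessors
#' @export
setGeneric("zygosityCalls", function(x) standardGeneric("zygosityCalls"))
#' @rdname accessors
#' @export
setGeneric("cellTissue", function(x) standardGeneric("cellTissue"))
#' @rdname accessors
#' @export
setGeneric("cellRegion", function(x) standardGeneric("cellRegion"))
#' @rdname accessors
#' @export
setGeneric("siteGene", function(x) standardGeneric("siteGene"))
#' @rdname accessors
#' @export
setGeneric("hetCalls", function(x) standardGeneric("hetCalls"))
#' @rdname accessors
#' @export
setGeneric("homCalls", function(x) standardGeneric("homCalls"))

#' @rdname accessors
#' @export
setMethod("adoRate", "NoiseRates", function(x) x@ado)
#' @rdname accessors
#' @export
setMethod("fpRate", "NoiseRates", function(x) x@fp)
#' @rdname accessors
#' @export
setMethod("seqError", "NoiseRates", function(x) x@seqError)

#' @rdname accessors
#' @export
setMethod("statusCalls", "StatusMatrix", function(x) assay(x, "status"))
#' @rdname accessors
#' @export
setMethod("zygosityCalls", "StatusMatrix", function(x) {
  if (!"zygosity" %in% assayNames(x)) return(NULL)
  assay(x, "zygosity")
})
#' @rdname accessors
#' @export
setMethod("cellTissue", "StatusMatrix", function(x) {
  stats::setNames(colData(x)$tissue, colnames(x))
})
#' @rdname accessors
#' @export
setMethod("cellRegion", "StatusMatrix", function(x) {
  if (!"region" %in% colnames(colData(x))) return(NULL)
  stats::setNames(colData(x)$region, colnames(x))
})
#' @rdname accessors
#' @export
setMethod("siteGene", "StatusMatrix", function(x) {
  if (!"gene" %in% colnames(rowData(x))) return(NULL)
  stats::setNames(rowData(x)$gene, rownames(x))
})
#' @rdname accessors
#' @export
setMethod("hetCalls", "ControlSites", function(x) x@het)
#' @rdname accessors
#' @export
setMethod("homCalls", "ControlSites", function(x) x@hom)
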