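#' @include AllClasses.R
NULL

#' Estimate per-cell false-positive rates from homozygous control sites
#'
#' Confident homozygous-reference sites from tissue sequencing serve as
#' controls: any non-reference call at such a site in a single cell is a false
#' positive. The per-cell rate is the number of non-reference calls divided by
#' the number of control sites with a confident call (no-calls, encoding sites
#' below the depth/posterior thresholds, are excluded from the denominator).
#' The cohort value is the mean over cells with at least one informative site.
#'
#' @param controls a \linkS4class{ControlSites}.
#' @return A list with \code{perCell} (data.frame: cell, rate, nInformative;
#'   rate is \code{NA} for cells without informative sites) and \code{cohort}
#'   (mean rate).
#' @examples
#' cs <- simulateControls(10, 1000, 5, NoiseRates(fp = 1e-3), seed = 1)
#' estimateFPRate(cs)$cohort
#' @export
estimateFPRate <- function(controls) {
  calls <- homCalls(controls)
  if (!length(calls)) stop("no homozygous-reference control sites")
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("cell", seq_len(ncol(calls)))
  informative <- calls != "NC"
  nonref <- informative & calls != "RR"
  nInf <- colSums(informative)
  rate <- ifelse(nInf > 0, colSums(nonref) / nInf, NA_real_)
  if (all(nInf == 0))
    stop("no cell has informative homozygous control sites")
  perCell <- data.frame(cell = colnames(calls), rate = rate,
                        nInformative = nInf, row.names = NULL)
  list(perCell = perCell, cohort = mean(rate, na.rm = TRUE))
}

#' Estimate per-cell allele-dropout rates from heterozygous control sites
#'
#' Known germline heterozygous SNP sites serve as controls: a confident
#' homozygous call (either allele) at such a site in a single cell is an
#' allele-dropout (ADO) event. The per-cell rate is the number of confident
#' homozygous calls divided by the number of heterozygous control sites with a
#' confident call; no-calls are excluded from the denominator. The cohort
#' value is the median over cells with at least one informative site.
#'
#' @param controls a \linkS4class{ControlSites}.
#' @return A list with \code{perCell} (data.frame: cell, rate, nInformative)
#'   and \code{cohort} (median rate).
#' @examples
#' cs <- simulateControls(2000, 10, 5, NoiseRates(ado = 0.103), seed = 1)
#' estimateADORate(cs)$cohort
#' @export
estimateADORate <- function(controls) {
  calls <- hetCalls(controls)
  if (!length(calls)) stop("no heterozygous control sites")
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("cell", seq_len(ncol(calls)))
  informative <- calls != "NC"
  homcall <- calls %in% c("RR", "AA") & informative
  dim(homcall) <- dim(calls)
  nInf <- colSums(informative)
  rate <- ifelse(nInf > 0, colSums(homcall) / nInf, NA_real_)
  if (all(nInf == 0))
    stop("no cell has informative heterozygous control sites")
  perCell <- data.frame(cell = colnames(calls), rate = rate,
                        nInformative = nInf, row.names = NULL)
  list(perCell = perCell, cohort = stats::median(rate, na.rm = TRUE))
}
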