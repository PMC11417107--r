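#' @include AllClasses.R
NULL

#' Run the full clonality analysis pipeline
#'
#' Orchestrates the analysis stages in dependency order on a simulated case
#' (or a fixture directory written by \code{\link{writeFixture}}): noise-rate
#' estimation from control sites, genotyping into a status matrix, tissue
#' heterogeneity, origin tracing of metastatic cells, mutational-signature
#' extraction from the per-cell mutation catalog, the pigeonhole seeding
#' call, expression scores on a paired expression case, and the clinical
#' contingency tests. Every threshold left open by convention is echoed in
#' the report; re-running with the same config reproduces all numeric fields
#' exactly.
#'
#' @param config a list; recognised fields: \code{seed} (mandatory),
#'   \code{stages} (subset of \code{c("sim", "rates", "genotype", "het",
#'   "trace", "signatures", "phylo", "scrna", "cohort")}), \code{fixtureDir}
#'   (read the case from disk instead of simulating), \code{case} (use an
#'   in-memory case), \code{caseParams} (passed to
#'   \code{\link{simulateCase}}), \code{minDepth}, \code{minPosterior},
#'   \code{callableMb}, \code{kRange}, \code{nResamples}, \code{nInits}.
#' @return A \code{RunReport} list: \code{config} (with all defaults
#'   resolved) and one entry per executed stage.
#' @export
runPipeline <- function(config) {
  if (is.null(config[["seed"]])) stop("config$seed is mandatory")
  defaults <- list(
    stages = c("sim", "rates", "genotype", "het", "trace", "phylo",
               "signatures", "scrna", "cohort"),
    caseParams = list(), minDepth = 5, minPosterior = 0.95,
    callableMb = 47, kRange = 1:4, nResamples = 10, nInits = 4,
    minInformative = 5, presenceThreshold = 0.05)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stages <- config$stages
  report <- list(config = config)

  case <- config[["case"]]
  if (is.null(case) && !is.null(config[["fixtureDir"]])) {
    if (!dir.exists(config[["fixtureDir"]]))
      stop("stage 'sim': fixture directory not found: ",
           config[["fixtureDir"]])
    case <- readFixture(config[["fixtureDir"]])
  }
  if (is.null(case) && "sim" %in% stages)
    case <- do.call(simulateCase,
                    c(config$caseParams, list(seed = config$seed)))
  needCase <- intersect(stages,
                        c("rates", "genotype", "het", "trace", "phylo",
                          "signatures"))
  if (length(needCase) && is.null(case))
    stop("stage '", needCase[1], "' needs a case: provide config$case, ",
         "config$fixtureDir, or include 'sim' in stages")

  if ("rates" %in% stages) {
    report$rates <- list(fp = estimateFPRate(case$controls)$cohort,
                         ado = estimateADORate(case$controls)$cohort)
  }
  status <- NULL
  if (any(c("genotype", "het", "trace") %in% stages)) {
    noise <- NoiseRates(ado = case$params$ado %||% 0.103,
                        fp = case$params$fp %||% 2.68e-6,
                        seqError = case$params$seqError %||% 0.005)
    status <- genotypeCase(case$refCounts, case$altCounts,
                           tissue = case$cellData$tissue,
                           region = case$cellData$region,
                           gene = case$siteData$gene, noise = noise,
                           minDepth = config$minDepth,
                           minPosterior = config$minPosterior)
    report$genotype <- list(
      statusSummary = table(statusCalls(status)),
      burden = mutationBurden(status, config$callableMb))
  }
  if ("het" %in% stages)
    report$heterogeneity <- tissueHeterogeneity(status)
  if ("trace" %in% stages) {
    mets <- setdiff(unique(case$cellData$tissue),
                    unique(stats::na.omit(case$cellData$region)))
    report$trace <- lapply(stats::setNames(mets, mets), function(m)
      traceOrigin(status, m, minInformative = config$minInformative,
                  sourceRegions = case$seeding$sourceRegions))
  }
  if ("phylo" %in% stages)
    report$phylo <- seedingCallFromCase(
      case, presenceThreshold = config$presenceThreshold,
      seed = config$seed)
  if ("signatures" %in% stages) {
    st <- statusCalls(status %||% genotypeCase(
      case$refCounts, case$altCounts, tissue = case$cellData$tissue))
    idx <- which(st == "MUT", arr.ind = TRUE)
    muts <- data.frame(sample = colnames(st)[idx[, 2]],
                       ref = case$siteData$ref[idx[, 1]],
                       alt = case$siteData$alt[idx[, 1]],
                       context = case$siteData$context[idx[, 1]])
    catalog <- build96Catalog(muts)
    report$signatures <- extractSignatures(
      catalog, kRange = config$kRange, nResamples = config$nResamples,
      nInits = config$nInits, seed = config$seed)[c("selectedK",
                                                    "selection")]
  }
  if ("scrna" %in% stages) {
    ec <- simulateExpressionCase(seed = config$seed)
    sc <- scoreExpressionCase(ec, seed = config$seed)
    report$scrna <- sc[c("mc", "regression", "accuracy")]
  }
  if ("cohort" %in% stages)
    report$cohort <- stageAssociationTests(clinicalStageTable())
  class(report) <- c("RunReport", class(report))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Schema and coordinate diagnostics for a fixture directory: status
#' vocabulary, 1-based positions, non-negative read counts, control call
#' vocabulary. Diagnostics only; never raises an error.
#'
#' @param dir fixture directory.
#' @return data.frame with columns \code{file} and \code{message}; zero rows
#'   when everything validates.
#' @export
validateInputs <- function(dir) {
  diags <- list()
  note <- function(file, message)
    diags[[length(diags) + 1]] <<- data.frame(file = file,
                                              message = message)
  tryRead <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) { note(f, "file missing"); return(NULL) }
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  g <- tryRead("genotypes.tsv")
  if (!is.null(g)) {
    if (!all(c("cell", "site", "ref_count", "alt_count") %in% colnames(g)))
      note("genotypes.tsv", "missing required columns")
    else if (any(g$ref_count < 0) || any(g$alt_count < 0))
      note("genotypes.tsv", "negative read counts")
  }
  s <- tryRead("sites.tsv")
  if (!is.null(s) && "pos" %in% colnames(s) && any(s$pos < 1))
    note("sites.tsv",
         paste("positions must be 1-based; offending lines:",
               paste(utils::head(which(s$pos < 1), 5), collapse = ", ")))
  ctrl <- tryRead("controls.tsv")
  if (!is.null(ctrl) && "call" %in% colnames(ctrl)) {
    bad <- !ctrl$call %in% .CALL_LEVELS
    if (any(bad))
      note("controls.tsv",
           paste("unknown call token(s) at lines:",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  if (!length(diags))
    return(data.frame(file = character(0), message = character(0)))
  do.call(rbind, diags)
}
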