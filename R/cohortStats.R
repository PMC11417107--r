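#' @include AllClasses.R
NULL

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of independence given both margins. The two-sided
#' p-value follows the minimum-likelihood rule of standard statistical
#' packages: the sum of hypergeometric probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7).
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param midP halve the probability of the observed table (mid-p variant).
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(53, 1, 46, 7), 2, 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(tab, midP = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("entries must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin; p = 1 by convention")
    return(1)
  }
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(tab[1, 1], m, n, k)
  sel <- probs <= pObs * (1 + 1e-7)
  p <- sum(probs[sel])
  if (midP) p <- p - 0.5 * pObs
  min(1, p)
}

# recursive enumeration of all r x c tables with the given margins,
# accumulating log-probabilities; used by fisherExactRxC
.enumerateTables <- function(rowSums, colSums, fun) {
  r <- length(rowSums)
  rec <- function(i, remaining, acc) {
    if (i == r) {
      if (any(remaining < 0)) return(invisible())
      fun(rbind(acc, remaining))
      return(invisible())
    }
    # enumerate compositions of rowSums[i] into length(colSums) cells,
    # bounded by the remaining column totals
    cells <- length(remaining)
    comp <- function(j, left, row) {
      if (j == cells) {
        if (left <= remaining[j]) rec(i + 1L, remaining - c(row, left),
                                      rbind(acc, c(row, left)))
        return(invisible())
      }
      for (x in 0:min(left, remaining[j]))
        comp(j + 1L, left - x, c(row, x))
    }
    comp(1L, rowSums[i], integer(0))
    invisible()
  }
  rec(1L, colSums, NULL)
}

# number of margin-consistent tables is bounded by the product over rows of
# the number of bounded compositions; a cheap upper bound for the cap check
.tableCountBound <- function(rowSums, colSums) {
  c1 <- length(colSums)
  prod(vapply(rowSums, function(rs) choose(rs + c1 - 1, c1 - 1), numeric(1)))
}

#' Two-sided Fisher exact test for an r x c table by complete enumeration
#'
#' Enumerates every table with the observed margins, computes its
#' conditional (multivariate hypergeometric) probability, and sums the
#' probabilities of tables no more probable than the observed one
#' (minimum-likelihood two-sided rule). All-zero rows and columns are
#' dropped with a warning. Enumeration is refused when the bound on the
#' number of margin-consistent tables exceeds \code{cap}.
#'
#' @param tab r x c matrix of non-negative integers.
#' @param cap maximum number of enumerated tables.
#' @return Two-sided p-value.
#' @examples
#' fisherExactRxC(matrix(c(35, 2, 38, 3, 26, 3), 3, 2, byrow = TRUE))
#' @export
fisherExactRxC <- function(tab, cap = 2e6) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("entries must be non-negative integers")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("fewer than 2 non-empty rows/columns; p = 1 by convention")
    return(1)
  }
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  bound <- .tableCountBound(rs, cs)
  if (!is.finite(bound) || bound > cap)
    stop("table too large for enumeration: bound ", format(bound),
         " exceeds cap ", format(cap))
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logProb <- function(x) const - sum(lgamma(x + 1))
  lpObs <- logProb(tab)
  env <- new.env()
  env$p <- 0
  .enumerateTables(rs, cs, function(x) {
    lp <- logProb(x)
    if (lp <= lpObs + 1e-7) env$p <- env$p + exp(lp)
  })
  min(1, env$p)
}

#' Association tests for a stage-by-mutation-status clinical table
#'
#' Runs one independence test per stage block of a clinical contingency
#' table. With \code{method = "auto"} (the convention of mainstream clinical
#' statistics software output), 2x2 blocks are tested with the two-sided
#' Fisher exact test and larger blocks with Pearson's chi-square test
#' without continuity correction; \code{"fisher"} forces the exact test
#' everywhere and \code{"chisq"} the chi-square test everywhere. All-zero
#' rows are dropped before testing.
#'
#' @param table data.frame with columns \code{block}, \code{stage},
#'   \code{wildtype}, \code{mutant} (as loaded by
#'   \code{\link{clinicalStageTable}}).
#' @param method \code{"auto"}, \code{"fisher"} or \code{"chisq"}.
#' @return data.frame with columns \code{block}, \code{test}, \code{p}.
#' @examples
#' stageAssociationTests(clinicalStageTable())
#' @export
stageAssociationTests <- function(table,
                                  method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  blocks <- unique(table$block)
  rows <- lapply(blocks, function(b) {
    sub <- table[table$block == b, , drop = FALSE]
    m <- as.matrix(sub[, c("wildtype", "mutant")])
    rownames(m) <- sub$stage
    m <- m[rowSums(m) > 0, , drop = FALSE]
    useFisher <- method == "fisher" ||
      (method == "auto" && nrow(m) == 2 && ncol(m) == 2)
    if (useFisher) {
      p <- if (nrow(m) == 2 && ncol(m) == 2) fisherExact2x2(m)
           else fisherExactRxC(m)
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
      test <- "chisq"
    }
    data.frame(block = b, test = test, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Packaged clinical stage table fixture
#'
#' Loads the packaged contingency fixture relating mutation status of a
#' candidate metastasis driver gene to pathological stage blocks (T, N, M
#' and AJCC stage) in a 107-patient colorectal cancer cohort.
#'
#' @return data.frame with columns \code{block}, \code{stage},
#'   \code{wildtype}, \code{mutant}.
#' @export
clinicalStageTable <- function() {
  f <- system.file("extdata", "clinical_stage_table.tsv",
                   package = "scClonality",
                   mustWork = TRUE)
  utils::read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
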