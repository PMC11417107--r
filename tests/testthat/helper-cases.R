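# shared fixture builders; everything is generated in code

tinyStatus <- function(status, tissue, region = NULL, gene = NULL) {
  StatusMatrix(status, tissue = tissue, region = region, gene = gene)
}

smallCase <- function(seed = 1, mode = "polyclonal", ...) {
  simulateCase(seedingMode = mode, seed = seed, cellsPerRegion = 6,
               cellsPerMet = 6, nHetControls = 50, nHomControls = 50, ...)
}

genotypeOf <- function(case, ...) {
  genotypeCase(case$refCounts, case$altCounts,
               tissue = case$cellData$tissue,
               region = case$cellData$region,
               gene = case$siteData$gene, ...)
}

# independent brute-force oracle for the tissue similarity index: explicit
# double loop over unordered pairs with the R rule applied literally
bruteForceIndex <- function(statusMat) {
  n <- ncol(statusMat)
  rs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- statusMat[, i]; b <- statusMat[, j]
    conflict <- any(a != "CND" & b != "CND" &
                      ((a == "MUT" & b == "WT") | (a == "WT" & b == "MUT")))
    rs <- c(rs, if (conflict) -1 else 1)
  }
  mean(rs)
}

# exhaustive-search oracle for pigeonhole trees: enumerate every
# trunk-rooted parent assignment, keep those satisfying the sibling-sum
# constraint in both samples, prefer the maximally branched tree (minimum
# total depth), and break remaining ties by the number of slack-free edges
# (parent CCF >= child CCF in every sample without using the tolerance)
oracleTree <- function(clusters, tolerance = 0.1) {
  ids <- clusters$cluster
  ccf <- as.matrix(clusters[, c("ccf_primary", "ccf_met")])
  rownames(ccf) <- ids
  trunk <- ids[which.max(rowSums(ccf))]
  rest <- setdiff(ids, trunk)
  choices <- expand.grid(rep(list(ids), length(rest)),
                         stringsAsFactors = FALSE)
  best <- NULL; bestScore <- c(Inf, Inf)
  for (i in seq_len(nrow(choices))) {
    parent <- setNames(c(NA_character_, unlist(choices[i, ])),
                       c(trunk, rest))
    depth <- function(n, seen = character(0)) {
      if (n %in% seen) return(NA_integer_)
      if (is.na(parent[[n]])) return(0L)
      d <- depth(parent[[n]], c(seen, n))
      if (is.na(d)) NA_integer_ else d + 1L
    }
    depths <- vapply(ids, depth, integer(1))
    if (anyNA(depths)) next
    ok <- TRUE; strictEdges <- 0L
    for (p in ids) {
      kids <- ids[!is.na(parent[ids]) & parent[ids] == p]
      if (length(kids) &&
          any(colSums(ccf[kids, , drop = FALSE]) > ccf[p, ] + tolerance))
        ok <- FALSE
      for (k in kids) {
        if (any(ccf[k, ] > ccf[p, ] + tolerance)) ok <- FALSE
        if (all(ccf[k, ] <= ccf[p, ])) strictEdges <- strictEdges + 1L
      }
    }
    score <- c(sum(depths), -strictEdges)
    if (ok && (score[1] < bestScore[1] ||
               (score[1] == bestScore[1] && score[2] < bestScore[2]))) {
      bestScore <- score; best <- parent
    }
  }
  best
}

# independent direct evaluation of the genotype likelihood in log space,
# written without dbinom for the normalized posterior check
oraclePosterior <- function(ref, alt, ado, eps, prior = c(1, 1, 1) / 3) {
  n <- ref + alt
  lchoose_ <- lgamma(n + 1) - lgamma(alt + 1) - lgamma(ref + 1)
  binom <- function(k, p) {
    if (p == 0) return(ifelse(k == 0, 1, 0))
    if (p == 1) return(ifelse(k == n, 1, 0))
    exp(lchoose_ + k * log(p) + (n - k) * log(1 - p))
  }
  lik <- c(RR = binom(alt, eps),
           RA = (1 - ado) * binom(alt, 0.5) + ado / 2 * binom(alt, eps) +
             ado / 2 * binom(ref, eps),
           AA = binom(ref, eps))
  post <- prior * lik
  post / sum(post)
}
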