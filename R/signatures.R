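#' @include AllClasses.R
NULL

#' The 96 pyrimidine-centric mutation classes
#'
#' Labels of the 96 single-base-substitution classes: the 6 pyrimidine-centric
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16
#' flanking dinucleotide contexts, in conventional lexicographic order
#' (substitution-major, then 5' base, then 3' base), e.g. \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @examples
#' head(signatureClasses())
#' @export
signatureClasses <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(p)
      paste0(p, "[", s, "]", vapply(bases, identity, character(1)))))))
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(.COMPLEMENT[ch]), collapse = ""), character(1))
}

#' Build a 96-class mutation catalog
#'
#' Counts every single-base substitution into one of the 96
#' pyrimidine-centric classes. Mutations with a purine reference base are
#' reverse-complemented into the corresponding pyrimidine class; the total
#' count is conserved. Records with malformed contexts (not a 3-mer whose
#' center matches the reference base) or non-SNV alleles are rejected with a
#' warning naming the offending records.
#'
#' @param mutations data.frame with columns \code{sample}, \code{ref},
#'   \code{alt} and \code{context} (3-mer centered on \code{ref}).
#' @return Integer matrix, samples x 96, with class-label columns; rejected
#'   record indices are attached as attribute \code{"rejected"}.
#' @examples
#' m <- data.frame(sample = "s1", ref = "G", alt = "T", context = "TGT")
#' cat96 <- build96Catalog(m)
#' cat96[, "A[C>A]A"]
#' @export
build96Catalog <- function(mutations) {
  classes <- signatureClasses()
  samples <- unique(as.character(mutations$sample))
  out <- matrix(0L, length(samples), 96,
                dimnames = list(samples, classes))
  if (!nrow(mutations)) {
    attr(out, "rejected") <- integer(0)
    return(out)
  }
  ref <- toupper(as.character(mutations$ref))
  alt <- toupper(as.character(mutations$alt))
  ctx <- toupper(as.character(mutations$context))
  bad <- nchar(ctx) != 3 | substr(ctx, 2, 2) != ref |
    !ref %in% names(.COMPLEMENT) | !alt %in% names(.COMPLEMENT) |
    ref == alt
  if (any(bad))
    warning(sum(bad), " malformed mutation record(s) rejected: rows ",
            paste(utils::head(which(bad), 10), collapse = ", "))
  ref2 <- ref; alt2 <- alt; ctx2 <- ctx
  flip <- !bad & ref %in% c("A", "G")
  ref2[flip] <- .COMPLEMENT[ref[flip]]
  alt2[flip] <- .COMPLEMENT[alt[flip]]
  ctx2[flip] <- .revcomp(ctx[flip])
  lab <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
                substr(ctx2, 3, 3))
  ok <- !bad
  tab <- table(factor(as.character(mutations$sample)[ok], levels = samples),
               factor(lab[ok], levels = classes))
  out[] <- as.integer(tab)
  attr(out, "rejected") <- which(bad)
  out
}

# multiplicative-update NMF minimizing the Frobenius norm; the objective is
# asserted non-increasing every iteration
.nmf <- function(V, k, maxIter = 1000, tol = 1e-6, W = NULL, H = NULL) {
  m <- nrow(V); n <- ncol(V)
  if (is.null(W)) W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  if (is.null(H)) H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  eps <- 1e-12
  obj <- sqrt(sum((V - W %*% H)^2))
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * ((V %*% t(H)) / (W %*% tcrossprod(H) + eps))
    newObj <- sqrt(sum((V - W %*% H)^2))
    if (newObj > obj + 1e-8 * (1 + obj))
      stop("NMF objective increased; multiplicative update invariant broken")
    if (abs(obj - newObj) < tol * (1 + obj)) { obj <- newObj; break }
    obj <- newObj
  }
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  list(W = W, H = H, error = obj)
}

#' Extract mutational signatures by NMF with stability-based rank selection
#'
#' For each candidate number of signatures K, the catalog is factorized by
#' multiplicative-update NMF (Frobenius objective) from multiple random
#' initializations plus one warm start from the K-1 solution (which makes the
#' reconstruction error non-increasing in K); signature stability is assessed
#' by factorizing bootstrap-resampled catalogs, partition-clustering the
#' pooled bootstrap signatures into K groups by cosine dissimilarity, and
#' averaging the silhouette widths per cluster, giving one stability value
#' per signature. The selected K is the largest K that is
#' both stable (minimum per-signature stability at least
#' \code{stabilityThreshold}) and justified
#' by the reconstruction error: its error must lie below the K-1 error by at
#' least a relative improvement of \code{minImprovement} (an elbow
#' condition; spurious extra signatures absorb only sampling noise and fail
#' it). If no K qualifies, the K of maximum stability is selected.
#' Stability at K = 1 is 1 by convention.
#'
#' @param catalog samples x 96 count matrix from \code{\link{build96Catalog}}.
#' @param kRange candidate K values (subset of 1..15).
#' @param nResamples bootstrap resamples per K.
#' @param nInits random initializations per K for the reported fit.
#' @param seed integer seed.
#' @param maxIter,tol multiplicative-update controls.
#' @param stabilityThreshold minimum stability for rank selection.
#' @param minImprovement minimum relative Frobenius-error improvement over
#'   the K-1 solution for K to be justified.
#' @return A list with \code{solutions} (one \linkS4class{SignatureSolution}
#'   per K), \code{selectedK}, and \code{selection} (data.frame of K,
#'   stability, frobeniusError).
#' @export
extractSignatures <- function(catalog, kRange = 1:5, nResamples = 50,
                              nInits = 20, seed = 1, maxIter = 1000,
                              tol = 1e-6, stabilityThreshold = 0.8,
                              minImprovement = 0.05) {
  stopifnot(all(kRange >= 1), all(kRange <= 15))
  if (nInits < 2) stop("stability assessment requires nInits >= 2")
  V <- t(catalog)  # 96 x samples
  if (all(V == 0)) stop("catalog has no mutations")
  kRange <- sort(unique(as.integer(kRange)))
  classes <- rownames(V)
  withSeed(deriveSeed(seed, "nmf"), {
    solutions <- list()
    prevFit <- NULL
    for (k in kRange) {
      fits <- vector("list", nInits)
      for (i in seq_len(nInits))
        fits[[i]] <- .nmf(V, k, maxIter, tol)
      # warm start from the previous K to enforce nested-model error decrease
      if (!is.null(prevFit) && ncol(prevFit$W) == k - 1L) {
        W0 <- cbind(prevFit$W,
                    matrix(stats::runif(nrow(V), 0.01, 0.1), nrow(V), 1))
        H0 <- rbind(prevFit$H,
                    matrix(stats::runif(ncol(V), 0.01, 0.1), 1, ncol(V)))
        fits[[nInits + 1L]] <- .nmf(V, k, maxIter, tol, W = W0, H = H0)
      }
      best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "error"))]]

      # bootstrap stability
      if (k == 1L) {
        stab <- 1
      } else {
        boot <- matrix(0, nrow(V), 0)
        for (r in seq_len(nResamples)) {
          Vb <- apply(V, 2, function(col) {
            tot <- sum(col)
            if (tot == 0) return(col)
            as.numeric(stats::rmultinom(1, tot, col / tot))
          })
          fb <- .nmf(Vb, k, maxIter = min(maxIter, 400), tol = tol * 10)
          boot <- cbind(boot, fb$W)
        }
        nv <- sqrt(colSums(boot^2)); nv[nv == 0] <- 1
        U <- sweep(boot, 2, nv, "/")
        dmat <- 1 - crossprod(U)
        dmat[dmat < 0] <- 0
        pm <- cluster::pam(stats::as.dist(dmat), k = k)
        sil <- cluster::silhouette(pm)
        perCluster <- tapply(sil[, "sil_width"], sil[, "cluster"], mean)
        # align each reported signature with its closest bootstrap cluster
        medoids <- U[, pm$id.med, drop = FALSE]
        bw <- best$W
        bn <- sqrt(colSums(bw^2)); bn[bn == 0] <- 1
        cosBM <- crossprod(sweep(bw, 2, bn, "/"), medoids)
        stab <- as.numeric(perCluster[max.col(cosBM, ties.method = "first")])
      }

      sig <- best$W
      colnames(sig) <- paste0("Sig", LETTERS[seq_len(k)])
      rownames(sig) <- classes
      expo <- best$H
      rownames(expo) <- colnames(sig); colnames(expo) <- rownames(catalog)
      solutions[[as.character(k)]] <- new(
        "SignatureSolution", k = k, signatures = sig, exposures = expo,
        stability = stab, frobeniusError = best$error)
      prevFit <- best
    }
    sel <- data.frame(
      k = kRange,
      stability = vapply(solutions, function(s) min(s@stability),
                         numeric(1)),
      frobeniusError = vapply(solutions, slot, numeric(1), "frobeniusError"))
    improvement <- c(Inf, 1 - sel$frobeniusError[-1] /
                            sel$frobeniusError[-nrow(sel)])
    ok <- sel$stability >= stabilityThreshold &
      improvement >= minImprovement
    selectedK <- if (any(ok)) max(sel$k[ok]) else sel$k[which.max(sel$stability)]
    sel$improvement <- improvement
    list(solutions = solutions, selectedK = selectedK, selection = sel)
  })
}

#' Match discovered signatures to a reference catalogue
#'
#' Cosine similarity between discovered and reference signatures over the 96
#' classes, with the best reference match of each discovered signature and an
#' unsupervised hierarchical co-clustering of the combined signature set on
#' cosine dissimilarity.
#'
#' @param discovered 96 x k matrix with class-label rownames.
#' @param reference 96 x m matrix over the same classes.
#' @return A list with \code{cosine} (k x m), \code{best} (data.frame:
#'   signature, match, cosine) and \code{hclust} of the combined set.
#' @examples
#' ref <- syntheticReferenceSignatures()
#' matchSignatures(ref[, 1:2], ref)$best
#' @export
matchSignatures <- function(discovered, reference) {
  if (!identical(rownames(discovered), rownames(reference)))
    stop("discovered and reference signatures must share the same ",
         "96 class labels in the same order")
  k <- ncol(discovered); m <- ncol(reference)
  cs <- matrix(NA_real_, k, m,
               dimnames = list(colnames(discovered), colnames(reference)))
  for (i in seq_len(k)) for (j in seq_len(m))
    cs[i, j] <- cosineSimilarity(discovered[, i], reference[, j])
  best <- data.frame(
    signature = colnames(discovered),
    match = colnames(reference)[max.col(cs, ties.method = "first")],
    cosine = apply(cs, 1, max), row.names = NULL)
  comb <- cbind(discovered, reference)
  nv <- sqrt(colSums(comb^2)); nv[nv == 0] <- 1
  U <- sweep(comb, 2, nv, "/")
  d <- 1 - crossprod(U); d[d < 0] <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(cosine = cs, best = best, hclust = hc)
}

#' Simulate a mutation catalog with planted signatures
#'
#' Draws sparse random 96-class signatures (enforcing pairwise cosine below
#' \code{maxCosine}), Dirichlet exposures per sample, and multinomial
#' mutation counts.
#'
#' @param nSignatures number of planted signatures.
#' @param nSamples number of samples.
#' @param mutationsPerSample mutations drawn per sample.
#' @param maxCosine maximum pairwise cosine between planted signatures.
#' @param seed integer seed.
#' @return A list with \code{catalog} (samples x 96), \code{signatures}
#'   (96 x k, columns sum to 1) and \code{exposures} (k x samples).
#' @export
simulateCatalog <- function(nSignatures = 3, nSamples = 50,
                            mutationsPerSample = 500, maxCosine = 0.3,
                            seed = 1) {
  classes <- signatureClasses()
  withSeed(deriveSeed(seed, "catalog"), {
    repeat {
      sig <- matrix(stats::rgamma(96 * nSignatures, shape = 0.2), 96,
                    nSignatures)
      sig <- sweep(sig, 2, colSums(sig), "/")
      nv <- sqrt(colSums(sig^2))
      cs <- crossprod(sweep(sig, 2, nv, "/"))
      if (nSignatures == 1 || max(cs[upper.tri(cs)]) <= maxCosine) break
    }
    rownames(sig) <- classes
    colnames(sig) <- paste0("TrueSig", seq_len(nSignatures))
    expo <- matrix(stats::rgamma(nSignatures * nSamples, shape = 1),
                   nSignatures, nSamples)
    expo <- sweep(expo, 2, colSums(expo), "/")
    p <- sig %*% expo
    catalog <- t(vapply(seq_len(nSamples), function(j)
      as.integer(stats::rmultinom(1, mutationsPerSample, p[, j])),
      integer(96)))
    dimnames(catalog) <- list(paste0("sample", seq_len(nSamples)), classes)
    rownames(expo) <- colnames(sig); colnames(expo) <- rownames(catalog)
    list(catalog = catalog, signatures = sig,
         exposures = expo * mutationsPerSample)
  })
}

#' Synthetic reference signature set
#'
#' A deterministic synthetic stand-in for an external reference signature
#' catalogue: five sparse 96-class profiles with low pairwise cosine
#' similarity, for testing signature matching. This set is synthetic and
#' carries no relation to any published catalogue.
#'
#' @return 96 x 5 matrix with columns summing to 1.
#' @export
syntheticReferenceSignatures <- function() {
  classes <- signatureClasses()
  withSeed(deriveSeed(20240101, "synthetic-reference"), {
    sig <- matrix(0, 96, 5, dimnames = list(classes, paste0("RefSig", 1:5)))
    blocks <- split(seq_len(96), rep(1:5, length.out = 96))
    for (j in 1:5) {
      w <- stats::rgamma(96, shape = 0.3)
      w[blocks[[j]]] <- w[blocks[[j]]] + stats::rgamma(length(blocks[[j]]),
                                                       shape = 5)
      sig[, j] <- w / sum(w)
    }
    sig
  })
}
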