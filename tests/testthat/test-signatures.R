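test_that("96-class catalog counts and reverse-complements correctly", {
  m <- data.frame(sample = c("s1", "s1", "s2"),
                  ref = c("C", "G", "C"),
                  alt = c("A", "T", "T"),
                  context = c("ACA", "TGT", "GCG"))
  cat96 <- build96Catalog(m)
  expect_equal(dim(cat96), c(2L, 96L))
  # G>T at TGT is the reverse complement of C>A at ACA
  expect_equal(cat96["s1", "A[C>A]A"], 2L)
  expect_equal(cat96["s2", "G[C>T]G"], 1L)
  expect_equal(rowSums(cat96), c(s1 = 2L, s2 = 1L))
  # independent complementation oracle for a batch of purine records
  set.seed(2)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:10) {
    ref <- sample(c("A", "G"), 1)
    alt <- sample(setdiff(bases, ref), 1)
    ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
    rc <- paste0(comp[substr(ctx, 3, 3)], comp[ref], comp[substr(ctx, 1, 1)])
    a <- build96Catalog(data.frame(sample = "x", ref = ref, alt = alt,
                                   context = ctx))
    b <- build96Catalog(data.frame(sample = "x", ref = comp[[ref]],
                                   alt = comp[[alt]], context = rc))
    expect_identical(a, b)
  }
})

test_that("malformed records are rejected and empty input yields zeros", {
  m <- data.frame(sample = "s1", ref = "C", alt = "A", context = "AGA")
  expect_warning(cat96 <- build96Catalog(m), "malformed")
  expect_equal(sum(cat96), 0L)
  expect_equal(attr(cat96, "rejected"), 1L)
  empty <- build96Catalog(data.frame(sample = character(0),
                                     ref = character(0),
                                     alt = character(0),
                                     context = character(0)))
  expect_equal(sum(empty), 0L)
})

test_that("rank-1 factorization recovers the shared profile", {
  p <- syntheticReferenceSignatures()[, 1]
  catalog <- outer(c(100, 220, 340), p)
  rownames(catalog) <- paste0("s", 1:3)
  ex <- extractSignatures(catalog, kRange = 1, nResamples = 5, nInits = 3,
                          seed = 1)
  sig <- ex$solutions[["1"]]@signatures[, 1]
  cs <- sum(sig * p) / sqrt(sum(sig^2) * sum(p^2))
  expect_gt(cs, 1 - 1e-8)
  expect_equal(unname(sig), unname(p), tolerance = 1e-4)
})

test_that("a noise-free two-signature mixture is recovered", {
  sig <- syntheticReferenceSignatures()[, c(1, 3)]
  expo <- rbind(seq(0.1, 0.9, length.out = 12),
                seq(0.9, 0.1, length.out = 12)) * 400
  catalog <- t(sig %*% expo)
  rownames(catalog) <- paste0("s", 1:12)
  ex <- extractSignatures(catalog, kRange = 2, nResamples = 5, nInits = 6,
                          seed = 2)
  sol <- ex$solutions[["2"]]
  mm <- matchSignatures(sol@signatures, sig)
  expect_true(all(mm$best$cosine >= 0.99))
  expect_setequal(mm$best$match, colnames(sig))
  # invariants: normalization and non-negative exposures
  expect_true(all(abs(colSums(sol@signatures) - 1) < 1e-9))
  expect_true(all(sol@exposures >= 0))
})

test_that("reconstruction error is non-increasing in K", {
  sim <- simulateCatalog(nSignatures = 3, nSamples = 15,
                         mutationsPerSample = 200, seed = 4)
  ex <- extractSignatures(sim$catalog, kRange = 1:4, nResamples = 4,
                          nInits = 3, seed = 4)
  err <- ex$selection$frobeniusError
  expect_true(all(diff(err) <= 1e-9))
  expect_error(extractSignatures(sim$catalog, kRange = 2, nInits = 1),
               "nInits")
})

test_that("cosine matching finds the right references", {
  ref <- syntheticReferenceSignatures()
  self <- matchSignatures(ref, ref)
  expect_equal(unname(diag(self$cosine)), rep(1, 5), tolerance = 1e-12)
  expect_equal(self$best$match, colnames(ref))
  # disjoint-support profiles are orthogonal
  a <- matrix(0, 96, 1, dimnames = list(signatureClasses(), "a"))
  b <- a; colnames(b) <- "b"
  a[1:48, 1] <- 1 / 48; b[49:96, 1] <- 1 / 48
  expect_equal(matchSignatures(a, b)$cosine[1, 1], 0)
  # a noisy copy of reference j still maps to j
  set.seed(9)
  noisy <- ref[, 2] + runif(96, 0, 0.002)
  noisy <- matrix(noisy / sum(noisy), 96,
                  dimnames = list(rownames(ref), "noisy"))
  expect_equal(matchSignatures(noisy, ref)$best$match, "RefSig2")
  colnames(a) <- "a"
  expect_error(matchSignatures(ref[96:1, , drop = FALSE], ref),
               "class labels")
})
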