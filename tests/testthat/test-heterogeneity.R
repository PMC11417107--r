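test_that("pair similarity follows the CND-tolerant rules", {
  # CND is compatible with anything
  r <- pairSimilarity(c("MUT", "WT", "CND"), c("MUT", "CND", "MUT"))
  expect_equal(r$R, 1)
  expect_equal(r$nInformative, 1)
  # a determinable MUT/WT conflict makes the pair different
  r2 <- pairSimilarity(c("MUT", "WT"), c("WT", "WT"))
  expect_equal(r2$R, -1)
  expect_equal(r2$concordance, 0.5)
  # all-CND cell matches anything with zero informative sites
  r3 <- pairSimilarity(c("CND", "CND"), c("MUT", "WT"))
  expect_equal(r3$R, 1)
  expect_equal(r3$nInformative, 0)
  expect_true(is.na(r3$concordance))
  expect_error(pairSimilarity(c("MUT"), c("MUT", "WT")), "same sites")
})

test_that("pair similarity is reflexive and symmetric", {
  set.seed(3)
  for (i in 1:30) {
    a <- sample(c("MUT", "WT", "CND"), 20, replace = TRUE)
    b <- sample(c("MUT", "WT", "CND"), 20, replace = TRUE)
    if (any(a != "CND")) {
      self <- pairSimilarity(a, a)
      expect_equal(self$R, 1)
      expect_equal(self$concordance, 1)
    }
    expect_identical(pairSimilarity(a, b), pairSimilarity(b, a))
  }
})

test_that("tissue index matches hand-derived values and the identity", {
  same <- matrix("MUT", 4, 3)
  h <- tissueHeterogeneity(tinyStatus(same, tissue = rep("t", 3)))
  expect_equal(h$similarityIndex, 1)
  expect_equal(h$H, 0)
  conflict <- matrix(c("MUT", "WT"), 1, 2)
  h2 <- tissueHeterogeneity(tinyStatus(conflict, tissue = rep("t", 2)))
  expect_equal(h2$similarityIndex, -1)
  expect_equal(h2$H, 1)
  # two 2-cell clones: 2 concordant pairs, 4 discordant, index = -1/3
  twoClones <- cbind(c("MUT", "WT"), c("MUT", "WT"),
                     c("WT", "MUT"), c("WT", "MUT"))
  h3 <- tissueHeterogeneity(tinyStatus(twoClones, tissue = rep("t", 4)))
  expect_equal(h3$similarityIndex, -1 / 3)
  expect_equal(h3$H, 2 / 3)
  expect_equal(h3$nPairs, 6L)
  expect_equal(h3$similarityIndex, 1 - 2 * h3$H)
})

test_that("tissue index equals brute-force pair enumeration", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    m <- sample(5:60, 1)
    st <- matrix(sample(c("MUT", "WT", "CND"), n * m, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2)), m, n)
    got <- tissueHeterogeneity(tinyStatus(st, tissue = rep("x", n)))
    expect_identical(got$similarityIndex, bruteForceIndex(st))
  }
})

test_that("normal-cell exclusion needs both low burden and no drivers", {
  st <- matrix("WT", 45, 3, dimnames = list(paste0("s", 1:45), NULL))
  st[1, 2] <- "MUT"; st[2, 2] <- "MUT"   # 2 muts incl. a driver site
  st[1:40, 3] <- "MUT"                    # high burden, no driver
  genes <- paste0("g", 1:45); genes[1] <- "APC"
  sm <- tinyStatus(st, tissue = rep("t", 3), gene = genes)
  res <- excludeNormalCells(sm, driverGenes = c("APC", "TP53"))
  expect_equal(res$excluded, colnames(statusCalls(sm))[1]) # 0 mutations
  expect_equal(ncol(res$tumor), 2L)
  expect_error(excludeNormalCells(sm, character(0)), "non-empty")
})

test_that("origin tracing assigns identical cells and flags ties", {
  st <- matrix("WT", 10, 4, dimnames = list(paste0("s", 1:10),
                                            c("p1", "p2", "p3", "m1")))
  st[1:4, "p1"] <- "MUT"
  st[5:8, "p2"] <- "MUT"
  st[1:4, "m1"] <- "MUT"      # identical to p1
  sm <- StatusMatrix(st, tissue = c("primary", "primary", "primary",
                                    "liver"),
                     region = c("colon5", "colon1", "colon3", NA))
  res <- traceOrigin(sm, "liver", minInformative = 5)
  expect_equal(res$assignments$region, "colon5")
  expect_equal(res$assignments$concordance, 1)
  expect_false(res$assignments$tie)
  # two equally concordant regions: lexicographically first, tie flagged
  st2 <- st; st2[, "p2"] <- st2[, "p1"]
  sm2 <- StatusMatrix(st2, tissue = c("primary", "primary", "primary",
                                      "liver"),
                      region = c("colon5", "colon1", "colon3", NA))
  res2 <- traceOrigin(sm2, "liver", minInformative = 5)
  expect_true(res2$assignments$tie)
  expect_equal(res2$assignments$region, "colon1")
  # informative-site floor leaves the cell unassigned
  res3 <- traceOrigin(sm, "liver", minInformative = 50)
  expect_true(is.na(res3$assignments$region))
})

test_that("tracing recovers the true source regions in simulation", {
  case <- simulateCase(seedingMode = "polyclonal", seed = 21,
                       cellsPerRegion = 6, cellsPerMet = 12,
                       nHetControls = 20, nHomControls = 20)
  sm <- genotypeOf(case)
  res <- suppressWarnings(
    traceOrigin(sm, "liver", sourceRegions = case$seeding$sourceRegions))
  expect_gte(res$tracedFraction, 0.9)
  expect_lt(res$p, 0.05)
})

test_that("clustering separates planted clones and PCA preserves geometry", {
  st <- cbind(matrix(rep(c("MUT", "WT"), c(5, 5)), 10, 3),
              matrix(rep(c("WT", "MUT"), c(5, 5)), 10, 3))
  colnames(st) <- paste0("c", 1:6); rownames(st) <- paste0("s", 1:10)
  dup <- st[, c(1:6, 1)]; colnames(dup)[7] <- "c1dup"
  sm <- tinyStatus(dup, tissue = rep("t", 7))
  emb <- clusterAndEmbed(sm)
  expect_true(all(diff(emb$hclust$height) >= -1e-12))
  expect_equal(min(emb$hclust$height), 0)  # duplicates merge first
  grp <- cutree(emb$hclust, k = 2)
  expect_equal(length(unique(grp[c(1, 2, 3, 7)])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  expect_true(grp[1] != grp[4])
  expect_match(emb$newick, "^\\(")
  # rank-2 toy: 2-component PCA reproduces pairwise distances exactly
  toy <- matrix(c("MUT", "WT", "WT",
                  "MUT", "MUT", "WT",
                  "WT", "MUT", "MUT",
                  "WT", "WT", "MUT"), 3, 4)
  enc <- (toy == "MUT") + 0
  emb2 <- clusterAndEmbed(tinyStatus(toy, tissue = rep("t", 4)),
                          nComponents = 2)
  expect_equal(as.matrix(dist(emb2$pca)), as.matrix(dist(t(enc))),
               tolerance = 1e-9, ignore_attr = TRUE)
  allcnd <- matrix("CND", 3, 3)
  expect_error(clusterAndEmbed(tinyStatus(allcnd, tissue = rep("t", 3))),
               "CND")
})

test_that("lineage counting separates mono from polyclonal metastases", {
  mono <- smallCase(seed = 31, mode = "monoclonal")
  poly <- smallCase(seed = 31, mode = "polyclonal")
  smM <- genotypeOf(mono); smP <- genotypeOf(poly)
  expect_equal(countMetLineages(smM, "liver"), 1L)
  expect_gte(countMetLineages(smP, "liver"), 2L)
  rM <- heterogeneitySeedingRule(smM, "liver", mono$seeding$sourceRegions)
  rP <- heterogeneitySeedingRule(smP, "liver", poly$seeding$sourceRegions)
  expect_equal(rM$mode, "monoclonal")
  expect_equal(rP$mode, "polyclonal")
  expect_lte(abs(rP$metH - rP$sourceH), 0.1)
})
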