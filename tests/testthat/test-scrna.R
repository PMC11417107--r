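test_that("projection assigns exact centroid matches and refuses zeros", {
  set.seed(4)
  primary <- matrix(rpois(200 * 30, 5), 200, 30,
                    dimnames = list(paste0("g", 1:200), paste0("p", 1:30)))
  clusters <- setNames(rep(c("k1", "k2", "k3"), each = 10),
                       colnames(primary))
  # a metastatic cell equal to the k2 centroid
  feats <- order(apply(primary, 1, var), decreasing = TRUE)[1:100]
  centroid <- apply(primary[, clusters == "k2"], 1, median)
  met <- cbind(m1 = centroid, m2 = 0)
  res <- projectCells(met, primary, clusters, nFeatures = 100)
  expect_equal(res$cluster[1], "k2")
  expect_equal(res$cosine[1], 1)
  expect_true(is.na(res$cluster[2]))   # all-zero cell unassigned
  # tiny clusters are dropped from the centroid set
  clusters2 <- clusters; clusters2[1:2] <- "tiny"
  clusters2 <- clusters2[-(3:10)]
  expect_warning(projectCells(met, primary[, names(clusters2)], clusters2,
                              nFeatures = 50), "< 3 cells")
})

test_that("MC scores are assignment fractions normalized to one", {
  a <- data.frame(cell = paste0("m", 1:5),
                  cluster = c("k2", "k2", "k2", "k2", "k2"))
  mc <- mcScore(a, clusters = c("k1", "k2", "k3"))
  expect_equal(unname(mc), c(0, 1, 0))
  b <- data.frame(cell = paste0("m", 1:10),
                  cluster = rep(paste0("k", 1:5), 2))
  expect_equal(unname(mcScore(b)), rep(0.2, 5))
  expect_equal(sum(mcScore(b)), 1)
  expect_warning(mcScore(data.frame(cell = "m", cluster = NA)), "undefined")
})

test_that("module score is zero on constants and recovers a planted shift", {
  const <- matrix(3, 120, 15, dimnames = list(paste0("g", 1:120), NULL))
  s <- emtModuleScore(const, paste0("g", 1:10), seed = 1)
  expect_equal(unname(s), rep(0, 15))
  # determinism under the same seed
  set.seed(77)
  expr <- matrix(rgamma(2000 * 200, 2, 0.5), 2000, 200,
                 dimnames = list(paste0("g", 1:2000), paste0("c", 1:200)))
  set1 <- emtModuleScore(expr, paste0("g", 1:50), seed = 9)
  set2 <- emtModuleScore(expr, paste0("g", 1:50), seed = 9)
  expect_identical(set1, set2)
  # +delta on the set genes in half the cells shifts their score by delta
  delta <- 2
  shifted <- expr
  shifted[paste0("g", 1:50), 1:100] <- shifted[paste0("g", 1:50), 1:100] + delta
  sc <- emtModuleScore(shifted, paste0("g", 1:50), seed = 9)
  gap <- mean(sc[1:100]) - mean(sc[101:200])
  expect_lt(abs(gap - delta) / delta, 0.1)
  expect_error(emtModuleScore(expr, character(0)), "empty")
  expect_error(emtModuleScore(expr, "nope"), "absent")
})

test_that("module score is centered under a label permutation null", {
  set.seed(31)
  expr <- matrix(rgamma(300 * 40, 2, 0.5), 300, 40,
                 dimnames = list(paste0("g", 1:300), paste0("c", 1:40)))
  nulls <- vapply(1:200, function(i) {
    genes <- sample(rownames(expr), 20)
    mean(emtModuleScore(expr, genes, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.05)
})

test_that("CNV score is the exact quadratic deviation sum", {
  cnv <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(cnvScore(cnv)), c(0, 0, 0))
  cnv["b", 2] <- 1.3
  expect_equal(cnvScore(cnv)[["b"]], 0.3^2)
  # homogeneity: doubling deviations quadruples the score
  cnv2 <- 1 + 2 * (cnv - 1)
  expect_equal(cnvScore(cnv2)[["b"]], 4 * cnvScore(cnv)[["b"]])
  cnv[1, 1] <- NA
  expect_error(cnvScore(cnv), "missing")
})

test_that("EMT-MC regression matches closed forms and refuses degeneracy", {
  r <- suppressWarnings(   # lm warns on an exactly collinear toy
    regressEmtMc(c(a = 0, b = 1, c = 2), c(a = 0, b = 1, c = 2)))
  expect_equal(r$slope, 1)
  expect_equal(r$rSquared, 1)
  expect_error(regressEmtMc(c(a = 1, b = 1, c = 1), c(a = 0, b = 1, c = 2)),
               "zero-variance")
  expect_error(regressEmtMc(c(a = 1, b = 2), c(a = 1, b = 2)), "3 clusters")
})

test_that("planted expression cases score as constructed", {
  ec <- simulateExpressionCase(nClusters = 5, cellsPerCluster = 40,
                               nMetCells = 80, nGenes = 500, seed = 14)
  sc <- scoreExpressionCase(ec, seed = 14)
  expect_gte(sc$accuracy, 0.95)
  expect_equal(sum(sc$mc), 1)
  # planted association: high-MC clusters carry the EMT elevation
  expect_gt(sc$regression$slope, 0)
  expect_true(all(sc$cnv >= 0))
  # high-contribution clusters have larger CNV scores by construction
  byCluster <- tapply(sc$cnv[names(ec$primaryClusters)],
                      ec$primaryClusters, mean)
  expect_gt(mean(byCluster[ec$highClusters]),
            mean(byCluster[setdiff(names(byCluster), ec$highClusters)]))
})

test_that("QC filter drops low-complexity and mitochondrial cells", {
  expr <- matrix(1, 300, 3,
                 dimnames = list(c(paste0("g", 1:299), "MT-CO1"), NULL))
  expr[1:150, 2] <- 0                 # only 150 detected genes
  expr["MT-CO1", 3] <- 200            # ~40% mitochondrial
  kept <- qcFilterCells(expr, minGenes = 200, maxMitoFrac = 0.2)
  expect_equal(ncol(kept), 1L)
})
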