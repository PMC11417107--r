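test_that("identical seeds reproduce a case bit for bit", {
  a <- smallCase(seed = 9)
  b <- smallCase(seed = 9)
  expect_identical(a$refCounts, b$refCounts)
  expect_identical(a$altCounts, b$altCounts)
  expect_identical(a$truthGenotypes, b$truthGenotypes)
  expect_identical(hetCalls(a$controls), hetCalls(b$controls))
  expect_identical(a$bulkVAF, b$bulkVAF)
  c <- smallCase(seed = 10)
  expect_false(identical(a$altCounts, c$altCounts))
})

test_that("zero noise makes observed genotypes equal the truth", {
  case <- smallCase(seed = 4, noise = NoiseRates(0, 0, 0))
  post <- genotypePosterior(as.vector(case$refCounts),
                            as.vector(case$altCounts), NoiseRates(0, 0, 0))
  map <- matrix(post$map, nrow(case$refCounts), ncol(case$refCounts))
  covered <- (case$refCounts + case$altCounts) >= 2
  expect_true(all((map == case$truthGenotypes)[covered]))
})

test_that("monoclonal metastatic cells carry one chain's mutations", {
  for (s in 1:5) {
    case <- smallCase(seed = 100 + s, mode = "monoclonal")
    target <- case$seeding$seedingClones
    expect_length(target, 1L)
    chain <- scClonality:::.ancestorsOrSelf(case$tree@parent, target)
    chainSites <- case$siteData$site[case$siteData$clone %in% chain]
    met <- case$cellData$tissue %in% c("liver", "lymph")
    carried <- case$truthGenotypes[, met, drop = FALSE] == "RA"
    expect_true(all(carried[chainSites, ]))
  }
})

test_that("polyclonal seeding needs three clones and spans two branches", {
  expect_error(simulateCase(nClones = 2, seedingMode = "polyclonal",
                            seed = 1), "at least 3")
  case <- smallCase(seed = 8, mode = "polyclonal")
  sc <- case$seeding$seedingClones
  expect_length(sc, 2L)
  p <- case$tree@parent
  expect_false(scClonality:::.isAncestorOrSelf(p, sc[1], sc[2]))
  expect_false(scClonality:::.isAncestorOrSelf(p, sc[2], sc[1]))
})

test_that("generated prevalences always satisfy the pigeonhole constraint", {
  for (s in 1:8) {
    mode <- if (s %% 2) "monoclonal" else "polyclonal"
    case <- smallCase(seed = 200 + s, mode = mode)
    expect_true(validObject(case$tree))  # validity enforces the constraint
    expect_true(all(case$tree@prevalence >= 0 &
                      case$tree@prevalence <= 1 + 1e-9))
  }
})

test_that("empirical ADO matches the configured rate at scale", {
  cs <- simulateControls(2000, 10, 50, NoiseRates(ado = 0.103), seed = 12)
  est <- estimateADORate(cs)
  # binomial 95% band around 0.103 at ~1900 informative sites per cell
  expect_gt(est$cohort, 0.093)
  expect_lt(est$cohort, 0.113)
})

test_that("expression case nulls behave as planted", {
  ec0 <- simulateExpressionCase(nClusters = 4, cellsPerCluster = 60,
                                nMetCells = 20, nGenes = 300,
                                emtEffect = 0, cnvProfile = "neutral",
                                seed = 2)
  emtMeans <- tapply(colMeans(ec0$primary[ec0$emtGenes, ]),
                     ec0$primaryClusters, mean)
  expect_lt(diff(range(emtMeans)), 0.5)       # no planted shift
  expect_true(all(ec0$cnv == 1))              # neutral baseline
  expect_equal(nrow(ec0$truth), 20L)          # bookkeeping
  expect_error(simulateExpressionCase(nGenes = 30, nEmtGenes = 50,
                                      seed = 1),
               "larger than the gene universe")
})

test_that("fixtures round-trip exactly and refuse dirty directories", {
  case <- simulateCase(seed = 6, cellsPerRegion = 3, cellsPerMet = 3,
                       nClones = 4, nMutations = 20,
                       nHetControls = 8, nHomControls = 8)
  d <- file.path(tempdir(), "fixture-roundtrip")
  unlink(d, recursive = TRUE)
  writeFixture(case, d)
  back <- readFixture(d)
  expect_identical(back$refCounts, case$refCounts)
  expect_identical(back$altCounts, case$altCounts)
  expect_identical(back$truthGenotypes, case$truthGenotypes)
  expect_identical(hetCalls(back$controls), hetCalls(case$controls))
  expect_equal(back$bulkVAF, case$bulkVAF)
  expect_identical(back$tree@parent, case$tree@parent)
  expect_equal(back$seeding$seedingClones, case$seeding$seedingClones)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(manifest$seed, 6)
  expect_true(all(c("ado", "fp", "seqError") %in% names(manifest)))
  expect_error(writeFixture(case, d), "overwrite")
  # an empty case (no cells) still writes valid, re-readable files
  empty <- case
  empty$refCounts <- case$refCounts[, 0, drop = FALSE]
  empty$altCounts <- case$altCounts[, 0, drop = FALSE]
  empty$truthGenotypes <- case$truthGenotypes[, 0, drop = FALSE]
  empty$cellData <- case$cellData[0, ]
  empty$controls <- new("ControlSites",
                        het = hetCalls(case$controls)[, 0, drop = FALSE],
                        hom = homCalls(case$controls)[, 0, drop = FALSE])
  d2 <- file.path(tempdir(), "fixture-empty")
  unlink(d2, recursive = TRUE)
  writeFixture(empty, d2)
  back2 <- readFixture(d2)
  expect_equal(ncol(back2$refCounts), 0L)
})
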