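test_that("posterior matches an independent likelihood evaluation", {
  noise <- NoiseRates(ado = 0.103, fp = 0, seqError = 0.005)
  for (ref in c(0:6, 12, 30)) for (alt in c(0:6, 12, 30)) {
    got <- genotypePosterior(ref, alt, noise)
    want <- oraclePosterior(ref, alt, ado = 0.103, eps = 0.005)
    expect_equal(unlist(got[c("pRR", "pRA", "pAA")]), want,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # high-coverage reference site is called RR; the dropout mixture caps the
  # attainable posterior at 1/(1 + ado/2), about 0.952 at ado = 0.1
  g <- genotypePosterior(20, 0, NoiseRates(ado = 0.1, seqError = 0.001))
  expect_equal(g$map, "RR")
  expect_gt(g$mapProb, 0.95)
  expect_lt(g$mapProb, 1 / (1 + 0.1 / 2) + 1e-6)
})

test_that("no-data posterior equals the prior; ref/alt swap is symmetric", {
  prior <- c(0.5, 0.3, 0.2)
  g <- genotypePosterior(0, 0, NoiseRates(), prior = prior)
  expect_equal(c(g$pRR, g$pRA, g$pAA), prior, tolerance = 1e-15)
  a <- genotypePosterior(17, 4, NoiseRates())
  b <- genotypePosterior(4, 17, NoiseRates())
  expect_equal(a$pRR, b$pAA, tolerance = 1e-12)
  expect_equal(a$pRA, b$pRA, tolerance = 1e-12)
  expect_error(genotypePosterior(-1, 2, NoiseRates()), "non-negative")
  expect_error(genotypePosterior(1, 1, NoiseRates(), prior = c(1, 1, 1)),
               "prior")
})

test_that("posteriors normalize for count pairs up to depth 500", {
  set.seed(1)
  n <- sample(0:500, 200, replace = TRUE)
  alt <- vapply(n, function(x) sample(0:x, 1), integer(1))
  g <- genotypePosterior(n - alt, alt, NoiseRates())
  expect_true(all(abs(g$pRR + g$pRA + g$pAA - 1) < 1e-12))
  expect_equal(g$mapProb, pmax(g$pRR, g$pRA, g$pAA))
})

test_that("the model reduces to the standard diploid caller at ado = 0", {
  eps <- 0.01
  for (alt in 0:10) {
    g <- genotypePosterior(10 - alt, alt, NoiseRates(ado = 0, seqError = eps))
    lik <- c(dbinom(alt, 10, eps), dbinom(alt, 10, 0.5),
             dbinom(10 - alt, 10, eps))
    expect_equal(c(g$pRR, g$pRA, g$pAA), lik / sum(lik), tolerance = 1e-12)
  }
})

test_that("status calls apply the depth and posterior thresholds", {
  g <- genotypePosterior(c(0, 30, 2), c(0, 28, 1), NoiseRates())
  st <- callStatus(g, minDepth = 5, minPosterior = 0.95)
  expect_equal(st$status[1], "CND")   # depth 0
  expect_equal(st$status[2], "MUT")   # confident het at depth 58
  expect_equal(st$status[3], "CND")   # depth 3 < 5
  # posterior below the threshold goes CND regardless of depth
  low <- data.frame(pRR = 0.6, pRA = 0.3, pAA = 0.1, depth = 30,
                    map = "RR", mapProb = 0.6)
  expect_equal(callStatus(low, minPosterior = 0.9)$status, "CND")
  expect_equal(callStatus(low, minPosterior = 0.5)$status, "WT")
})

test_that("SNV support filter applies both rule variants", {
  st <- matrix("WT", 3, 5, dimnames = list(paste0("s", 1:3),
                                           paste0("c", 1:5)))
  st["s1", 1:2] <- "MUT"          # 2 cells, no tissue support
  st["s2", 1:3] <- "MUT"          # 3 cells, no tissue support
  sm <- tinyStatus(st, tissue = rep("primary", 5))
  support <- matrix(0, 3, 2, dimnames = list(rownames(st), c("t1", "t2")))
  support["s3", 1] <- 12          # tissue support only
  expect_setequal(filterSNVs(sm, support, rule = "OR"), c("s2", "s3"))
  expect_equal(filterSNVs(sm, support, rule = "AND"), character(0))
  expect_error(filterSNVs(sm, NULL), "tissue support")
})

test_that("mutation burden is count over callable megabases", {
  st <- matrix("WT", 50, 3)
  st[1:43, 1] <- "MUT"
  st[, 3] <- "CND"
  b <- mutationBurden(tinyStatus(st, tissue = rep("a", 3)), callableMb = 50)
  expect_equal(b$ratePerMb, c(0.86, 0, 0))
  expect_equal(b$nInformative[3], 0)   # all-CND cell flagged by zero sites
})

test_that("single-cell fractions correlate with bulk as hand-computed", {
  st <- matrix("CND", 3, 6, dimnames = list(paste0("s", 1:3),
                                            paste0("c", 1:6)))
  st[1, ] <- c("MUT", "WT", "MUT", "WT", "CND", "CND")   # 1/2
  st[2, ] <- c("MUT", "WT", "WT", "CND", "CND", "CND")   # 1/3
  st[3, ] <- c("MUT", "MUT", "CND", "CND", "CND", "CND") # 1
  sm <- tinyStatus(st, tissue = rep("colon", 6))
  bulk <- matrix(c(0.25, 0.15, 0.45), 3, 1,
                 dimnames = list(rownames(st), "colon"))
  res <- siteFractionConcordance(sm, bulk)
  x <- c(1 / 2, 1 / 3, 1); y <- c(0.5, 0.3, 0.9)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson, rHand, tolerance = 1e-12)
  expect_equal(res$perSite$scFraction, x)
  # identical vectors give r = 1
  bulk2 <- matrix(x / 2, 3, 1, dimnames = list(rownames(st), "colon"))
  expect_equal(siteFractionConcordance(sm, bulk2)$pearson, 1)
})

test_that("dropout-aware genotyping is near-perfect at informative sites", {
  case <- smallCase(seed = 5)
  acc <- genotypeAccuracy(case, minDepth = 20)
  expect_gt(acc$accuracy, 0.99)
  expect_gt(acc$n, 1000)
  # with dropout included, accuracy is bounded by the dropout rate
  expect_lt(acc$accuracyAll, acc$accuracy + 1e-12)
})
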