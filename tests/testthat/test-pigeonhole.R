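test_that("CCF conversion and degenerate clustering behave as defined", {
  cl <- clusterCCF(vafPrimary = 0.25, vafMet = 0.25, purity = c(1, 1))
  expect_equal(cl$ccf_primary, 0.5)
  # all mutations clonal: a single trunk cluster
  cl2 <- clusterCCF(rep(0.5, 20), rep(0.5, 20))
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$n_mutations, 20L)
  expect_error(clusterCCF(numeric(0), numeric(0)), "empty")
  expect_error(clusterCCF(0.8, 0.1), "VAF")
})

test_that("well-separated planted clusters are recovered exactly", {
  set.seed(5)
  truth <- rep(1:3, each = 30)
  cp <- c(0.5, 0.3, 0.1)[truth] + rnorm(90, 0, 0.015)
  cm <- c(0.5, 0.05, 0.25)[truth] + rnorm(90, 0, 0.015)
  cl <- clusterCCF(pmax(cp, 0) / 2, pmin(pmax(cm, 0), 1) / 2,
                   purity = c(1, 1), seed = 5)
  expect_equal(nrow(cl), 3L)
  asg <- attr(cl, "assignment")
  expect_equal(length(unique(paste(truth, asg))), 3L)  # exact recovery
})

test_that("forced nesting yields a chain, room yields branching", {
  chainCase <- data.frame(cluster = c("A", "B", "C"),
                          n_mutations = c(10, 6, 4),
                          ccf_primary = c(1, 0.6, 0.5),
                          ccf_met = c(1, 0.9, 0.8))
  tr <- buildTree(chainCase)
  expect_equal(tr$parent[match(c("A", "B", "C"), tr$cluster)],
               c(NA, "A", "B"))
  branchCase <- data.frame(cluster = c("A", "B", "C"),
                           n_mutations = c(10, 6, 4),
                           ccf_primary = c(1, 0.6, 0.3),
                           ccf_met = c(1, 0.7, 0.2))
  tr2 <- buildTree(branchCase)
  expect_equal(tr2$parent[match(c("B", "C"), tr2$cluster)], c("A", "A"))
  # exhaustive-search oracle agrees on both worked examples
  for (cs in list(chainCase, branchCase)) {
    got <- buildTree(cs)
    want <- oracleTree(cs)
    expect_equal(setNames(got$parent, got$cluster), want[got$cluster])
  }
  single <- data.frame(cluster = "A", n_mutations = 5,
                       ccf_primary = 1, ccf_met = 1)
  tr3 <- buildTree(single)
  expect_equal(nrow(tr3), 1L)
  expect_true(is.na(tr3$parent))
})

test_that("branch lengths sum to one and survive relabeling", {
  cl <- data.frame(cluster = c("A", "B", "C"), n_mutations = c(10, 6, 4),
                   ccf_primary = c(1, 0.6, 0.3), ccf_met = c(1, 0.7, 0.2))
  tr <- buildTree(cl)
  expect_equal(sum(tr$branch_length), 1)
  relabeled <- cl
  relabeled$cluster <- c("Z", "Q", "M")
  tr2 <- buildTree(relabeled)
  expect_equal(sort(tr2$branch_length), sort(tr$branch_length))
  nwk <- treeNewick(tr)
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("seeding classification follows the path criterion", {
  trunkOnly <- buildTree(data.frame(
    cluster = c("A", "B"), n_mutations = c(8, 4),
    ccf_primary = c(1, 0.5), ccf_met = c(1, 0.01)))
  expect_equal(classifySeeding(trunkOnly)$mode, "monoclonal")
  chain <- buildTree(data.frame(
    cluster = c("A", "B", "C"), n_mutations = c(10, 6, 4),
    ccf_primary = c(1, 0.6, 0.5), ccf_met = c(1, 0.9, 0.8)))
  expect_equal(classifySeeding(chain)$mode, "monoclonal")
  branching <- buildTree(data.frame(
    cluster = c("A", "B", "C"), n_mutations = c(10, 6, 4),
    ccf_primary = c(1, 0.6, 0.3), ccf_met = c(1, 0.7, 0.2)))
  call <- classifySeeding(branching)
  expect_equal(call$mode, "polyclonal")
  expect_setequal(call$seedingLineages, c("B", "C"))
  nothing <- buildTree(data.frame(
    cluster = "A", n_mutations = 5, ccf_primary = 1, ccf_met = 1))
  nothing$ccf_met <- 0
  expect_warning(res <- classifySeeding(nothing), "undefined")
  expect_true(is.na(res$mode))
})

test_that("every built tree satisfies the pigeonhole constraint", {
  for (s in 1:10) {
    mode <- if (s %% 2) "monoclonal" else "polyclonal"
    cc <- simulateCCFCase(mode, seed = 40 + s)
    out <- suppressWarnings(seedingCallFromCCF(cc$mutations, seed = s))
    expect_true(scClonality:::.treeSatisfiesPigeonhole(out$tree))
  }
})

test_that("seeding-mode classification is accurate on noisy CCF clusters", {
  hits <- 0; n <- 0
  for (mode in c("monoclonal", "polyclonal")) for (s in 1:20) {
    cc <- simulateCCFCase(mode, seed = 300 + s)
    call <- suppressWarnings(
      seedingCallFromCCF(cc$mutations, seed = s)$call$mode)
    hits <- hits + identical(call, mode); n <- n + 1
  }
  expect_gte(hits / n, 0.9)
})

test_that("the packaged ten-patient cohort splits six to four", {
  cohort <- tenPatientCohort()
  calls <- vapply(cohort, function(cl)
    classifySeeding(buildTree(cl))$mode, character(1))
  expect_equal(sum(calls == "polyclonal"), 6L)
  expect_equal(sum(calls == "monoclonal"), 4L)
  expect_setequal(names(calls)[calls == "monoclonal"],
                  c("P1", "P4", "P8", "P10"))
})
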