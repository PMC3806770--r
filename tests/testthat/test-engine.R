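test_that("DPM weights reproduce hand-expanded cases", {
  # two leaves, alpha = 1: pi = Gamma(2) / (Gamma(2) + 1*1) = 1/2
  w <- dpmWeights(log(1), log(1), 1, 1, alpha = 1)
  expect_equal(exp(w$logPi), 0.5, tolerance = 1e-14)
  expect_equal(exp(w$logD), 2, tolerance = 1e-14)

  # alpha -> 0+: pi = alpha/(alpha + alpha^2) -> 1
  a <- 1e-10
  w0 <- dpmWeights(log(a), log(a), 1, 1, alpha = a)
  expect_equal(exp(w0$logPi), 1, tolerance = 1e-8)

  # cascade ((x1,x2),x3) at alpha = 1: d_12 = 2 so pi_root =
  # Gamma(3)/(Gamma(3) + 2*1) = 1/2
  w12 <- dpmWeights(log(1), log(1), 1, 1, alpha = 1)
  wroot <- dpmWeights(w12$logD, log(1), 2, 1, alpha = 1)
  expect_equal(exp(wroot$logPi), 0.5, tolerance = 1e-14)

  expect_error(dpmWeights(0, 0, 1, 1, alpha = 0), "positive")
  expect_error(dpmWeights(0, 0, 1, 1, alpha = -2), "positive")
})

test_that("node evidence matches closed cases and naive arithmetic", {
  # symmetric evidence at pi = 1/2 gives r = 1/2
  ev <- nodeEvidence(log(0.5), -3, -1.5, -1.5)
  expect_equal(ev$r, 0.5, tolerance = 1e-14)

  # merged hypothesis ahead by log 3 gives r = 3/4
  ev2 <- nodeEvidence(log(0.5), -2 + log(3), -1, -1)
  expect_equal(ev2$r, 0.75, tolerance = 1e-12)

  # pi = 1: the split branch has no prior mass
  ev3 <- nodeEvidence(0, -4, -1, -1)
  expect_identical(ev3$r, 1)
  expect_identical(ev3$logMlTree, -4)

  # randomized moderate magnitudes against naive (non-log) arithmetic
  set.seed(8)
  for (rep in 1:50) {
    logPi <- log(runif(1, 0.05, 0.95))
    m1 <- runif(1, -20, 0)
    t1 <- runif(1, -12, 0)
    t2 <- runif(1, -12, 0)
    got <- nodeEvidence(logPi, m1, t1, t2)
    want <- nodeEvidenceNaive(logPi, m1, t1, t2)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$logMlTree, want$logMlTree, tolerance = 1e-10)
  }
})

test_that("two-point tree matches the hand-computed recursion to 1e-12", {
  X <- matrix(c(0.4, -0.8, 1.2, 0.1), 2, 2)
  hp <- ngHyperParams(1.2, 0.8, 1.5)
  alpha <- 1.7
  tree <- buildTree(X, "fixed", alpha = alpha, hp = hp)

  logml1 <- clusterMarginalLogLik(X[1, , drop = FALSE], hp)
  logml2 <- clusterMarginalLogLik(X[2, , drop = FALSE], hp)
  logmlh1 <- clusterMarginalLogLik(X, hp)
  d12 <- alpha * gamma(2) + alpha^2
  pi12 <- alpha * gamma(2) / d12
  mltree <- pi12 * exp(logmlh1) + (1 - pi12) * exp(logml1) * exp(logml2)
  r <- pi12 * exp(logmlh1) / mltree

  expect_equal(tree$logD[3], log(d12), tolerance = 1e-12)
  expect_equal(tree$logPi[3], log(pi12), tolerance = 1e-12)
  expect_equal(tree$logMlH1[3], logmlh1, tolerance = 1e-12)
  expect_equal(tree$logMlTree[3], log(mltree), tolerance = 1e-12)
  expect_equal(tree$r[3], r, tolerance = 1e-12)
  # leaf initialization
  expect_equal(tree$logPi[1:2], c(0, 0))
  expect_equal(tree$logD[1:2], rep(log(alpha), 2))
  expect_equal(tree$r[1:2], c(1, 1))
  expect_equal(tree$logMlTree[1:2], c(logml1, logml2))
})

test_that("greedy selection matches exhaustive candidate evaluation", {
  # two well-separated 1-D clusters; every within-cluster merge must precede
  # the single cross-cluster merge, and each engine merge must be the argmax
  # the R oracle finds
  X <- matrix(scale(c(-5.1, -5.0, -4.9, 4.9, 5.0, 5.1)), ncol = 1)
  hp <- ngHyperParams(1, 1, 1)
  tree <- buildTree(X, "fixed", alpha = 1, hp = hp)
  members <- treeMembers(tree)
  oracle <- greedyOracleOrder(X, 1, hp)
  for (t in seq_along(oracle)) {
    expect_identical(members[[6 + t]], oracle[[t]]$members)
    expect_equal(tree$r[6 + t], oracle[[t]]$r, tolerance = 1e-9)
  }
  # within-cluster merges (sizes 2 then 3, twice) come before the root
  sizes <- tree$nK[7:11]
  expect_true(all(sizes[1:4] <= 3))
  expect_identical(sizes[5], 6L)
})

test_that("single and two-observation inputs build valid trees", {
  lone <- buildTree(matrix(c(0.2, 0.4), 1, 2), "fixed")
  expect_identical(length(lone$r), 1L)
  expect_identical(lone$r, 1)

  X <- matrix(c(-2, 2), 2, 1)
  for (scheme in c("fixed", "node")) {
    tr <- buildTree(X, scheme)
    expect_identical(length(tr$r), 3L)
    expect_identical(tr$nK[3], 2L)
  }
  expect_error(buildTree(matrix(numeric(0), 0, 2)), "at least one row")
})

test_that("tree marginal dominates the merged-hypothesis term at every node", {
  set.seed(9)
  sim <- simulateScenario1(n = 50, d = 5, k = 3, seed = 9)
  for (scheme in c("node", "tree")) {
    fit <- gbhc(sim$data, scheme = scheme)
    nd <- fit@nodes
    internal <- nd$left != 0
    expect_true(all(nd$logMlTree[internal] >=
                      nd$logPi[internal] + nd$logMlH1[internal] - 1e-10))
    expect_true(all(nd$r >= 0 & nd$r <= 1))
    # disjoint-union bookkeeping
    members <- treeMembers(nd)
    for (i in which(internal)) {
      expect_identical(members[[i]],
                       sort(c(members[[nd$left[i]]], members[[nd$right[i]]])))
    }
  }
})

test_that("cut rule splits exactly the nodes with r at or below threshold", {
  # hand-built 5-leaf tree: root r=0.2 splits; left (leaves 1,2) r=0.9 holds;
  # right r=0.4 splits into (3,4) with r=0.8 and leaf 5 -> 3 clusters
  left <- c(0L, 0L, 0L, 0L, 0L, 1L, 3L, 7L, 6L)
  right <- c(0L, 0L, 0L, 0L, 0L, 2L, 4L, 5L, 8L)
  r <- c(1, 1, 1, 1, 1, 0.9, 0.8, 0.4, 0.2)
  part <- gbhc:::.cutPartition(left, right, r, 0.5, paste0("o", 1:5))
  expect_identical(length(unique(part)), 3L)
  expect_identical(as.integer(part), c(1L, 1L, 2L, 2L, 3L))

  # all mergers confident -> one cluster
  part1 <- gbhc:::.cutPartition(left, right, rep(1, 9), 0.5, paste0("o", 1:5))
  expect_identical(nlevels(part1), 1L)

  # root splits, both children confident -> exactly two clusters
  r2 <- c(1, 1, 1, 1, 1, 0.9, 0.8, 0.9, 0.3)
  part2 <- gbhc:::.cutPartition(left, right, r2, 0.5, paste0("o", 1:5))
  expect_identical(nlevels(part2), 2L)

  # boundary r = threshold splits
  r3 <- c(1, 1, 1, 1, 1, 0.9, 0.8, 0.9, 0.5)
  expect_identical(nlevels(gbhc:::.cutPartition(left, right, r3, 0.5,
                                                paste0("o", 1:5))), 2L)
})

test_that("partitions are invariant to observation order on separated data", {
  sim <- simulateScenario1(n = 45, d = 5, k = 3, seed = 10)
  for (scheme in c("node", "tree")) {
    fit <- gbhc(sim$data, scheme = scheme)
    set.seed(1)
    perm <- sample(nrow(sim$data))
    fitp <- gbhc(sim$data[perm, ], scheme = scheme)
    p1 <- partition(fit)[rownames(sim$data)]
    p2 <- partition(fitp)[rownames(sim$data)]
    expect_equal(adjustedRandIndex(p1, p2), 1)
  }
})

test_that("cluster count is non-decreasing in the concentration alpha", {
  sim <- simulateScenario1(n = 60, d = 6, k = 3, seed = 12)
  counts <- vapply(c(0.01, 1, 100), function(a)
    nClusters(gbhc(sim$data, scheme = "tree", alpha = a)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("fits are deterministic and expose consistent accessors", {
  sim <- simulateScenario1(n = 40, d = 5, k = 2, seed = 13)
  f1 <- gbhc(sim$data, scheme = "node")
  f2 <- gbhc(sim$data, scheme = "node")
  expect_identical(partition(f1), partition(f2))
  expect_identical(f1@nodes, f2@nodes)
  expect_identical(partition(f1), cutTree(f1, f1@cutThreshold))
  expect_identical(nClusters(f1), clusterCount(partition(f1)))
  expect_identical(length(mergeProbabilities(f1)), nrow(sim$data) - 1L)
  expect_output(show(f1), "GBHCFit")
})

test_that("unnormalized input triggers a warning, not an error", {
  X <- matrix(rnorm(40, mean = 5, sd = 3), 20, 2)
  expect_warning(gbhc(X, scheme = "tree"), "normalized")
  sim <- simulateScenario1(n = 20, d = 3, k = 2, seed = 14)
  expect_silent(gbhc(sim$data, scheme = "tree"))
})
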