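test_that("node objective decomposes into likelihood plus prior", {
  set.seed(20)
  X <- matrix(rnorm(24), 8, 3)
  s <- clusterStats(X)
  pr <- hyperPrior(shape = c(2, 1.5, 3), rate = c(2, 1, 0.5))
  for (rep in 1:10) {
    hp <- ngHyperParams(runif(1, 0.2, 4), runif(1, 0.2, 4), runif(1, 0.2, 4))
    lik <- clusterMarginalLogLik(X, hp)
    priorpart <- sum(dgamma(c(hp@c, hp@a, hp@b), shape = pr@shape,
                            rate = pr@rate, log = TRUE))
    expect_equal(nodeLogPosterior(s, hp, pr), lik + priorpart,
                 tolerance = 1e-12)
  }
})

test_that("flat-prior limit reduces the objective to the likelihood", {
  set.seed(21)
  X <- matrix(rnorm(15), 5, 3)
  s <- clusterStats(X)
  hp <- ngHyperParams(0.8, 1.1, 1.4)
  r <- 1e-12
  pr <- hyperPrior(shape = c(1, 1, 1), rate = rep(r, 3))
  # with shape 1 the gamma log-density is log(rate) - rate*x; the constant
  # 3*log(rate) is the only surviving prior contribution as rate -> 0+
  expect_equal(nodeLogPosterior(s, hp, pr) - 3 * log(r),
               clusterMarginalLogLik(X, hp), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  set.seed(22)
  for (rep in 1:20) {
    X <- matrix(rnorm(sample(2:20, 1) * 4, sd = runif(1, 0.5, 2)), ncol = 4)
    s <- clusterStats(X)
    pr <- hyperPrior(shape = runif(3, 0.8, 3), rate = runif(3, 0.5, 3))
    hp <- exp(runif(3, -1, 1))
    g <- nodeGradient(s, ngHyperParams(hp[1], hp[2], hp[3]), pr)
    # central differences on log-parameters, step 1e-6
    h <- 1e-6
    theta <- log(hp)
    fd <- vapply(1:3, function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h
      tm[i] <- tm[i] - h
      fp <- nodeLogPosterior(s, ngHyperParams(exp(tp[1]), exp(tp[2]),
                                              exp(tp[3])), pr)
      fm <- nodeLogPosterior(s, ngHyperParams(exp(tm[1]), exp(tm[2]),
                                              exp(tm[3])), pr)
      (fp - fm) / (2 * h)
    }, numeric(1))
    analytic <- unname(g) * hp  # chain rule to log-parameters
    expect_equal(analytic, fd, tolerance = 1e-5)
  }
})

test_that("empty clusters reduce the gradient to the prior-only gradient", {
  s0 <- clusterStats(matrix(numeric(0), 0, 3))
  pr <- hyperPrior(shape = c(2, 3, 1.5), rate = c(1, 2, 0.7))
  hp <- ngHyperParams(0.9, 1.2, 2.1)
  g <- nodeGradient(s0, hp, pr)
  expected <- (pr@shape - 1) / c(hp@c, hp@a, hp@b) - pr@rate
  expect_equal(unname(g), expected, tolerance = 1e-14)
  # objective likewise collapses to the prior density
  expect_equal(nodeLogPosterior(s0, hp, pr),
               sum(dgamma(c(hp@c, hp@a, hp@b), shape = pr@shape,
                          rate = pr@rate, log = TRUE)), tolerance = 1e-14)
})

test_that("R and C++ objective/gradient agree", {
  set.seed(23)
  for (rep in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    s <- clusterStats(X)
    pr <- hyperPrior(shape = runif(3, 1, 3), rate = runif(3, 0.5, 2))
    hp <- exp(runif(3, -1, 1))
    expect_equal(
      gbhc:::.cppNodeObjective(s$n, s$mean, s$ssd, hp, pr@shape, pr@rate),
      nodeLogPosterior(s, ngHyperParams(hp[1], hp[2], hp[3]), pr),
      tolerance = 1e-12)
    expect_equal(
      gbhc:::.cppNodeGradient(s$n, s$mean, s$ssd, hp, pr@shape, pr@rate),
      nodeGradient(s, ngHyperParams(hp[1], hp[2], hp[3]), pr),
      tolerance = 1e-10)
  }
})

test_that("optimizeNode ascends, is deterministic and stationary", {
  set.seed(24)
  s <- clusterStats(matrix(rnorm(80), 40, 2))
  pr <- hyperPrior()
  opt <- optimizeNode(s, pr)
  fopt <- attr(opt, "objective")
  expect_equal(fopt, nodeLogPosterior(s, opt, pr), tolerance = 1e-10)
  # ascent over 5 random restart starting points
  for (rep in 1:5) {
    start <- ngHyperParams(exp(runif(1, -1.5, 1.5)), exp(runif(1, -1.5, 1.5)),
                           exp(runif(1, -1.5, 1.5)))
    expect_gte(fopt + 1e-8, nodeLogPosterior(s, start, pr))
    o2 <- optimizeNode(s, pr, init = start)
    expect_gte(attr(o2, "objective") + 1e-8, nodeLogPosterior(s, start, pr))
  }
  # first-order condition at the interior optimum (log-scale gradient)
  g <- nodeGradient(s, opt, pr) * c(opt@c, opt@a, opt@b)
  expect_lt(sqrt(sum(g^2)), 1e-4)
  # identical clusters give identical hyperparameters
  o3 <- optimizeNode(s, pr)
  expect_identical(c(opt@c, opt@a, opt@b), c(o3@c, o3@a, o3@b))
})

test_that("optimized hyperparameters imply a calibrated posterior predictive", {
  # n = 500 draws from the assumed model with mu = 0, tau = 1: the posterior
  # predictive variance b_n (c_n + 1) / (a_n c_n) * 2a_n / (2a_n - 2) at the
  # optimized hyperparameters must track the empirical variance
  set.seed(25)
  X <- matrix(rnorm(1000), 500, 2)
  s <- clusterStats(X)
  opt <- optimizeNode(s, hyperPrior())
  post <- ngPosteriorUpdate(s, opt)
  predvar <- mean(post$b) * (post$c + 1) / (post$a * post$c) *
    (2 * post$a) / (2 * post$a - 2)
  empirical <- mean(apply(X, 2, var))
  expect_lt(abs(predvar - empirical) / empirical, 0.2)
})

test_that("TREE outer loop is monotone and improves on the initial fit", {
  sim <- simulateScenario1(n = 50, d = 5, k = 3, seed = 26)
  init <- ngHyperParams(2, 0.5, 2)
  opt <- optimizeTree(sim$data, init = init)
  expect_true(all(diff(opt$trace) > 0 | length(opt$trace) == 1))
  # never worse than the tree built at the initialization
  tr0 <- buildTree(sim$data, "fixed", hp = init)
  expect_gte(opt$rootLogLik, tr0$logMlTree[length(tr0$logMlTree)])
  # the returned tree is the one built under the returned hyperparameters
  tr <- buildTree(sim$data, "fixed", hp = opt$hp)
  expect_equal(tr$logMlTree, opt$tree$logMlTree, tolerance = 1e-12)
  # single observation degenerates gracefully
  one <- optimizeTree(matrix(c(0.1, -0.2), 1, 2))
  expect_identical(length(one$tree$r), 1L)
})

test_that("two observations reduce both schemes to one merger decision", {
  for (gap in c(0.1, 8)) {
    X <- matrix(c(-gap / 2, gap / 2), 2, 1)
    for (scheme in c("node", "tree")) {
      fit <- suppressWarnings(gbhc(X, scheme = scheme))
      expect_identical(nrow(fit@nodes), 3L)
      r <- fit@nodes$r[3]
      # the partition is fully determined by the single merger's r
      expect_identical(nClusters(fit), if (r > 0.5) 1L else 2L)
    }
  }
})

test_that("hyperparameters on the boundary are rejected", {
  s <- clusterStats(matrix(rnorm(10), 5, 2))
  expect_error(nodeLogPosterior(s, ngHyperParams(0, 1, 1)), "positive")
  expect_error(nodeGradient(s, ngHyperParams(1, 1, -1)), "positive")
  expect_error(hyperPrior(shape = c(0, 1, 1)), "positive")
})
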