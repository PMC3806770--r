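# Independent oracles used across the suite. None of them call into the
# package's own closed forms.

# High-precision 2-D quadrature of the marginal-likelihood integrand for one
# dimension: integral over (mu, tau) of
#   prod_i N(x_i | mu, tau) * N(mu | 0, (c tau)^-1) * Gamma(tau | a, b)
ngMarginalQuad <- function(x, cc, a, b, rel.tol = 1e-9) {
  outer_f <- function(tau) sapply(tau, function(t) {
    inner <- function(mu) sapply(mu, function(m)
      prod(stats::dnorm(x, m, 1 / sqrt(t))) *
        stats::dnorm(m, 0, 1 / sqrt(cc * t)))
    stats::integrate(inner, -Inf, Inf, rel.tol = rel.tol)$value *
      stats::dgamma(t, a, rate = b)
  })
  log(stats::integrate(outer_f, 0, Inf, rel.tol = rel.tol)$value)
}

# Brute-force adjusted Rand index by explicit pair counting
ariBruteForce <- function(p, q) {
  n <- length(p)
  s11 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- p[i] == p[j]
    sq <- q[i] == q[j]
    if (sp && sq) s11 <- s11 + 1
    else if (sp) s10 <- s10 + 1
    else if (sq) s01 <- s01 + 1
  }
  total <- n * (n - 1) / 2
  rowsum <- s11 + s10
  colsum <- s11 + s01
  expected <- rowsum * colsum / total
  maxidx <- (rowsum + colsum) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)
  (s11 - expected) / (maxidx - expected)
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments of the pooled ranks (no ties assumed)
wilcoxExactEnum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, function(idx)
    sum(rank(seq_len(n1 + n2))[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# naive (non-log) evidence arithmetic for moderate magnitudes
nodeEvidenceNaive <- function(logPi, logMlH1, logMlT1, logMlT2) {
  pi <- exp(logPi)
  mlTree <- pi * exp(logMlH1) + (1 - pi) * exp(logMlT1) * exp(logMlT2)
  list(logMlTree = log(mlTree), r = pi * exp(logMlH1) / mlTree)
}

# hand-rolled greedy step: the pair of current clusters with maximal r,
# evaluated from raw data with the package's exported primitives only
greedyOracleOrder <- function(X, alpha, hp) {
  clusters <- as.list(seq_len(nrow(X)))
  logd <- rep(log(alpha), nrow(X))
  logmlt <- vapply(seq_len(nrow(X)), function(i)
    clusterMarginalLogLik(X[i, , drop = FALSE], hp), numeric(1))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      w <- dpmWeights(logd[i], logd[j], length(clusters[[i]]),
                      length(clusters[[j]]), alpha)
      mlh1 <- clusterMarginalLogLik(
        X[c(clusters[[i]], clusters[[j]]), , drop = FALSE], hp)
      ev <- nodeEvidence(w$logPi, mlh1, logmlt[i], logmlt[j],
                         log1mPi = logd[i] + logd[j] - w$logD)
      if (is.null(best) || ev$r > best$r)
        best <- list(i = i, j = j, r = ev$r, logD = w$logD,
                     logMlTree = ev$logMlTree)
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best$i]], clusters[[best$j]])),
           r = best$r)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    logd[best$i] <- best$logD
    logmlt[best$i] <- best$logMlTree
    clusters[[best$j]] <- NULL
    logd <- logd[-best$j]
    logmlt <- logmlt[-best$j]
  }
  merges
}

# members of every node of a raw buildTree() result
treeMembers <- function(tree) {
  M <- length(tree$left)
  members <- vector("list", M)
  for (i in seq_len(M)) {
    members[[i]] <- if (tree$left[i] == 0L) i
      else sort(c(members[[tree$left[i]]], members[[tree$right[i]]]))
  }
  members
}
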