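.checkPrior <- function(prior) {
  if (!methods::is(prior, "HyperPrior")) stop("'prior' must be a HyperPrior")
  methods::validObject(prior)
  invisible(prior)
}

#' Log posterior of the hyperparameters at one merger
#'
#' The objective maximized by the NODE scheme for a candidate cluster: the
#' cluster's log marginal likelihood under shared hyperparameters (c, a, b)
#' plus independent log gamma hyper-prior densities on each of c, a, b.
#'
#' @param stats \code{\link{clusterStats}} of the cluster (all dimensions).
#' @param hp an \code{\link{NGHyperParams}}; must be strictly positive.
#' @param prior a \code{\link{hyperPrior}}.
#' @return a finite real; it decomposes exactly as likelihood + prior.
#' @examples
#' s <- clusterStats(matrix(rnorm(30), 10, 3))
#' nodeLogPosterior(s, ngHyperParams(), hyperPrior())
#' @export
nodeLogPosterior <- function(stats, hp, prior = hyperPrior()) {
  .checkHp(hp)
  .checkStats(stats)
  .checkPrior(prior)
  .marginalFromStats(stats, hp) +
    sum(stats::dgamma(c(hp@c, hp@a, hp@b), shape = prior@shape,
                      rate = prior@rate, log = TRUE))
}

#' Analytic gradient of the node log posterior
#'
#' Gradient of \code{\link{nodeLogPosterior}} with respect to (c, a, b),
#' summed over dimensions. With posterior updates
#' \eqn{c_n = c + n}, \eqn{a_n = a + n/2},
#' \eqn{b_{n,j} = b + ssd_j/2 + c n \bar x_j^2/(2 c_n)}:
#' \deqn{\partial_a = d\,[\psi(a_n) - \psi(a) + \log b] - \sum_j \log b_{n,j}}
#' \deqn{\partial_b = d\,a/b - a_n \sum_j 1/b_{n,j}}
#' \deqn{\partial_c = \tfrac{d}{2}(1/c - 1/c_n)
#'   - \sum_j (a_n / b_{n,j})\, n^2 \bar x_j^2 / (2 c_n^2)}
#' plus the gamma-prior terms \eqn{(k-1)/x - r}. \eqn{\psi} is the digamma
#' function. For an empty cluster the likelihood part is exactly zero.
#'
#' @inheritParams nodeLogPosterior
#' @return named numeric gradient over \code{c}, \code{a}, \code{b}.
#' @examples
#' s <- clusterStats(matrix(rnorm(30), 10, 3))
#' nodeGradient(s, ngHyperParams(), hyperPrior())
#' @export
nodeGradient <- function(stats, hp, prior = hyperPrior()) {
  .checkHp(hp)
  .checkStats(stats)
  .checkPrior(prior)
  n <- stats$n
  d <- length(stats$mean)
  x <- c(hp@c, hp@a, hp@b)
  gPrior <- (prior@shape - 1) / x - prior@rate
  if (n == 0)
    return(stats::setNames(gPrior, c("c", "a", "b")))
  cn <- hp@c + n
  an <- hp@a + n / 2
  bn <- hp@b + stats$ssd / 2 + hp@c * n * stats$mean^2 / (2 * cn)
  ga <- d * (digamma(an) - digamma(hp@a) + log(hp@b)) - sum(log(bn))
  gb <- d * hp@a / hp@b - an * sum(1 / bn)
  dbndc <- n^2 * stats$mean^2 / (2 * cn^2)
  gc <- d * 0.5 * (1 / hp@c - 1 / cn) - an * sum(dbndc / bn)
  stats::setNames(c(gc, ga, gb) + gPrior, c("c", "a", "b"))
}

#' Maximize the hyperparameter posterior of one cluster
#'
#' Conjugate-gradient ascent (Polak-Ribiere with backtracking line search) on
#' \code{\link{nodeLogPosterior}} in (log c, log a, log b); the log
#' reparameterization enforces positivity. This is the inner optimization of
#' the NODE scheme, run once per candidate merger.
#'
#' @param stats \code{\link{clusterStats}} of the cluster.
#' @param prior a \code{\link{hyperPrior}} (hyper-priors, tolerances,
#'   iteration cap).
#' @param init starting \code{\link{NGHyperParams}}; defaults to the prior's
#'   \code{init} triple.
#' @return an \code{\link{NGHyperParams}} with attributes \code{objective},
#'   \code{converged} and \code{iterations}. A warning is emitted if the
#'   iteration cap was reached first (the objective can be non-convex; the
#'   best iterate is returned).
#' @examples
#' s <- clusterStats(matrix(rnorm(200), 100, 2))
#' optimizeNode(s, hyperPrior())
#' @export
optimizeNode <- function(stats, prior = hyperPrior(), init = NULL) {
  .checkStats(stats)
  .checkPrior(prior)
  start <- if (is.null(init)) prior@init else {
    .checkHp(init)
    c(init@c, init@a, init@b)
  }
  res <- .cppOptimizeNode(stats$n, stats$mean, stats$ssd, start,
                          prior@shape, prior@rate,
                          prior@maxIter, prior@gradTol, prior@objTol)
  if (!res$converged)
    warning("hyperparameter optimization hit the iteration cap; ",
            "returning the best iterate")
  out <- ngHyperParams(res$c, res$a, res$b)
  attr(out, "objective") <- res$objective
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  out
}

#' Global hyperparameter optimization over the whole tree
#'
#' The TREE scheme: alternate between (i) building the full dendrogram under
#' the current shared hyperparameters and (ii) maximizing the root marginal
#' likelihood over (log c, log a, log b) with the tree structure held fixed
#' (the gradients of the root marginal are tractable only then). Iteration
#' stops when a rebuild no longer improves the root log marginal likelihood,
#' or after \code{maxRounds} rounds; the best (hyperparameters, tree) pair is
#' returned, so the recorded trace is non-decreasing. The fixed-structure
#' step uses Nelder-Mead on the three log-parameters.
#'
#' @param X numeric matrix, observations in rows.
#' @param alpha DPM concentration.
#' @param init starting \code{\link{NGHyperParams}}.
#' @param prior a \code{\link{hyperPrior}}; only its optimizer tolerances are
#'   used here (the TREE objective carries no hyper-prior).
#' @param maxRounds maximum outer rounds.
#' @param verbose print per-round progress.
#' @return list with \code{hp} (an \code{NGHyperParams}), \code{tree} (raw
#'   node arrays, as consumed by \code{\link{gbhc}}), \code{rootLogLik} and
#'   \code{trace} (root log marginal likelihood per accepted round).
#' @examples
#' sim <- simulateScenario1(n = 40, d = 4, k = 2, seed = 1)
#' opt <- optimizeTree(sim$data)
#' opt$hp
#' @export
optimizeTree <- function(X, alpha = 1, init = ngHyperParams(),
                         prior = hyperPrior(), maxRounds = 20L,
                         verbose = FALSE) {
  X <- .checkMatrix(X)
  .checkHp(init)
  .checkPrior(prior)
  stopifnot(alpha > 0, maxRounds >= 1L)
  hp <- c(init@c, init@a, init@b)
  best <- NULL
  trace <- numeric(0)
  for (round in seq_len(maxRounds)) {
    tree <- .cppBuildTree(X, alpha, FALSE, hp, prior@shape, prior@rate,
                          prior@init, prior@maxIter, prior@gradTol,
                          prior@objTol)
    ml <- tree$logMlTree[length(tree$logMlTree)]
    if (!is.null(best) && ml <= best$ml + prior@objTol) break
    best <- list(hp = hp, tree = tree, ml = ml)
    trace <- c(trace, ml)
    if (verbose)
      message(sprintf("  round %d: root logML %.6f  (c=%.3g a=%.3g b=%.3g)",
                      round, ml, hp[1], hp[2], hp[3]))
    obj <- function(theta) {
      h <- exp(pmin(pmax(theta, -25), 25))
      -.cppRootLogLikFixed(tree$left, tree$right, as.numeric(tree$nK),
                           tree$means, tree$ssds, alpha, h[1], h[2], h[3])
    }
    fit <- stats::optim(log(hp), obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (-fit$value <= ml + prior@objTol) break  # structure is self-consistent
    hp <- exp(pmin(pmax(fit$par, -25), 25))
  }
  list(hp = ngHyperParams(best$hp[1], best$hp[2], best$hp[3]),
       tree = best$tree, rootLogLik = best$ml, trace = trace)
}
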