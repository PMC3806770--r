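#' Dirichlet process mixture merge prior
#'
#' The recursive weight term and merge prior of the DPM approximation:
#' \deqn{d_k = \alpha\,\Gamma(n_k) + d_i d_j, \qquad
#'       \pi_k = \alpha\,\Gamma(n_k) / d_k,}
#' computed in log space with log-gamma (the gamma function overflows near
#' n = 170 otherwise). Leaves carry \eqn{d = \alpha}, \eqn{\pi = 1}.
#'
#' @param logD1,logD2 log d of the two children.
#' @param n1,n2 member counts of the two children.
#' @param alpha DPM concentration, positive; larger values raise the expected
#'   number of clusters.
#' @return list with \code{logD} and \code{logPi} of the merged cluster.
#' @examples
#' dpmWeights(log(1), log(1), 1, 1, alpha = 1)  # pi = 1/2
#' @export
dpmWeights <- function(logD1, logD2, n1, n2, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive number")
  nk <- n1 + n2
  lg <- log(alpha) + lgamma(nk)
  logD <- .logsumexp2(lg, logD1 + logD2)
  list(logD = logD, logPi = lg - logD)
}

.logsumexp2 <- function(x, y) {
  if (x == -Inf) return(y)
  if (y == -Inf) return(x)
  m <- max(x, y)
  m + log(exp(x - m) + exp(y - m))
}

#' Tree marginal likelihood and posterior merge probability of one node
#'
#' The recursive evidence of the subtree rooted at a candidate merger and the
#' posterior probability that its two children belong to a single mixture
#' component:
#' \deqn{p(D_k | T_k) = \pi_k\,p(D_k | H_1) +
#'       (1-\pi_k)\,p(D_i | T_i)\,p(D_j | T_j), \qquad
#'       r_k = \pi_k\,p(D_k|H_1) / p(D_k|T_k),}
#' evaluated with log-sum-exp.
#'
#' @param logPi log merge prior of the node.
#' @param logMlH1 log marginal likelihood of the merged cluster under the
#'   single-component hypothesis.
#' @param logMlTreeLeft,logMlTreeRight children's log tree marginals.
#' @param log1mPi optional log(1 - pi); supply
#'   \code{logD1 + logD2 - logD} for exact log-space arithmetic, otherwise
#'   it is derived from \code{logPi}.
#' @return list with \code{logMlTree} and \code{r} (in [0, 1]).
#' @examples
#' nodeEvidence(log(0.5), -3, -1.5, -1.5)  # r = 0.5
#' @export
nodeEvidence <- function(logPi, logMlH1, logMlTreeLeft, logMlTreeRight,
                         log1mPi = NULL) {
  stopifnot(is.finite(logMlH1), is.finite(logMlTreeLeft),
            is.finite(logMlTreeRight), logPi <= 0)
  if (logPi == 0)  # pi = 1: the split hypothesis has zero prior mass
    return(list(logMlTree = logMlH1, r = 1))
  if (is.null(log1mPi)) log1mPi <- log1p(-exp(logPi))
  t1 <- logPi + logMlH1
  t2 <- log1mPi + logMlTreeLeft + logMlTreeRight
  logMlTree <- .logsumexp2(t1, t2)
  list(logMlTree = logMlTree, r = min(1, max(0, exp(t1 - logMlTree))))
}

# engine call; returns raw node arrays from C++
.buildTreeRaw <- function(X, scheme, alpha, hp, prior) {
  .cppBuildTree(X, alpha, identical(scheme, "node"),
                c(hp@c, hp@a, hp@b), prior@shape, prior@rate, prior@init,
                prior@maxIter, prior@gradTol, prior@objTol)
}

#' Low-level greedy agglomeration
#'
#' Builds the full binary dendrogram by repeatedly merging the candidate pair
#' with the highest posterior merge probability r; ties break toward the
#' lexicographically smallest pair of positions in the creation-ordered
#' cluster list, so reruns are deterministic. Under \code{scheme = "fixed"}
#' the supplied hyperparameters are used throughout (the TREE scheme's inner
#' build); under \code{scheme = "node"} every candidate merger's
#' hyperparameters are optimized against its own posterior
#' (\code{\link{optimizeNode}}). Most users want \code{\link{gbhc}}, which
#' wraps this and cuts the tree.
#'
#' @param X numeric matrix, observations in rows.
#' @param scheme \code{"fixed"} or \code{"node"}.
#' @param alpha DPM concentration.
#' @param hp shared \code{\link{NGHyperParams}} for \code{scheme = "fixed"}.
#' @param prior a \code{\link{hyperPrior}} for \code{scheme = "node"}.
#' @return list of per-node vectors over the 2n-1 nodes (leaves first, then
#'   merges in order): \code{left}, \code{right} (0 for leaves), \code{nK},
#'   \code{logD}, \code{logPi}, \code{logMlH1}, \code{logMlTree}, \code{r},
#'   plus the per-node hyperparameter matrix \code{hp} and per-node
#'   sufficient statistics \code{means}, \code{ssds}.
#' @examples
#' X <- matrix(c(-5.1, -5, -4.9, 4.9, 5, 5.1), ncol = 1)
#' tr <- buildTree(X, "fixed")
#' tr$r
#' @export
buildTree <- function(X, scheme = c("fixed", "node"), alpha = 1,
                      hp = ngHyperParams(), prior = hyperPrior()) {
  scheme <- match.arg(scheme)
  X <- .checkMatrix(X)
  .checkHp(hp)
  .checkPrior(prior)
  stopifnot(alpha > 0)
  .buildTreeRaw(X, if (scheme == "node") "node" else "tree", alpha, hp, prior)
}

# flat partition by descending from the root and splitting every node with
# r <= threshold; clusters are the maximal surviving subtrees
.cutPartition <- function(left, right, r, threshold, labels) {
  n <- length(labels)
  assign <- integer(n)
  root <- length(left)
  stack <- root
  cluster <- 0L
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (left[id] != 0L && r[id] <= threshold) {
      stack <- c(stack, left[id], right[id])
    } else {
      cluster <- cluster + 1L
      # collect leaves of this subtree
      sub <- id
      while (length(sub)) {
        s <- sub[[length(sub)]]
        sub <- sub[-length(sub)]
        if (left[s] == 0L) assign[s] <- cluster
        else sub <- c(sub, left[s], right[s])
      }
    }
  }
  # relabel in order of first appearance for determinism
  assign <- match(assign, unique(assign[order(seq_len(n))]))
  structure(factor(assign), names = labels)
}

#' Cut a fitted dendrogram into a flat partition
#'
#' Descends from the root and splits every node whose posterior merge
#' probability r is at or below the threshold; the clusters are the maximal
#' subtrees whose root has r above it. At the default threshold 0.5 the
#' partition keeps exactly the mergers that are more likely than not.
#'
#' @param object a \code{\link{GBHCFit}}.
#' @param threshold merge-probability cut level in (0, 1).
#' @param ... unused.
#' @return a named factor assigning each observation to a cluster.
#' @examples
#' sim <- simulateScenario1(n = 40, d = 4, k = 2, seed = 1)
#' fit <- gbhc(sim$data)
#' table(cutTree(fit, 0.5))
#' @rdname cutTree
#' @aliases cutTree,GBHCFit-method
#' @export
setMethod("cutTree", "GBHCFit", function(object, threshold = 0.5, ...) {
  stopifnot(threshold > 0, threshold < 1)
  .cutPartition(object@nodes$left, object@nodes$right, object@nodes$r,
                threshold, object@labels)
})

#' Gaussian Bayesian hierarchical clustering
#'
#' Greedy model-based agglomeration of the rows of \code{X}. Starting from
#' singleton clusters, the pair with the highest posterior merge probability
#' r (under a Dirichlet process mixture of Gaussians with a normal-gamma
#' prior on each dimension's unknown mean and precision) is merged until one
#' cluster remains; the dendrogram is then cut where r drops to 0.5 or below,
#' which also infers the number of clusters.
#'
#' Two empirical-Bayes schemes set the hyperparameters: \code{"tree"}
#' alternates between building the tree under the current shared triple
#' (c, a, b) and maximizing the root marginal likelihood with the structure
#' held fixed; \code{"node"} maximizes, for every candidate merger, the
#' posterior of its own hyperparameters under gamma hyper-priors, by
#' conjugate-gradient ascent in log space with analytic digamma gradients
#' (warm-started from the larger child).
#'
#' Input rows are expected to be z-score normalized (each column mean 0,
#' variance 1); a warning is emitted otherwise.
#'
#' @param X numeric matrix, observations in rows.
#' @param scheme \code{"node"} (default) or \code{"tree"}.
#' @param alpha DPM concentration (default 1); larger values favour more
#'   clusters. Not optimized.
#' @param cutThreshold merge-probability cut level, default 0.5.
#' @param prior a \code{\link{hyperPrior}}: gamma hyper-priors (NODE) and
#'   optimizer settings for both schemes.
#' @param hp initial shared hyperparameters (TREE scheme).
#' @param maxRounds maximum outer build/optimize rounds for the TREE scheme.
#' @param verbose print progress.
#' @return a \code{\link{GBHCFit}}.
#' @examples
#' sim <- simulateScenario1(n = 60, d = 5, k = 3, seed = 1)
#' fit <- gbhc(sim$data, scheme = "node")
#' nClusters(fit)
#' adjustedRandIndex(partition(fit), sim$labels)
#' @export
gbhc <- function(X, scheme = c("node", "tree"), alpha = 1,
                 cutThreshold = 0.5, prior = hyperPrior(),
                 hp = ngHyperParams(), maxRounds = 20L, verbose = FALSE) {
  scheme <- match.arg(scheme)
  X <- .checkMatrix(X)
  stopifnot(alpha > 0, cutThreshold > 0, cutThreshold < 1)
  .warnIfUnnormalized(X)
  if (scheme == "tree") {
    opt <- optimizeTree(X, alpha = alpha, init = hp, prior = prior,
                        maxRounds = maxRounds, verbose = verbose)
    raw <- opt$tree
    hpOut <- opt$hp
    trace <- opt$trace
  } else {
    raw <- .buildTreeRaw(X, "node", alpha, hp, prior)
    root <- length(raw$left)
    hpOut <- ngHyperParams(raw$hp[root, "c"], raw$hp[root, "a"],
                           raw$hp[root, "b"])
    trace <- raw$logMlTree[length(raw$logMlTree)]
  }
  labels <- rownames(X)
  part <- .cutPartition(raw$left, raw$right, raw$r, cutThreshold, labels)
  if (verbose)
    message(sprintf("GBHC-%s: %d clusters at r <= %g (root logML %.3f)",
                    toupper(scheme), nlevels(part), cutThreshold,
                    raw$logMlTree[length(raw$logMlTree)]))
  new("GBHCFit",
      scheme = scheme, alpha = alpha, cutThreshold = cutThreshold,
      nodes = data.frame(left = raw$left, right = raw$right, nK = raw$nK,
                         logD = raw$logD, logPi = raw$logPi,
                         logMlH1 = raw$logMlH1, logMlTree = raw$logMlTree,
                         r = raw$r),
      hyperParams = hpOut, nodeHyperParams = raw$hp,
      partition = part, labels = labels,
      rootLogLik = raw$logMlTree[length(raw$logMlTree)],
      trace = trace)
}

.checkMatrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  if (nrow(X) < 1L) stop("'X' must have at least one row")
  if (any(!is.finite(X))) stop("non-finite values in 'X'")
  if (is.null(rownames(X)))
    rownames(X) <- sprintf("obs%d", seq_len(nrow(X)))
  X
}

.warnIfUnnormalized <- function(X, tol = 1e-4) {
  if (nrow(X) < 2L) return(invisible())
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  if (max(abs(mu)) > tol || max(abs(v - 1)) > tol)
    warning("input does not look z-score normalized ",
            "(column means 0, variances 1); see zscoreNormalize()")
  invisible()
}
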